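#' @include AllClasses.R
NULL

## Coordinate-space aliases accepted in foci files
.SPACE_ALIASES <- c(
    "MNI" = "MNI", "MNI152" = "MNI", "ICBM" = "MNI",
    "TAL" = "TAL", "TALAIRACH" = "TAL", "TLRC" = "TAL")
.GROUP_ALIASES <- c(
    "ASD" = "ASD", "AUTISM" = "ASD", "AUTISTIC" = "ASD", "ASC" = "ASD",
    "NT" = "NT", "TD" = "NT", "CONTROL" = "NT", "NEUROTYPICAL" = "NT",
    "HC" = "NT")

#' Read a per-study activation-foci table
#'
#' Reads a UTF-8 TSV with header \code{study_id, group, x, y, z, space}, one
#' peak per row. Group and space tokens are normalised (e.g. "Talairach" to
#' \code{TAL}, "control" to \code{NT}); exact duplicate rows are dropped with
#' a warning.
#'
#' @param path path to the TSV file.
#' @return a \linkS4class{StudyFociTable}.
#' @seealso \code{\link{normalizeToMni}}
#' @export
readFoci <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE)
    req <- c("study_id", "group", "x", "y", "z", "space")
    miss <- setdiff(req, names(raw))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    for (cc in c("x", "y", "z")) {
        v <- suppressWarnings(as.numeric(raw[[cc]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(sprintf("non-numeric %s at row %d: '%s'",
                         cc, bad[1], raw[[cc]][bad[1]]))
        raw[[cc]] <- v
    }
    raw$group <- .mapToken(raw$group, .GROUP_ALIASES, "group")
    raw$space <- .mapToken(raw$space, .SPACE_ALIASES, "space")
    dup <- duplicated(raw[, req])
    if (any(dup)) {
        warning(sum(dup), " duplicate focus row(s) removed")
        raw <- raw[!dup, , drop = FALSE]
    }
    StudyFociTable(raw[, req])
}

.mapToken <- function(x, aliases, what) {
    key <- toupper(trimws(x))
    out <- aliases[key]
    bad <- which(is.na(out))
    if (length(bad))
        stop(sprintf("unknown %s token at row %d: '%s'",
                     what, bad[1], x[bad[1]]))
    unname(out)
}

## ---------------------------------------------------------------------------
## Talairach <-> MNI transforms
## ---------------------------------------------------------------------------

## MNI -> Talairach affine of Lacadie et al. (2008), the "mni2tal" mapping of
## BioImage Suite. TAL -> MNI is its exact matrix inverse.
.LACADIE_MNI2TAL <- matrix(c(
     0.9357,  0.0029, -0.0072, -1.0423,
    -0.0065,  0.9396, -0.0726, -1.3940,
     0.0103,  0.0752,  0.8967,  3.6475,
     0,       0,       0,       1), 4, 4, byrow = TRUE)

## Brett (1999) piecewise mni2tal: separate linear maps above/below the
## AC-PC plane (z >= 0 vs z < 0), identity-translation free.
.BRETT_UP <- matrix(c(      # MNI -> TAL, z >= 0
    0.9900, 0,       0,
    0,      0.9688,  0.0460,
    0,     -0.0485,  0.9189), 3, 3, byrow = TRUE)
.BRETT_DOWN <- matrix(c(    # MNI -> TAL, z < 0
    0.9900, 0,       0,
    0,      0.9688,  0.0420,
    0,     -0.0485,  0.8390), 3, 3, byrow = TRUE)

#' Convert between Talairach and MNI coordinates
#'
#' \code{talToMni} maps Talairach mm coordinates into MNI space;
#' \code{mniToTal} is the reverse map. Two published transforms are
#' supported: the default \code{"lacadie"} affine (the mni2tal mapping of
#' Lacadie et al., inverted exactly for the TAL-to-MNI direction, so the two
#' functions are exact functional inverses) and the \code{"brett"} piecewise
#' transform, which uses separate linear maps above and below z = 0 (branch
#' chosen by the sign of the input z; the piecewise pair is only
#' approximately self-inverse near the boundary plane).
#'
#' @param xyz numeric length-3 coordinate or n x 3 matrix, in mm.
#' @param method \code{"lacadie"} (affine, default) or \code{"brett"}
#'   (piecewise).
#' @return coordinates of the same shape as \code{xyz}.
#' @export
#' @examples
#' p <- c(-8, -26, 2)
#' mniToTal(talToMni(p))   # recovers p (affine transform)
talToMni <- function(xyz, method = c("lacadie", "brett")) {
    method <- match.arg(method)
    if (method == "lacadie")
        .applyAffine(solve(.LACADIE_MNI2TAL), xyz)
    else
        .applyPiecewise(xyz, solve(.BRETT_UP), solve(.BRETT_DOWN))
}

#' @rdname talToMni
#' @export
mniToTal <- function(xyz, method = c("lacadie", "brett")) {
    method <- match.arg(method)
    if (method == "lacadie")
        .applyAffine(.LACADIE_MNI2TAL, xyz)
    else
        .applyPiecewise(xyz, .BRETT_UP, .BRETT_DOWN)
}

.applyPiecewise <- function(xyz, up, down) {
    one <- function(p) {
        m <- if (p[3] >= 0) up else down
        as.vector(m %*% p)
    }
    if (is.matrix(xyz)) t(apply(xyz, 1L, one)) else one(xyz)
}

#' Normalise a foci table to MNI space
#'
#' Applies \code{\link{talToMni}} to every Talairach-tagged focus; MNI rows
#' are untouched. Idempotent: a second call changes nothing. The number of
#' converted rows is reported via \code{message}.
#'
#' @param table a \linkS4class{StudyFociTable}.
#' @param method transform passed to \code{\link{talToMni}}.
#' @return a \linkS4class{StudyFociTable} with all entries in MNI space.
#' @export
normalizeToMni <- function(table, method = c("lacadie", "brett")) {
    method <- match.arg(method)
    e <- table@entries
    isTal <- e$space == "TAL"
    if (any(isTal)) {
        xyz <- as.matrix(e[isTal, c("x", "y", "z")])
        mni <- talToMni(xyz, method = method)
        e[isTal, c("x", "y", "z")] <- mni
        e$space[isTal] <- "MNI"
    }
    message(sum(isTal), " focus/foci converted TAL -> MNI (", method, ")")
    StudyFociTable(e)
}
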