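#' @include AllClasses.R
NULL

## Canonical JSON snapshot of a config (stable key order), and its md5 hash
## via a temporary file (tools::md5sum hashes files, which is all we need).

configSnapshot <- function(config) {
    sl <- slotNames(class(config))
    out <- lapply(sl, function(s) slot(config, s))
    names(out) <- sl
    out[order(names(out))]
}

configHash <- function(config) {
    js <- jsonlite::toJSON(configSnapshot(config), auto_unbox = TRUE,
                           digits = NA)
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf))
    writeLines(as.character(js), tf)
    unname(tools::md5sum(tf))
}

fileHashes <- function(paths) {
    ex <- paths[file.exists(paths)]
    if (length(ex) == 0L) return(list())
    h <- tools::md5sum(ex)
    as.list(h)
}

writeManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}
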