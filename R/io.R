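# Serialization shared by the command-line tools: tidy CSV payloads with a
# JSON metadata sidecar, and a run manifest recording command, seed and
# outputs so deterministic runs are reproducible from the manifest alone.

#' Write a response field to CSV with a JSON sidecar
#'
#' The CSV holds columns `x`, `r_E`, `r_I`; the sidecar `<path>.meta.json`
#' records the solver settings and parameter provenance.
#'
#' @param r An `nw_response_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_field <- function(r, path) {
  stopifnot(inherits(r, "nw_response_field"))
  if (is.matrix(r$r_E))
    stop("time-resolved fields are not supported by the CSV writer; ",
         "extract a single time slice first")
  utils::write.csv(data.frame(x = r$grid, r_E = r$r_E, r_I = r$r_I),
                   path, row.names = FALSE)
  meta <- r$meta
  meta$params <- unclass_plain(meta$params)
  meta$stimulus <- unclass_plain(meta$stimulus)
  meta$wave <- unclass_plain(meta$wave)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(path)
}

unclass_plain <- function(x) {
  if (is.null(x)) return(NULL)
  x <- unclass(x)
  x[vapply(x, function(el) is.atomic(el) || is.null(el), logical(1))]
}

#' Read a response field written by [write_response_field()]
#'
#' @param path CSV path.
#' @return An `nw_response_field` (metadata restored from the sidecar when
#'   present).
#' @export
read_response_field <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x", "r_E", "r_I") %in% names(d)))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  new_response_field(d$x, d$r_E, d$r_I, meta)
}

# Run manifest: one per CLI invocation.
write_manifest <- function(out_dir, command, args, seed, outputs) {
  manifest <- list(
    command = command,
    args = args,
    seed = seed,
    package = "neuralwave",
    version = as.character(utils::packageVersion("neuralwave")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
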