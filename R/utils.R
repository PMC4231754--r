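#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every generator is a pure function of (config, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Write a dataset with its generator-truth sidecar
#'
#' Writes the long-format data as CSV and the `truth` attribute (generator
#' ground truth: seeds, rates, per-variant expectations) as a JSON sidecar
#' next to it.
#'
#' @param data a data.frame carrying a `truth` attribute.
#' @param path CSV path; the sidecar is written to `<path>_truth.json` with
#'   the `.csv` extension stripped.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    side <- paste0(sub("\\.csv$", "", path), "_truth.json")
    jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
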