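#' Read and write photon tables as CSV
#'
#' The on-disk dialect is a plain CSV with columns `time_s`, `channel`,
#' `excitation`, and optional `delay_ns` — one row per photon, sorted
#' by time.
#'
#' @param file Path.
#' @return `read_photons()` returns a validated photon tibble;
#'   `write_photons()` returns `file` invisibly.
#' @export
read_photons <- function(file) {
  validate_photons(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_photons
#' @param photons A photon table.
#' @export
write_photons <- function(photons, file) {
  utils::write.csv(validate_photons(photons), file, row.names = FALSE)
  invisible(file)
}

#' Read and write titration series as CSV
#'
#' Columns: `conc_m`, `state`, `fraction`, optional `sd`.
#'
#' @param file Path.
#' @export
read_titration <- function(file) {
  out <- as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
  req <- c("conc_m", "state", "fraction")
  if (!all(req %in% names(out))) {
    abort("titration CSV needs columns conc_m, state, fraction.")
  }
  out
}

#' @rdname read_titration
#' @param series A titration tibble.
#' @export
write_titration <- function(series, file) {
  utils::write.csv(series, file, row.names = FALSE)
  invisible(file)
}

#' Serialise a Markov model bundle to and from JSON
#'
#' @param msm A [markov_model()].
#' @param file Path.
#' @export
write_markov_model <- function(msm, file) {
  stopifnot(inherits(msm, "markov_model"))
  jsonlite::write_json(
    list(t_matrix = msm$t_matrix, lag_ns = msm$lag_ns,
         rescale = msm$rescale, populations = msm$populations,
         distances = msm$distances, efficiencies = msm$efficiencies),
    file, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(file)
}

#' @rdname write_markov_model
#' @export
read_markov_model <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  markov_model(x$t_matrix, lag_ns = x$lag_ns, rescale = x$rescale,
               distances = x$distances, efficiencies = x$efficiencies,
               populations = x$populations)
}

#' Serialise a distance model to and from JSON
#'
#' @param model A [distance_model()].
#' @param file Path.
#' @export
write_distance_model <- function(model, file) {
  stopifnot(inherits(model, "distance_model"))
  jsonlite::write_json(unclass(model), file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_distance_model
#' @export
read_distance_model <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(distance_model, x)
}
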