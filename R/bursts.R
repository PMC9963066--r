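#' Validate a photon-record table
#'
#' Photon streams are plain tables with one row per detected photon:
#' `time_s` (arrival time, seconds, non-decreasing), `channel`
#' (`"donor"` or `"acceptor"`), `excitation` (`"donor_pulse"` or
#' `"acceptor_pulse"`, from pulsed interleaved excitation), and an
#' optional `delay_ns` (time since the excitation pulse, for lifetime
#' work).
#'
#' @param photons A data frame of photon records.
#' @return The validated tibble, invisibly usable downstream.
#' @export
validate_photons <- function(photons) {
  photons <- as_tibble(photons)
  req <- c("time_s", "channel", "excitation")
  missing <- setdiff(req, names(photons))
  if (length(missing)) {
    abort(paste0("photon table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(photons) && is.unsorted(photons$time_s)) {
    abort("photon times must be non-decreasing: malformed stream.")
  }
  if (nrow(photons) && any(photons$time_s < 0)) abort("photon times must be >= 0.")
  if (!all(photons$channel %in% c("donor", "acceptor"))) {
    abort("`channel` must be 'donor' or 'acceptor'.")
  }
  if (!all(photons$excitation %in% c("donor_pulse", "acceptor_pulse"))) {
    abort("`excitation` must be 'donor_pulse' or 'acceptor_pulse'.")
  }
  if ("delay_ns" %in% names(photons) &&
      any(photons$delay_ns < 0, na.rm = TRUE)) {
    abort("`delay_ns` must be >= 0 where present.")
  }
  photons
}

#' Detect photon bursts in a time-sorted stream
#'
#' All-photon sliding criterion: photons separated by an inter-photon
#' gap larger than `max_gap_s` never share a burst, and a candidate
#' cluster is kept only if it contains at least `threshold`
#' donor-excitation photons (the counts that enter the transfer
#' efficiency). Acceptor-excitation photons ride along for the
#' stoichiometry ratio.
#'
#' @param photons A photon table (see [validate_photons()]).
#' @param threshold Minimum number of donor-excitation photons per burst
#'   (default 50).
#' @param max_gap_s Maximum inter-photon gap within a burst, seconds
#'   (default 100 microseconds).
#' @return A tibble of bursts: `burst_id`, `start_s`, `stop_s`,
#'   `n_d` (donor-excited donor counts), `n_a` (donor-excited acceptor),
#'   `n_aa` (acceptor-excited acceptor), `n_photons`, and `mean_delay_ns`
#'   (NA when the stream carries no delays).
#' @examples
#' sim <- make_burst_dataset(
#'   tibble::tibble(mean_e = 0.5, weight = 1), n_bursts = 20, seed = 1)
#' detect_bursts(sim$photons)
#' @export
detect_bursts <- function(photons, threshold = 50, max_gap_s = 100e-6) {
  photons <- validate_photons(photons)
  if (!nrow(photons)) {
    return(tibble(burst_id = integer(), start_s = numeric(), stop_s = numeric(),
                  n_d = integer(), n_a = integer(), n_aa = integer(),
                  n_photons = integer(), mean_delay_ns = numeric()))
  }
  cluster <- cumsum(c(0, diff(photons$time_s) > max_gap_s))
  has_delay <- "delay_ns" %in% names(photons)
  photons$.cluster <- cluster
  de <- photons$excitation == "donor_pulse"
  out <- photons |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      start_s = min(.data$time_s), stop_s = max(.data$time_s),
      n_d = sum(.data$excitation == "donor_pulse" & .data$channel == "donor"),
      n_a = sum(.data$excitation == "donor_pulse" & .data$channel == "acceptor"),
      n_aa = sum(.data$excitation == "acceptor_pulse" & .data$channel == "acceptor"),
      n_photons = dplyr::n(),
      mean_delay_ns = if (has_delay) {
        mean(.data$delay_ns[.data$excitation == "donor_pulse" &
                              .data$channel == "donor"], na.rm = TRUE)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_d + .data$n_a >= threshold) |>
    dplyr::mutate(burst_id = dplyr::row_number(), .before = 1) |>
    dplyr::select(-".cluster")
  out
}

#' Corrected transfer efficiency and stoichiometry per burst
#'
#' Applies, in order: background subtraction (per-channel rate times the
#' burst duration), donor-to-acceptor crosstalk, acceptor direct
#' excitation (proportional to the acceptor-excitation counts), and the
#' gamma detection correction:
#' `E = nA' / (nA' + gamma * nD')`. With the neutral default setup the
#' formula reduces to the raw proximity ratio `nA / (nA + nD)`.
#' Efficiencies are clipped to the reporting range `[-0.1, 1.1]`, which
#' accommodates background over-subtraction. The stoichiometry ratio
#' `S = (nD + nA) / (nD + nA + nAA)` uses raw counts; donor-only
#' molecules sit at S ~ 1, acceptor-only species near 0, and 1:1
#' labelled molecules near 0.5.
#'
#' @param bursts A burst table from [detect_bursts()].
#' @param setup A [fret_setup()].
#' @return The burst tibble with columns `e` and `s` appended. Bursts
#'   with zero donor-excitation photons are dropped (E undefined) with a
#'   warning.
#' @examples
#' b <- tibble::tibble(burst_id = 1, start_s = 0, stop_s = 1e-3,
#'                     n_d = 50, n_a = 50, n_aa = 40)
#' burst_metrics(b, fret_setup())   # e = 0.5
#' @export
burst_metrics <- function(bursts, setup = fret_setup()) {
  setup <- as_fret_setup(setup)
  bursts <- as_tibble(bursts)
  bad <- bursts$n_d + bursts$n_a <= 0
  if (any(bad)) {
    warn(sprintf("%d burst(s) with zero donor-excitation photons rejected.", sum(bad)))
    bursts <- bursts[!bad, ]
  }
  dur <- bursts$stop_s - bursts$start_s
  nd_c <- bursts$n_d - setup$bg_donor * dur
  na_c <- bursts$n_a - setup$bg_acceptor * dur -
    setup$crosstalk * nd_c - setup$direct_excitation * bursts$n_aa
  e <- na_c / (na_c + setup$gamma * nd_c)
  tot <- bursts$n_d + bursts$n_a + bursts$n_aa
  bursts |>
    dplyr::mutate(
      e = pmin(pmax(e, -0.1), 1.1),
      s = ifelse(tot > 0, (bursts$n_d + bursts$n_a) / tot, NA_real_)
    )
}

#' Build a transfer-efficiency histogram from selected bursts
#'
#' Filters bursts to a stoichiometry window (default `[0.3, 0.7]`, which
#' removes donor-only and acceptor-only molecules) and bins their
#' corrected efficiencies. Histogram mass always equals the number of
#' retained bursts.
#'
#' @param bursts A burst table; `e`/`s` columns are computed via
#'   [burst_metrics()] if absent.
#' @param setup A [fret_setup()], used when metrics must be computed.
#' @param s_window Stoichiometry acceptance window, length-2 numeric.
#'   Use `c(0, 1)` to disable filtering.
#' @param bins Number of bins (default 50).
#' @param range Efficiency range covered by the bins (default the
#'   reporting range `[-0.1, 1.1]`).
#' @return An `e_histogram` object: `bin_edges`, `counts`, `n_bursts`,
#'   `mean_burst_size` (mean donor-excitation photons of retained
#'   bursts, used as the shot-noise scale by [fit_mixture()]), and the
#'   retained burst table.
#' @examples
#' sim <- make_burst_dataset(
#'   tibble::tibble(mean_e = c(0.3, 0.8), weight = c(0.6, 0.4)),
#'   n_bursts = 300, seed = 2)
#' h <- sim$photons |> detect_bursts() |> build_histogram()
#' h
#' @export
build_histogram <- function(bursts, setup = fret_setup(),
                            s_window = c(0.3, 0.7), bins = 50,
                            range = c(-0.1, 1.1)) {
  stopifnot(length(s_window) == 2, s_window[1] <= s_window[2],
            length(range) == 2, range[1] < range[2], bins >= 1)
  bursts <- as_tibble(bursts)
  if (!all(c("e", "s") %in% names(bursts))) {
    bursts <- burst_metrics(bursts, setup)
  }
  keep <- bursts |>
    dplyr::filter(.data$s >= s_window[1], .data$s <= s_window[2])
  edges <- seq(range[1], range[2], length.out = bins + 1)
  counts <- if (nrow(keep)) {
    e_clip <- pmin(pmax(keep$e, range[1]), range[2])
    tabulate(findInterval(e_clip, edges, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = bins)
  } else integer(bins)
  structure(
    list(bin_edges = edges, counts = counts, n_bursts = nrow(keep),
         mean_burst_size = if (nrow(keep)) mean(keep$n_d + keep$n_a) else NA_real_,
         s_window = s_window, bursts = keep),
    class = "e_histogram"
  )
}

#' @export
print.e_histogram <- function(x, ...) {
  cat(sprintf("<e_histogram> %d bursts in %d bins on [%.2f, %.2f]",
              x$n_bursts, length(x$counts), min(x$bin_edges), max(x$bin_edges)))
  if (x$n_bursts == 0) cat("  [empty: no bursts retained]")
  cat("\n")
  invisible(x)
}

#' @rdname build_histogram
#' @param x An `e_histogram`.
#' @param ... Unused.
#' @export
tidy.e_histogram <- function(x, ...) {
  width <- diff(x$bin_edges)
  tibble(
    bin_mid = (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2,
    count = x$counts,
    density = if (x$n_bursts > 0) x$counts / (x$n_bursts * width) else 0
  )
}

#' @rdname build_histogram
#' @param object An `e_histogram`.
#' @export
autoplot.e_histogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_edges)[1], fill = "grey60") +
    ggplot2::labs(x = "transfer efficiency", y = "bursts") +
    ggplot2::theme_minimal()
}

#' Burst variance analysis
#'
#' Splits each burst's donor-excitation photon sequence into
#' consecutive windows of `window_photons` photons, computes the
#' efficiency of each window, and compares the across-window standard
#' deviation with the binomial shot-noise expectation
#' `sqrt(E (1 - E) / window_photons)`. Bursts whose windowed spread
#' exceeds the shot-noise envelope carry conformational dynamics on the
#' burst (millisecond) timescale; static conformations stay inside it.
#'
#' @param photons The photon stream the bursts came from.
#' @param bursts Burst table from [detect_bursts()] on that stream.
#' @param window_photons Photons per window (default 10).
#' @return A tibble with one row per analysed burst: `burst_id`, `e`
#'   (burst proximity ratio), `sd_e` (across-window standard deviation),
#'   `n_windows`, and `expected_sd` (the shot-noise envelope at the
#'   burst's E). Bursts with fewer than 2 complete windows are skipped;
#'   the number skipped is attached as attribute `n_skipped`.
#' @examples
#' sim <- make_burst_dataset(
#'   tibble::tibble(mean_e = 0.5, weight = 1), n_bursts = 50, seed = 3)
#' b <- detect_bursts(sim$photons)
#' bva <- burst_variance_analysis(sim$photons, b)
#' attr(bva, "n_skipped")
#' @export
burst_variance_analysis <- function(photons, bursts, window_photons = 10) {
  photons <- validate_photons(photons)
  stopifnot(window_photons >= 2)
  de <- photons[photons$excitation == "donor_pulse", ]
  res <- purrr::map_dfr(seq_len(nrow(bursts)), function(i) {
    b <- bursts[i, ]
    acc <- de$channel[de$time_s >= b$start_s & de$time_s <= b$stop_s] == "acceptor"
    n_win <- length(acc) %/% window_photons
    if (n_win < 2) return(NULL)
    acc <- acc[seq_len(n_win * window_photons)]
    win_e <- colMeans(matrix(acc, nrow = window_photons))
    e_burst <- mean(acc)
    tibble(burst_id = b$burst_id, e = e_burst, sd_e = sd(win_e),
           n_windows = n_win,
           expected_sd = sqrt(e_burst * (1 - e_burst) / window_photons))
  })
  if (is.null(res) || !nrow(res)) {
    res <- tibble(burst_id = integer(), e = numeric(), sd_e = numeric(),
                  n_windows = integer(), expected_sd = numeric())
  }
  attr(res, "n_skipped") <- nrow(bursts) - nrow(res)
  attr(res, "window_photons") <- window_photons
  res
}

#' @rdname burst_variance_analysis
#' @param bva A burst-variance table from [burst_variance_analysis()].
#' @export
plot_bva <- function(bva) {
  grid <- tibble(e = seq(0.001, 0.999, length.out = 200))
  wp <- attr(bva, "window_photons") %||% 10
  grid$envelope <- sqrt(grid$e * (1 - grid$e) / wp)
  ggplot2::ggplot(bva, ggplot2::aes(x = .data$e, y = .data$sd_e)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$envelope),
                       colour = "red") +
    ggplot2::labs(x = "burst transfer efficiency", y = "windowed SD of E") +
    ggplot2::theme_minimal()
}
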