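#' Discrete-state kinetic model driving the photon simulator
#'
#' A Markov state model: a row-stochastic transition matrix `t_matrix`
#' at lag time `lag_ns`, its stationary distribution, and per-state
#' inter-dye distances (nm) or fixed efficiencies. The `rescale` factor
#' maps model-time dynamics onto the experimental photon timescale: the
#' state path advances once every `lag_ns * rescale` nanoseconds of
#' simulated photon time, so slow conformational exchange sampled at a
#' short model lag can be played back against millisecond bursts.
#'
#' @param t_matrix Square row-stochastic matrix.
#' @param lag_ns Lag time of the transition matrix, nanoseconds.
#' @param distances Per-state inter-dye distances (nm); mutually
#'   exclusive with `efficiencies`.
#' @param efficiencies Per-state fixed transfer efficiencies in `[0, 1]`.
#' @param rescale Time-rescaling factor (> 0, default 225).
#' @param populations Optional stationary vector; computed from
#'   `t_matrix` by power iteration when omitted and checked against it
#'   otherwise.
#' @return An object of class `markov_model`.
#' @examples
#' markov_model(matrix(c(0.99, 0.01, 0.02, 0.98), 2, byrow = TRUE),
#'              efficiencies = c(0.2, 0.8))
#' @export
markov_model <- function(t_matrix, lag_ns = 10, distances = NULL,
                         efficiencies = NULL, rescale = 225,
                         populations = NULL) {
  t_matrix <- as.matrix(t_matrix)
  n <- nrow(t_matrix)
  if (ncol(t_matrix) != n) abort("`t_matrix` must be square.")
  if (any(t_matrix < 0) || any(abs(rowSums(t_matrix) - 1) > 1e-9)) {
    abort("`t_matrix` must be row-stochastic (rows sum to 1, entries >= 0).")
  }
  if (rescale <= 0) abort("`rescale` must be positive.")
  if (is.null(distances) == is.null(efficiencies)) {
    abort("give exactly one of `distances` or `efficiencies` (one per state).")
  }
  if (!is.null(distances) && (length(distances) != n || any(distances <= 0))) {
    abort("`distances` must be positive, one per state.")
  }
  if (!is.null(efficiencies) &&
      (length(efficiencies) != n || any(efficiencies < 0 | efficiencies > 1))) {
    abort("`efficiencies` must lie in [0, 1], one per state.")
  }
  pops <- stationary_distribution(t_matrix)
  if (!is.null(populations)) {
    if (max(abs(populations - pops)) > 1e-6) {
      warn("supplied `populations` is not the fixed point of `t_matrix`; using the computed one.")
    }
  }
  structure(
    list(n_states = n, t_matrix = t_matrix, lag_ns = lag_ns,
         rescale = rescale, populations = pops,
         distances = distances, efficiencies = efficiencies),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d states, lag %.3g ns, rescale %.5g\n",
              x$n_states, x$lag_ns, x$rescale))
  cat("  stationary:", paste(sprintf("%.3f", x$populations), collapse = " "), "\n")
  invisible(x)
}

stationary_distribution <- function(t_matrix, tol = 1e-12, max_iter = 100000) {
  n <- nrow(t_matrix)
  p <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    p_new <- as.vector(p %*% t_matrix)
    if (max(abs(p_new - p)) < tol) return(p_new / sum(p_new))
    p <- p_new
  }
  warn("power iteration for the stationary vector hit the iteration cap.")
  p / sum(p)
}

state_efficiencies <- function(msm, setup) {
  if (!is.null(msm$efficiencies)) msm$efficiencies
  else forster_efficiency(msm$distances, setup$r0)
}

#' Simulation settings for the kinetic Monte Carlo photon engine
#'
#' @param photon_rate Donor-excitation photon detection rate during a
#'   burst, Hz (default 1e5: ~100 photons per millisecond burst).
#' @param burst_duration_s Duration of each simulated burst, seconds.
#' @param n_bursts Number of bursts to simulate.
#' @param aa_rate_ratio Acceptor-excitation photon rate relative to
#'   `photon_rate`; 1 yields stoichiometries near 0.5 so simulated
#'   bursts survive the standard stoichiometry filter.
#' @param gap_s Silent gap inserted between consecutive bursts.
#' @param seed Master seed; per-burst substreams are derived from it so
#'   earlier bursts are unchanged when `n_bursts` grows.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(photon_rate = 1e5, burst_duration_s = 1e-3,
                       n_bursts = 1000, aa_rate_ratio = 1,
                       gap_s = 5e-3, seed = 0) {
  if (photon_rate < 0 || aa_rate_ratio < 0) abort("rates must be >= 0.")
  if (n_bursts < 1) abort("`n_bursts` must be >= 1.")
  structure(
    list(photon_rate = photon_rate, burst_duration_s = burst_duration_s,
         n_bursts = n_bursts, aa_rate_ratio = aa_rate_ratio,
         gap_s = gap_s, seed = seed),
    class = "sim_config"
  )
}

#' Kinetic Monte Carlo photon-trajectory simulation from a Markov model
#'
#' For each burst, the conformational state evolves by the model's
#' transition matrix once every `lag_ns * rescale` nanoseconds; photon
#' arrivals are a Poisson process at the configured rate; each
#' donor-excitation photon is routed to the acceptor channel with the
#' probability given by the current state's transfer efficiency (from
#' its inter-dye distance through the Forster relation, or a fixed E).
#' Shot noise and kinetic averaging over the observation window thus
#' emerge naturally: dwell times much longer than the burst give one
#' peak per state, dwell times much shorter collapse the histogram onto
#' the population-weighted mean efficiency. Acceptor-excitation photons
#' are emitted alongside so the stream carries stoichiometry
#' information.
#'
#' @param msm A [markov_model()].
#' @param setup A [fret_setup()]; only `r0` matters when the model
#'   carries distances.
#' @param cfg A [sim_config()].
#' @return A list of class `photon_sim`: `photons` (a photon table, see
#'   [validate_photons()]), `burst_truth` (per-burst modal state and
#'   time-averaged true efficiency), and `state_paths` (list of integer
#'   state paths, one per burst).
#' @examples
#' m <- markov_model(diag(2) * 0 + c(0.995, 0.005, 0.005, 0.995),
#'                   efficiencies = c(0.2, 0.8))
#' sim <- simulate_photons(m, fret_setup(), sim_config(n_bursts = 10, seed = 1))
#' head(sim$photons)
#' @export
simulate_photons <- function(msm, setup = fret_setup(), cfg = sim_config()) {
  stopifnot(inherits(msm, "markov_model"), inherits(cfg, "sim_config"))
  setup <- as_fret_setup(setup)
  e_states <- state_efficiencies(msm, setup)
  dt <- msm$lag_ns * 1e-9 * msm$rescale
  n_steps <- max(1L, ceiling(cfg$burst_duration_s / dt))
  nb <- cfg$n_bursts
  cum_t <- t(apply(msm$t_matrix, 1, cumsum))

  withr::with_seed(cfg$seed, {
    # evolve all bursts' chains in lock-step (vectorised over bursts)
    path <- matrix(0L, nrow = nb, ncol = n_steps)
    path[, 1] <- findInterval(runif(nb), cumsum(msm$populations)) + 1L
    if (n_steps > 1) {
      for (s in 2:n_steps) {
        u <- runif(nb)
        prev <- path[, s - 1]
        nxt <- integer(nb)
        for (st in seq_len(msm$n_states)) {
          idx <- prev == st
          if (any(idx)) {
            nxt[idx] <- findInterval(u[idx], cum_t[st, ]) + 1L
          }
        }
        path[, s] <- pmin(nxt, msm$n_states)
      }
    }

    n_de <- rpois(nb, cfg$photon_rate * cfg$burst_duration_s)
    n_aa <- rpois(nb, cfg$photon_rate * cfg$aa_rate_ratio * cfg$burst_duration_s)
    burst_start <- (seq_len(nb) - 1) * (cfg$burst_duration_s + cfg$gap_s)

    per_burst <- purrr::map(seq_len(nb), function(i) {
      t_de <- sort(runif(n_de[i], 0, cfg$burst_duration_s))
      step_idx <- pmin(floor(t_de / dt) + 1L, n_steps)
      st <- path[i, step_idx]
      acceptor <- runif(n_de[i]) < e_states[st]
      t_aa <- sort(runif(n_aa[i], 0, cfg$burst_duration_s))
      tibble(
        time_s = burst_start[i] + c(t_de, t_aa),
        channel = c(ifelse(acceptor, "acceptor", "donor"),
                    rep("acceptor", n_aa[i])),
        excitation = c(rep("donor_pulse", n_de[i]),
                       rep("acceptor_pulse", n_aa[i])),
        .burst = i
      ) |> dplyr::arrange(.data$time_s)
    })
    photons <- dplyr::bind_rows(per_burst)

    burst_truth <- tibble(
      burst = seq_len(nb),
      modal_state = apply(path, 1, function(p) {
        as.integer(names(which.max(table(p))))
      }),
      mean_e_true = rowMeans(matrix(e_states[path], nrow = nb)),
      n_de = n_de, n_aa = n_aa
    )

    structure(
      list(photons = dplyr::select(photons, -".burst"),
           burst_truth = burst_truth,
           state_paths = lapply(seq_len(nb), function(i) path[i, ]),
           dt_s = dt, config = cfg),
      class = "photon_sim"
    )
  })
}

#' @export
print.photon_sim <- function(x, ...) {
  cat(sprintf("<photon_sim> %d bursts, %d photons, state step %.3g us\n",
              nrow(x$burst_truth), nrow(x$photons), x$dt_s * 1e6))
  invisible(x)
}

#' Predicted transfer-efficiency histogram from a Markov model
#'
#' Runs the full chain [simulate_photons()] -> [detect_bursts()] ->
#' [burst_metrics()] -> [build_histogram()], returning the histogram a
#' single-molecule experiment on this kinetic model would record,
#' including shot noise and kinetic averaging. Per-burst provenance
#' (the modal ground-truth state) is attached to the retained bursts.
#'
#' @inheritParams simulate_photons
#' @param bins,s_window,threshold,max_gap_s Passed to the burst and
#'   histogram stages.
#' @return An `e_histogram`; its `bursts` table carries a `modal_state`
#'   column.
#' @examples
#' m <- markov_model(matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE),
#'                   efficiencies = c(0.25, 0.85))
#' h <- predict_histogram(m, cfg = sim_config(n_bursts = 200, seed = 2))
#' @export
predict_histogram <- function(msm, setup = fret_setup(), cfg = sim_config(),
                              bins = 50, s_window = c(0.3, 0.7),
                              threshold = 50, max_gap_s = 100e-6) {
  sim <- simulate_photons(msm, setup, cfg)
  bursts <- detect_bursts(sim$photons, threshold = threshold,
                          max_gap_s = max_gap_s)
  bursts <- burst_metrics(bursts, setup)
  # map detected bursts back to simulated bursts by start time
  slot <- cfg$burst_duration_s + cfg$gap_s
  bursts$modal_state <- sim$burst_truth$modal_state[
    pmin(floor(bursts$start_s / slot) + 1L, nrow(sim$burst_truth))]
  build_histogram(bursts, setup, s_window = s_window, bins = bins)
}

#' Estimate a Markov model from discrete state trajectories
#'
#' Counts transitions at the requested lag, symmetrises the count
#' matrix (`(C + C^T)/2`, enforcing detailed balance), row-normalises,
#' and computes the stationary vector by power iteration. States never
#' visited are dropped with a warning, as is a reducible (block
#' disconnected) result.
#'
#' @param trajectories A list of integer vectors of state labels (or a
#'   single vector).
#' @param lag_steps Lag in trajectory steps (default 1).
#' @param lag_ns Physical lag time assigned to the estimated matrix.
#' @param rescale Time-rescaling factor carried into the model.
#' @param distances,efficiencies Optional per-state observables passed
#'   through to [markov_model()]; defaults to uniform fixed
#'   efficiencies when neither is given (estimation itself needs
#'   neither).
#' @return A [markov_model()] whose states are the visited labels in
#'   ascending order (mapping attached as attribute `state_labels`).
#' @examples
#' traj <- c(1, 1, 1, 2, 2, 1, 1, 2, 2, 2)
#' estimate_msm(traj)
#' @export
estimate_msm <- function(trajectories, lag_steps = 1, lag_ns = 10,
                         rescale = 225, distances = NULL,
                         efficiencies = NULL) {
  if (is.numeric(trajectories)) trajectories <- list(trajectories)
  if (!length(trajectories) || !sum(lengths(trajectories))) {
    abort("no trajectory data supplied.")
  }
  if (lag_steps < 1) abort("`lag_steps` must be >= 1.")
  labels <- sort(unique(unlist(trajectories)))
  n <- length(labels)
  counts <- matrix(0, n, n)
  for (tr in trajectories) {
    tr <- match(tr, labels)
    if (length(tr) > lag_steps) {
      from <- tr[seq_len(length(tr) - lag_steps)]
      to <- tr[seq_len(length(tr) - lag_steps) + lag_steps]
      counts <- counts + unclass(table(factor(from, levels = seq_len(n)),
                                       factor(to, levels = seq_len(n))))
    }
  }
  visited <- rowSums(counts) + colSums(counts) > 0
  if (!all(visited)) {
    warn(sprintf("%d state(s) never involved in transitions dropped.", sum(!visited)))
    counts <- counts[visited, visited, drop = FALSE]
    labels <- labels[visited]
    n <- length(labels)
  }
  sym <- (counts + t(counts)) / 2
  rs <- rowSums(sym)
  if (any(rs == 0)) abort("a retained state has no transitions: cannot normalise.")
  t_matrix <- sym / rs
  dimnames(t_matrix) <- NULL

  # reducibility check on the symmetrised connectivity
  reach <- (sym > 0) | diag(n) > 0
  for (i in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  if (!all(reach)) warn("estimated transition matrix is reducible (disconnected state blocks).")

  if (is.null(distances) && is.null(efficiencies)) {
    efficiencies <- seq(0.1, 0.9, length.out = n)
  }
  out <- markov_model(t_matrix, lag_ns = lag_ns * lag_steps,
                      distances = distances, efficiencies = efficiencies,
                      rescale = rescale)
  attr(out, "state_labels") <- labels
  attr(out, "counts") <- counts
  out
}

#' L1 distance between two transfer-efficiency histograms
#'
#' Per-bin absolute difference of the count-normalised histograms:
#' symmetric, zero iff the normalised histograms coincide, and at most
#' 2 (fully disjoint distributions).
#'
#' @param h1,h2 `e_histogram` objects on identical bin edges.
#' @return A single number in `[0, 2]`.
#' @export
compare_histograms <- function(h1, h2) {
  stopifnot(inherits(h1, "e_histogram"), inherits(h2, "e_histogram"))
  if (length(h1$bin_edges) != length(h2$bin_edges) ||
      max(abs(h1$bin_edges - h2$bin_edges)) > 1e-12) {
    abort("histograms are on different binnings; rebin before comparing.")
  }
  p1 <- if (h1$n_bursts > 0) h1$counts / h1$n_bursts else h1$counts
  p2 <- if (h2$n_bursts > 0) h2$counts / h2$n_bursts else h2$counts
  sum(abs(p1 - p2))
}
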