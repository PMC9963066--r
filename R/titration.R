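#' Linear free-energy (denaturant) model of folding states
#'
#' Each conformational state `s` has a free energy, relative to the
#' reference (unfolded) state, that depends linearly on denaturant
#' concentration `c`: `G_s(c) = dg0_s + m_s * c`, in units of RT.
#' Folded-stable states carry negative `dg0` (they lie below the
#' unfolded state at zero denaturant) and positive `m` (denaturant
#' destabilises them). The first state in `states` is the reference and
#' has `dg0 = m = 0` by construction.
#'
#' @param states Character vector of state names, reference first
#'   (e.g. `c("U", "I", "F")`).
#' @param dg0 Named numeric vector of zero-denaturant free energies (RT)
#'   for the non-reference states.
#' @param m Named numeric vector of denaturant m-values (RT per molar)
#'   for the non-reference states.
#' @return An object of class `thermo_model`.
#' @examples
#' # a three-state folding equilibrium: U <-> I <-> F
#' thermo_model(c("U", "I", "F"), dg0 = c(I = -5.6, F = -8.3),
#'              m = c(I = 3.0, F = 4.15))
#' @export
thermo_model <- function(states, dg0, m) {
  if (length(states) < 2) abort("a thermo_model needs at least two states.")
  if (anyDuplicated(states)) abort("state names must be unique.")
  non_ref <- states[-1]
  if (!setequal(names(dg0), non_ref) || !setequal(names(m), non_ref)) {
    abort("`dg0` and `m` must be named for exactly the non-reference states.")
  }
  structure(
    list(states = states,
         dg0 = c(setNames(0, states[1]), dg0[non_ref]),
         m = c(setNames(0, states[1]), m[non_ref])),
    class = "thermo_model"
  )
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("<thermo_model>", length(x$states), "states (RT units, reference =",
      x$states[1], ")\n")
  print(tibble(state = x$states, dg0 = unname(x$dg0), m = unname(x$m)))
  invisible(x)
}

fraction_matrix <- function(model, conc) {
  # Boltzmann weights exp(-G_s(c)); log-sum-exp for numerical safety
  g <- outer(conc, model$m, "*") + rep(model$dg0, each = length(conc))
  w <- exp(-(g - apply(g, 1, min)))
  w / rowSums(w)
}

#' Equilibrium state fractions versus denaturant concentration
#'
#' Boltzmann populations of the model's states,
#' `p_s(c) = exp(-G_s(c)) / sum_t exp(-G_t(c))`, at each requested
#' concentration.
#'
#' @param model A [thermo_model()].
#' @param conc Denaturant concentrations (molar), `>= 0`.
#' @return A tibble in long format: `conc_m`, `state`, `fraction`.
#'   Fractions sum to 1 at every concentration.
#' @examples
#' tm <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 2.524))
#' state_fractions(tm, c(0, 2.06, 5))
#' @export
state_fractions <- function(model, conc) {
  stopifnot(inherits(model, "thermo_model"))
  if (any(conc < 0)) abort("concentrations must be >= 0.")
  p <- fraction_matrix(model, conc)
  tibble(
    conc_m = rep(conc, times = length(model$states)),
    state = factor(rep(model$states, each = length(conc)), levels = model$states),
    fraction = as.vector(p)
  )
}

#' Transition midpoint between two states
#'
#' The denaturant concentration at which two states are equally
#' populated: the root of `dG0 + dm * c = 0` for the pair, i.e.
#' `c_half = -(dg0_b - dg0_a) / (m_b - m_a)`.
#'
#' @param model A [thermo_model()].
#' @param state_pair Character vector of two state names `c(a, b)`.
#' @return Midpoint concentration in molar.
#' @examples
#' tm <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 2.524))
#' midpoint(tm, c("U", "F"))   # 2.06 M
#' @export
midpoint <- function(model, state_pair) {
  stopifnot(inherits(model, "thermo_model"), length(state_pair) == 2)
  if (!all(state_pair %in% model$states)) abort("unknown state name in `state_pair`.")
  ddg0 <- model$dg0[state_pair[2]] - model$dg0[state_pair[1]]
  dm <- model$m[state_pair[2]] - model$m[state_pair[1]]
  if (abs(dm) < 1e-12) {
    if (abs(ddg0) < 1e-12) return(0)
    abort("the pair's free-energy gap does not depend on denaturant: no midpoint exists.")
  }
  c_half <- -ddg0 / dm
  if (c_half < 0) {
    warn("midpoint lies at negative concentration; the states never invert for c >= 0.")
  }
  unname(c_half)
}

#' Free-energy difference from a pair of population fractions
#'
#' Direct Boltzmann inversion `dG = -ln(p_b / p_a)` in RT units, the
#' model-free estimate of the free-energy gap between two coexisting
#' states from their observed fractions at one condition. Antisymmetric
#' under swapping the pair.
#'
#' @param p_a,p_b Population fractions, both `> 0`.
#' @return Free-energy difference `G_b - G_a` in RT.
#' @examples
#' delta_g_from_fractions(0.6, 0.4)   # 0.405 RT
#' @export
delta_g_from_fractions <- function(p_a, p_b) {
  if (any(p_a <= 0) || any(p_b <= 0)) {
    abort("zero or negative fraction: the free-energy difference is unbounded.")
  }
  -log(p_b / p_a)
}

#' Fit a linear free-energy model to a denaturant titration
#'
#' Weighted least squares on observed per-state population fractions
#' across denaturant concentrations, estimating `dg0` and `m` for every
#' non-reference state. Because fractions sum to 1 at each condition,
#' the reference state's rows are redundant and are excluded from the
#' objective (they would double-count information and understate the
#' parameter uncertainty). Parameter covariance comes from the inverse
#' observed information (Gauss-Newton Hessian of the chi-square);
#' percentile bootstrap intervals (residual resampling of fractions with
#' renormalisation) are available via `n_boot`.
#'
#' @param series A titration table: columns `conc_m`, `state`,
#'   `fraction`, optional `sd` (per-point uncertainty; defaults to
#'   equal weights).
#' @param states Character vector giving state order, reference first.
#'   Defaults to order of appearance.
#' @param n_boot Number of bootstrap resamples for percentile CIs
#'   (0 disables).
#' @param seed Seed for the bootstrap resampler.
#' @return An object of class `titration_fit` with elements `model`
#'   (the fitted [thermo_model()]), `estimates` (tidy parameter table
#'   with standard errors and 95% intervals), `midpoints`, `chisq`,
#'   and diagnostic flags. `tidy()` and `glance()` methods apply.
#' @examples
#' tm <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 2.524))
#' obs <- make_titration_dataset(tm, seq(0, 5, length.out = 12),
#'                               noise_sd = 0.02, seed = 1)
#' fit <- fit_titration(obs)
#' tidy(fit)
#' @export
fit_titration <- function(series, states = NULL, n_boot = 0, seed = 0) {
  series <- as_tibble(series)
  req <- c("conc_m", "state", "fraction")
  if (!all(req %in% names(series))) {
    abort("`series` needs columns conc_m, state, fraction (optional sd).")
  }
  if (is.null(states)) states <- unique(as.character(series$state))
  if (!all(series$state %in% states)) abort("`states` must cover every state in `series`.")
  n_states <- length(states)
  conc <- sort(unique(series$conc_m))
  n_par <- 2 * (n_states - 1)
  if (length(conc) < n_par + 2) {
    abort(sprintf("need at least %d distinct concentrations to fit %d parameters.",
                  n_par + 2, n_par))
  }

  wide <- series |>
    dplyr::mutate(state = as.character(.data$state)) |>
    dplyr::arrange(.data$conc_m)
  # per condition the fractions sum to 1, so the reference state's row is
  # determined by the others; including it would double-count information
  # and shrink the parameter covariance spuriously
  fit_rows <- wide[wide$state != states[1], ]
  if (!nrow(fit_rows)) abort("the series contains only the reference state.")
  sd_col <- if ("sd" %in% names(fit_rows)) pmax(fit_rows$sd, 1e-6) else rep(1, nrow(fit_rows))
  obs <- fit_rows$fraction
  w_state <- match(fit_rows$state, states)
  w_conc <- fit_rows$conc_m

  unpack <- function(par) {
    thermo_model(states,
                 dg0 = setNames(par[seq_len(n_states - 1)], states[-1]),
                 m = setNames(par[n_states - 1 + seq_len(n_states - 1)], states[-1]))
  }
  predict_frac <- function(par) {
    p <- fraction_matrix(unpack(par), w_conc)
    p[cbind(seq_along(w_conc), w_state)]
  }
  chisq_fn <- function(par) sum(((obs - predict_frac(par)) / sd_col)^2)

  # multi-start: the data-driven start plus generic folding-scale starts,
  # keeping the best basin — the log-ratio heuristic occasionally lands in
  # a degenerate basin where a state is expelled and its parameters run off
  start0 <- start_values_titration(wide, states)
  starts <- list(
    start0,
    c(rep(-3, n_states - 1), rep(2, n_states - 1)),
    start0 / 2
  )
  cands <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, chisq_fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
  })
  cands <- purrr::compact(cands)
  if (!length(cands)) abort("titration fit failed from every start.")
  # prefer finite-scale solutions (free energies beyond ~30 RT are a
  # degenerate state-expulsion basin) unless nothing else converged
  ok_scale <- purrr::map_lgl(cands, ~ max(abs(.x$par)) < 30)
  if (any(ok_scale)) cands <- cands[ok_scale]
  best <- cands[[which.min(purrr::map_dbl(cands, "value"))]]
  fit <- optim(best$par, chisq_fn, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    abort(sprintf("titration fit did not converge (optim code %d): %s",
                  fit$convergence, fit$message %||% "no message"))
  }

  covmat <- tryCatch(2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covmat)) rep(NA_real_, n_par) else sqrt(pmax(diag(covmat), 0))
  par_names <- c(paste0("dg0_", states[-1]), paste0("m_", states[-1]))
  model <- unpack(fit$par)

  boot <- NULL
  if (n_boot > 0) {
    boot <- withr::with_seed(seed, {
      resid_tbl <- obs - predict_frac(fit$par)
      replicate(n_boot, {
        idx <- sample(length(obs), replace = TRUE)
        obs_b <- pmin(pmax(predict_frac(fit$par) + resid_tbl[idx], 0), 1)
        fb <- tryCatch(
          optim(fit$par, function(par) sum(((obs_b - predict_frac(par)) / sd_col)^2),
                method = "BFGS", control = list(maxit = 300, reltol = 1e-10))$par,
          error = function(e) rep(NA_real_, n_par))
        fb
      })
    })
  }

  ci_lo <- fit$par - 1.96 * se
  ci_hi <- fit$par + 1.96 * se
  if (!is.null(boot)) {
    qs <- apply(boot, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    ci_lo <- qs[1, ]; ci_hi <- qs[2, ]
  }

  estimates <- tibble(
    term = par_names, estimate = unname(fit$par), std_error = se,
    conf_low = unname(ci_lo), conf_high = unname(ci_hi)
  )

  # transition midpoints vs the reference state, where they exist
  mids <- purrr::map_dbl(states[-1], function(s) {
    tryCatch(suppressWarnings(midpoint(model, c(states[1], s))),
             error = function(e) NA_real_)
  })
  midpoints <- tibble(transition = paste(states[1], states[-1], sep = "-"),
                      c_half_m = mids)

  # identifiability: a state never exceeding 10% anywhere is weakly constrained
  max_frac <- fraction_matrix(model, conc) |> apply(2, max)
  weak <- states[max_frac < 0.1]

  structure(
    list(model = model, estimates = estimates, midpoints = midpoints,
         chisq = fit$value, df = length(obs) - n_par,
         n_obs = length(obs), states = states, series = wide,
         covariance = covmat, bootstrap = boot,
         weakly_identified = weak, seed = seed),
    class = "titration_fit"
  )
}

start_values_titration <- function(wide, states) {
  n_states <- length(states)
  # crude starts: log-ratio of each state to the reference at low/high conc
  ref <- states[1]
  lo <- min(wide$conc_m); hi <- max(wide$conc_m)
  eps <- 1e-3
  frac_at <- function(s, c0) {
    rows <- wide[wide$state == s, ]
    if (nrow(rows) < 2) {
      # state absent from the table (e.g. reference dropped as redundant):
      # reconstruct it as the complement of the others per condition
      comp <- wide |>
        dplyr::group_by(.data$conc_m) |>
        dplyr::summarise(fraction = max(1 - sum(.data$fraction), eps),
                         .groups = "drop")
      rows <- comp
    }
    max(approx(rows$conc_m, rows$fraction, xout = c0, rule = 2)$y, eps)
  }
  dg0 <- m <- numeric(n_states - 1)
  for (k in seq_len(n_states - 1)) {
    s <- states[k + 1]
    g_lo <- -log(frac_at(s, lo) / frac_at(ref, lo))
    g_hi <- -log(frac_at(s, hi) / frac_at(ref, hi))
    m[k] <- (g_hi - g_lo) / max(hi - lo, eps)
    dg0[k] <- g_lo - m[k] * lo
  }
  c(dg0, m)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> %d states, %d points, chi-square %.3g on %d df\n",
              length(x$states), x$n_obs, x$chisq, x$df))
  print(x$estimates)
  if (length(x$weakly_identified)) {
    cat("  weakly identified state(s):", paste(x$weakly_identified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_titration
#' @param x A `titration_fit` object.
#' @param ... Unused.
#' @export
tidy.titration_fit <- function(x, ...) x$estimates

#' @rdname fit_titration
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(n_states = length(x$states), n_obs = x$n_obs,
         chisq = x$chisq, df = x$df,
         weakly_identified = paste(x$weakly_identified, collapse = ","))
}

#' @rdname fit_titration
#' @param object A `titration_fit` object.
#' @export
autoplot.titration_fit <- function(object, ...) {
  grid <- seq(min(object$series$conc_m), max(object$series$conc_m),
              length.out = 200)
  pred <- state_fractions(object$model, grid)
  obs <- object$series |> dplyr::mutate(state = factor(.data$state, levels = object$states))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$conc_m, y = .data$fraction,
                                    colour = .data$state)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "denaturant (M)", y = "population fraction",
                  colour = "state") +
    ggplot2::theme_minimal()
}
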