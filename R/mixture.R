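#' Decompose a transfer-efficiency histogram into Gaussian populations
#'
#' Maximum-likelihood mixture of `k` Gaussian peaks fitted to the binned
#' burst counts (Poisson likelihood per bin, each bin's expectation
#' being the retained-burst number times the mixture mass in the bin).
#' Peak widths are bounded below by the shot-noise width
#' `sqrt(E (1 - E) / n)` at the histogram's mean burst size `n`, so a
#' population can never be fitted sharper than photon-counting
#' statistics allow. Components are reported sorted by ascending mean
#' efficiency; standard errors come from the observed information
#' (inverse Hessian at the optimum).
#'
#' Optional equality constraints on means support analyses where the
#' same conformational state is tracked across conditions and its mean
#' efficiency is shared.
#'
#' @param h An `e_histogram` from [build_histogram()].
#' @param k Number of populations, `>= 1`.
#' @param fixed_means Optional numeric vector of length `k`; non-NA
#'   entries pin the corresponding (ascending) component mean.
#' @param mean_burst_size Override for the shot-noise scale; defaults to
#'   the histogram's own mean retained-burst size.
#' @param n_starts Number of random restarts (jittered quantile starts).
#' @param seed Seed for the restarts.
#' @return An object of class `mixture_fit` with a tidy component table
#'   (`mean`, `width`, `fraction`, standard errors), the log-likelihood,
#'   and diagnostic flags: `ill_conditioned` is `TRUE` when components
#'   collapse onto each other or a fraction vanishes, signalling that
#'   `k` exceeds the resolvable number of peaks.
#' @examples
#' sim <- make_burst_dataset(
#'   tibble::tibble(mean_e = c(0.3, 0.8), weight = c(0.6, 0.4)),
#'   n_bursts = 400, seed = 4)
#' h <- sim$photons |> detect_bursts() |> build_histogram()
#' fit <- fit_mixture(h, k = 2)
#' tidy(fit)
#' @export
fit_mixture <- function(h, k, fixed_means = NULL, mean_burst_size = NULL,
                        n_starts = 5, seed = 0) {
  stopifnot(inherits(h, "e_histogram"), k >= 1)
  if (h$n_bursts == 0) abort("cannot fit an empty histogram.")
  if (!is.null(fixed_means) && length(fixed_means) != k) {
    abort("`fixed_means` must have length `k` (use NA for free means).")
  }
  nbar <- mean_burst_size %||% h$mean_burst_size
  if (!is.finite(nbar) || nbar < 1) nbar <- 50
  edges <- h$bin_edges
  counts <- h$counts
  n <- h$n_bursts
  fixed <- fixed_means %||% rep(NA_real_, k)

  floor_width <- function(mu) {
    mu_c <- pmin(pmax(mu, 0.02), 0.98)
    sqrt(mu_c * (1 - mu_c) / nbar)
  }

  # parameter packing: free means, log width excess over the floor,
  # fraction logits (k-1)
  free_idx <- which(is.na(fixed))
  unpack <- function(par) {
    mu <- fixed
    n_free <- length(free_idx)
    if (n_free) mu[free_idx] <- par[seq_len(n_free)]
    lw <- par[n_free + seq_len(k)]
    sigma <- floor_width(mu) * (1 + exp(lw))
    logits <- c(par[n_free + k + seq_len(k - 1)], 0)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    list(mu = mu, sigma = sigma, w = w)
  }
  bin_mass <- function(mu, sigma, w) {
    # mixture probability mass per bin, renormalised to the histogram support
    per_comp <- vapply(seq_len(k), function(j) {
      p <- diff(pnorm(edges, mu[j], sigma[j]))
      tot <- pnorm(max(edges), mu[j], sigma[j]) - pnorm(min(edges), mu[j], sigma[j])
      if (tot < 1e-12) rep(0, length(p)) else p / tot
    }, numeric(length(edges) - 1))
    as.vector(per_comp %*% w)
  }
  nll <- function(par) {
    p <- unpack(par)
    lambda <- pmax(n * bin_mass(p$mu, p$sigma, p$w), 1e-12)
    -sum(counts * log(lambda) - lambda)
  }

  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  base_mu <- if (n > 0) {
    qs <- quantile(rep(mids, counts), probs = (seq_len(k) - 0.5) / k)
    as.numeric(qs)
  } else seq(0.2, 0.8, length.out = k)

  fits <- withr::with_seed(seed, {
    purrr::map(seq_len(n_starts), function(s) {
      mu0 <- sort(base_mu + if (s == 1) 0 else rnorm(k, 0, 0.08))
      par0 <- c(mu0[free_idx], rep(log(0.5), k), rep(0, k - 1))
      tryCatch(
        optim(par0, nll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-12)),
        error = function(e) NULL)
    })
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) abort("mixture fit failed to converge from any start.")
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  if (best$convergence != 0) {
    warn(sprintf("mixture optimiser reported convergence code %d.", best$convergence))
  }
  hess <- tryCatch(
    optim(best$par, nll, method = "BFGS", hessian = TRUE,
          control = list(maxit = 1)),
    error = function(e) NULL)
  covmat <- if (!is.null(hess)) {
    tryCatch(solve(hess$hessian), error = function(e) NULL)
  } else NULL

  p <- unpack(best$par)
  ord <- order(p$mu)
  mu <- p$mu[ord]; sigma <- p$sigma[ord]; w <- p$w[ord]

  # delta-method SEs for the free means only (widths/fractions reported
  # without propagation through the transform when the Hessian is singular)
  se_mu <- rep(NA_real_, k)
  if (!is.null(covmat)) {
    d <- sqrt(pmax(diag(covmat), 0))
    n_free <- length(free_idx)
    se_full <- rep(NA_real_, k)
    se_full[free_idx] <- d[seq_len(n_free)]
    se_mu <- se_full[ord]
  }

  min_sep <- if (k > 1) min(diff(mu)) else Inf
  ill <- any(w < 1e-3) || (k > 1 && min_sep < 0.5 * max(sigma))
  if (ill) {
    warn(paste0("mixture fit is ill-conditioned (vanishing fraction or ",
                "overlapping components): `k` likely exceeds the resolvable peaks."))
  }

  structure(
    list(
      components = tibble(
        component = seq_len(k), mean = mu, width = sigma, fraction = w,
        mean_se = se_mu
      ),
      k = k, loglik = -best$value, n_bursts = n,
      mean_burst_size = nbar, ill_conditioned = ill,
      histogram = h, fixed_means = fixed
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d on %d bursts, logLik %.2f%s\n",
              x$k, x$n_bursts, x$loglik,
              if (x$ill_conditioned) "  [ill-conditioned]" else ""))
  print(x$components)
  invisible(x)
}

#' @rdname fit_mixture
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) x$components

#' @rdname fit_mixture
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(k = x$k, n_bursts = x$n_bursts, loglik = x$loglik,
         mean_burst_size = x$mean_burst_size,
         ill_conditioned = x$ill_conditioned)
}

#' @rdname fit_mixture
#' @param object A `mixture_fit` object.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  h <- object$histogram
  df <- tidy(h)
  width <- diff(h$bin_edges)[1]
  grid <- seq(min(h$bin_edges), max(h$bin_edges), length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    row <- object$components[j, ]
    tibble(component = factor(j), e = grid,
           count = object$n_bursts * width * row$fraction *
             dnorm(grid, row$mean, row$width))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = width, fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$e, y = .data$count,
                                    colour = .data$component)) +
    ggplot2::labs(x = "transfer efficiency", y = "bursts") +
    ggplot2::theme_minimal()
}
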