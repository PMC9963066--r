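# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (linear scans, all-pairs loops, Riemann sums) so
# they share no code path with the implementation they check.

# linear scan burst search: split on gaps, then threshold on
# donor-excitation counts
oracle_bursts <- function(photons, threshold, max_gap_s) {
  if (!nrow(photons)) return(list())
  groups <- list()
  cur <- 1
  for (i in seq_len(nrow(photons))[-1]) {
    if (photons$time_s[i] - photons$time_s[i - 1] > max_gap_s) {
      groups <- c(groups, list(cur:(i - 1)))
      cur <- i
    }
  }
  groups <- c(groups, list(cur:nrow(photons)))
  keep <- Filter(function(g) {
    sum(photons$excitation[g] == "donor_pulse") >= threshold
  }, groups)
  keep
}

# all-pairs contact scan
oracle_contacts <- function(xyz, resno, cutoff, min_sep) {
  n <- nrow(xyz)
  out <- NULL
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    i <- min(resno[a], resno[b]); j <- max(resno[a], resno[b])
    if (d < cutoff && j - i >= min_sep) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) {
    return(tibble::tibble(res_i = integer(), res_j = integer()))
  }
  out <- tibble::tibble(res_i = out[, 1], res_j = out[, 2])
  dplyr::arrange(out, res_i, res_j)
}

# dense midpoint Riemann sum for a distribution-averaged efficiency
oracle_mean_e <- function(pdf, lower, upper, r0, n = 200000) {
  r <- seq(lower, upper, length.out = n + 1)
  mid <- (utils::head(r, -1) + utils::tail(r, -1)) / 2
  h <- diff(r)[1]
  p <- pdf(mid)
  z <- sum(p) * h
  sum(p * (1 / (1 + (mid / r0)^6))) * h / z
}

# brute-force Boltzmann populations for a linear free-energy model
oracle_fractions <- function(dg0, m, conc) {
  # dg0/m include the reference state's zeros
  w <- exp(-(dg0 + m * conc))
  w / sum(w)
}

make_frame_ensemble <- function(xyz, resno = seq_len(nrow(xyz))) {
  coords <- array(0, c(1, nrow(xyz), 3))
  coords[1, , ] <- xyz
  conformer_ensemble(coords, resno = resno)
}

toy_photon_cluster <- function(t0, n_donor, n_acceptor, n_aa = 0,
                               spacing = 1e-5) {
  n <- n_donor + n_acceptor + n_aa
  tibble::tibble(
    time_s = t0 + spacing * (seq_len(n) - 1),
    channel = c(rep("donor", n_donor), rep("acceptor", n_acceptor),
                rep("acceptor", n_aa)),
    excitation = c(rep("donor_pulse", n_donor + n_acceptor),
                   rep("acceptor_pulse", n_aa))
  )
}
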