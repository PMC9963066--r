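#' Generate a synthetic burst dataset with known ground truth
#'
#' Emulates a confocal single-molecule FRET measurement on a mixture of
#' conformational populations. Each burst draws a population by weight,
#' a size from a log-normal distribution (median 80 donor-excitation
#' photons — a realistic burst-size spread), and binomial
#' donor/acceptor counts at the population's mean efficiency (shot
#' noise). Populations may be given as fixed mean efficiencies or as
#' [distance_model()]s (whose distribution-averaged efficiency is
#' used). A configurable fraction of molecules is donor-only
#' (photobleached or unlabelled acceptor): they emit no
#' acceptor-excitation photons, so their stoichiometry sits near 1 and
#' the standard S filter removes them. Acceptor-excitation photons for
#' double-labelled molecules arrive at roughly the donor-excitation
#' rate, putting their stoichiometry near 0.5.
#'
#' @param populations A tibble with a `weight` column plus either
#'   `mean_e` or a list-column `model` of [distance_model()]s.
#' @param n_bursts Number of bursts (before burst-search losses).
#' @param setup A [fret_setup()] (its `r0` converts distance models to
#'   efficiencies).
#' @param donor_only_fraction Fraction of bursts from donor-only
#'   molecules.
#' @param size_meanlog,size_sdlog Log-normal burst-size parameters
#'   (defaults give median 80).
#' @param photon_rate Photon rate within a burst (Hz), setting burst
#'   durations.
#' @param gap_s Silent gap between bursts.
#' @param seed Seed (mandatory for reproducibility; default 0).
#' @return A list: `photons` (a photon table), `truth` (per-burst
#'   tibble: `burst`, `population` — `0` marks donor-only — `e_true`,
#'   `n_de`), and `populations` (the normalised input spec with the
#'   realised `mean_e`).
#' @examples
#' sim <- make_burst_dataset(
#'   tibble::tibble(mean_e = c(0.24, 0.59, 0.87),
#'                  weight = c(0.3, 0.5, 0.2)),
#'   n_bursts = 100, seed = 1)
#' table(sim$truth$population)
#' @export
make_burst_dataset <- function(populations, n_bursts = 1000,
                               setup = fret_setup(),
                               donor_only_fraction = 0,
                               size_meanlog = log(80), size_sdlog = 0.4,
                               photon_rate = 1e5, gap_s = 5e-3, seed = 0) {
  populations <- as_tibble(populations)
  if (!nrow(populations)) abort("at least one population is required.")
  if (!"weight" %in% names(populations)) abort("`populations` needs a weight column.")
  setup <- as_fret_setup(setup)
  if ("model" %in% names(populations)) {
    populations$mean_e <- purrr::map_dbl(populations$model,
                                         ~ mean_efficiency(.x, setup$r0)$mean_e)
  }
  if (!"mean_e" %in% names(populations)) {
    abort("`populations` needs `mean_e` or a `model` list-column.")
  }
  if (donor_only_fraction < 0 || donor_only_fraction >= 1) {
    abort("`donor_only_fraction` must be in [0, 1).")
  }
  populations$weight <- populations$weight / sum(populations$weight)

  withr::with_seed(seed, {
    pop_id <- sample(nrow(populations), n_bursts, replace = TRUE,
                     prob = populations$weight)
    donor_only <- runif(n_bursts) < donor_only_fraction
    pop_id[donor_only] <- 0L
    n_de <- pmax(2L, round(rlnorm(n_bursts, size_meanlog, size_sdlog)))
    e_true <- ifelse(donor_only, 0, populations$mean_e[pmax(pop_id, 1L)])
    n_a <- rbinom(n_bursts, n_de, e_true)
    n_d <- n_de - n_a
    n_aa <- ifelse(donor_only, 0L, rpois(n_bursts, n_de))

    duration <- n_de / photon_rate
    start <- cumsum(c(0, head(duration, -1) + gap_s))
    per_burst <- purrr::map(seq_len(n_bursts), function(i) {
      nd <- n_d[i]; na <- n_a[i]; naa <- n_aa[i]
      tot_de <- nd + na
      t_de <- sort(runif(tot_de, 0, duration[i]))
      chan_de <- sample(c(rep("donor", nd), rep("acceptor", na)))
      t_aa <- sort(runif(naa, 0, duration[i]))
      tibble(
        time_s = start[i] + c(t_de, t_aa),
        channel = c(chan_de, rep("acceptor", naa)),
        excitation = c(rep("donor_pulse", tot_de), rep("acceptor_pulse", naa))
      ) |> dplyr::arrange(.data$time_s)
    })
    photons <- dplyr::bind_rows(per_burst)

    list(
      photons = photons,
      truth = tibble(burst = seq_len(n_bursts), population = pop_id,
                     e_true = e_true, n_de = n_de),
      populations = populations
    )
  })
}

#' Generate a synthetic denaturant titration with known ground truth
#'
#' Evaluates the model's state fractions at the requested
#' concentrations and perturbs them with Gaussian noise truncated to
#' `[0, 1]`, then renormalises each condition to the probability
#' simplex. Truncation plus renormalisation slightly biases fractions
#' near 0 and 1 toward the interior — documented behaviour, shared by
#' any bounded noise scheme.
#'
#' @param thermo A [thermo_model()].
#' @param concentrations Denaturant concentrations (M).
#' @param noise_sd Standard deviation of the per-point fraction noise
#'   (`>= 0`).
#' @param seed Seed.
#' @return A titration tibble `conc_m`, `state`, `fraction`, `sd`, with
#'   the generating model attached as attribute `truth`.
#' @examples
#' tm <- thermo_model(c("U", "I", "F"), dg0 = c(I = -5.6, F = -8.3),
#'                    m = c(I = 3.0, F = 4.15))
#' make_titration_dataset(tm, seq(0, 5, 0.5), noise_sd = 0.03, seed = 1)
#' @export
make_titration_dataset <- function(thermo, concentrations, noise_sd = 0.03,
                                   seed = 0) {
  stopifnot(inherits(thermo, "thermo_model"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  clean <- state_fractions(thermo, concentrations)
  withr::with_seed(seed, {
    noisy <- clean |>
      dplyr::mutate(fraction = pmin(pmax(.data$fraction +
                                           rnorm(dplyr::n(), 0, noise_sd), 0), 1)) |>
      dplyr::group_by(.data$conc_m) |>
      dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
      dplyr::ungroup() |>
      dplyr::mutate(sd = pmax(noise_sd, 1e-4))
  })
  attr(noisy, "truth") <- thermo
  noisy
}

#' Generate a toy conformer ensemble with planted contacts and
#' subpopulation geometry
#'
#' Builds residue-level coordinate frames around an extended reference
#' chain (3.8 Angstrom per residue along x, small isotropic jitter) and
#' plants two kinds of structure with machine-readable ground truth:
#'
#' * `planted_contacts`: rows `res_i`, `res_j`, `persistence` — in the
#'   stated fraction of frames, residue `res_j` is moved to within the
#'   contact cutoff of `res_i` (2.5 Angstrom COM separation).
#' * `pair_geometry`: rows `label`, `weight`, `res_i`, `res_j`,
#'   `dist_nm` — frames are partitioned by weight into named groups and
#'   residue `res_j` is placed at the stated distance from `res_i`
#'   (plus jitter), creating well-separated clusters in the
#'   distance-pair plane for subpopulation boxing.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames.
#' @param planted_contacts Optional contact plants (see above); pairs
#'   must respect `min_seq_sep`.
#' @param pair_geometry Optional subpopulation geometry plants.
#' @param min_seq_sep Separation the plants must respect (default 6).
#' @param jitter_a Isotropic coordinate jitter, Angstrom.
#' @param seed Seed.
#' @return A list: `ensemble` (a [conformer_ensemble()]), `truth`
#'   (list with the plant tables and per-frame group labels).
#' @examples
#' toy <- make_toy_ensemble(40, 20,
#'   planted_contacts = tibble::tibble(res_i = 5, res_j = 20,
#'                                     persistence = 0.8), seed = 1)
#' @export
make_toy_ensemble <- function(n_residues = 100, n_frames = 50,
                              planted_contacts = NULL, pair_geometry = NULL,
                              min_seq_sep = 6, jitter_a = 0.3, seed = 0) {
  if (!is.null(planted_contacts)) {
    planted_contacts <- as_tibble(planted_contacts)
    if (any(planted_contacts$res_j - planted_contacts$res_i < min_seq_sep)) {
      abort("planted contact violates the minimum sequence separation.")
    }
    if (any(planted_contacts$res_j > n_residues)) abort("plant outside the chain.")
  }
  if (!is.null(pair_geometry)) {
    pair_geometry <- as_tibble(pair_geometry)
    pair_geometry$weight <- pair_geometry$weight / sum(pair_geometry$weight)
  }
  withr::with_seed(seed, {
    base <- cbind(3.8 * seq_len(n_residues), 0, 0)
    coords <- array(0, c(n_frames, n_residues, 3))
    for (f in seq_len(n_frames)) {
      coords[f, , ] <- base + matrix(rnorm(n_residues * 3, 0, jitter_a),
                                     n_residues, 3)
    }
    group <- rep(NA_character_, n_frames)
    if (!is.null(pair_geometry)) {
      grp_id <- sample(nrow(pair_geometry), n_frames, replace = TRUE,
                       prob = pair_geometry$weight)
      group <- pair_geometry$label[grp_id]
      for (f in seq_len(n_frames)) {
        g <- pair_geometry[grp_id[f], ]
        # place res_j at dist_nm from res_i along +y, off the chain axis
        coords[f, g$res_j, ] <- coords[f, g$res_i, ] +
          c(0, g$dist_nm * 10, 0) + rnorm(3, 0, jitter_a)
      }
    }
    if (!is.null(planted_contacts)) {
      for (p in seq_len(nrow(planted_contacts))) {
        pc <- planted_contacts[p, ]
        on <- runif(n_frames) < pc$persistence
        for (f in which(on)) {
          coords[f, pc$res_j, ] <- coords[f, pc$res_i, ] +
            c(0, 0, 2.5) + rnorm(3, 0, 0.1)
        }
        for (f in which(!on)) {
          coords[f, pc$res_j, ] <- coords[f, pc$res_i, ] +
            c(0, 0, 30) + rnorm(3, 0, 0.5)
        }
      }
    }
    list(
      ensemble = conformer_ensemble(coords),
      truth = list(planted_contacts = planted_contacts,
                   pair_geometry = pair_geometry,
                   frame_group = group)
    )
  })
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' One MODEL per frame, one CA pseudo-atom per residue carrying the
#' residue centre of mass — the same layout [read_ensemble()] ingests,
#' so generation and ingestion round-trip.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(ensemble$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (k in seq_len(ensemble$n_residues)) {
      xyz <- ensemble$coords[f, k, ]
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        k, ensemble$resno[k], xyz[1], xyz[2], xyz[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Build a Markov model from dwell times and sample trajectories
#'
#' Constructs the transition matrix of an exponential-dwell kinetic
#' scheme at the model lag: each state persists with probability
#' `1 - lag/dwell` per step and otherwise jumps uniformly to the other
#' states (requires `dwell >> lag`). Discrete trajectories are sampled
#' from it for estimator round-trip tests.
#'
#' @param n_states Number of states.
#' @param dwell_ns Per-state mean dwell times (ns), each `> lag_ns`.
#' @param distances Optional per-state distances (nm); defaults to
#'   fixed efficiencies spread over (0, 1).
#' @param lag_ns Lag time (ns).
#' @param rescale Time-rescaling factor for the returned model.
#' @param n_traj,traj_length Number and length of sampled trajectories.
#' @param seed Seed.
#' @return A list: `model` (a [markov_model()]) and `trajectories`
#'   (list of integer paths).
#' @examples
#' make_msm(2, dwell_ns = c(200, 400), n_traj = 2, traj_length = 100,
#'          seed = 1)$model
#' @export
make_msm <- function(n_states, dwell_ns, distances = NULL, lag_ns = 10,
                     rescale = 225, n_traj = 5, traj_length = 1000,
                     seed = 0) {
  if (length(dwell_ns) != n_states) abort("one dwell time per state, please.")
  if (any(dwell_ns <= lag_ns)) abort("dwell times must exceed the lag time.")
  t_matrix <- diag(1 - lag_ns / dwell_ns)
  if (n_states > 1) {
    for (i in seq_len(n_states)) {
      t_matrix[i, -i] <- (lag_ns / dwell_ns[i]) / (n_states - 1)
    }
  } else {
    t_matrix <- matrix(1, 1, 1)
  }
  model <- markov_model(
    t_matrix, lag_ns = lag_ns, rescale = rescale, distances = distances,
    efficiencies = if (is.null(distances)) {
      seq(0.15, 0.85, length.out = n_states)
    } else NULL
  )
  trajectories <- withr::with_seed(seed, {
    cum_t <- t(apply(t_matrix, 1, cumsum))
    purrr::map(seq_len(n_traj), function(j) {
      path <- integer(traj_length)
      path[1] <- sample(n_states, 1, prob = model$populations)
      if (traj_length > 1) {
        u <- runif(traj_length - 1)
        for (s in 2:traj_length) {
          path[s] <- findInterval(u[s - 1], cum_t[path[s - 1], ]) + 1L
        }
      }
      pmin(path, n_states)
    })
  })
  list(model = model, trajectories = trajectories)
}
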