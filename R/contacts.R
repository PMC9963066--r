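#' Conformer ensembles of residue-level coordinates
#'
#' A `conformer_ensemble` holds per-frame, per-residue centre-of-mass
#' coordinates in Angstrom: an array `frames x residues x 3`, 1-based
#' residue numbering, per-residue masses, and optional frame weights
#' (e.g. Markov-model stationary populations). Multi-model PDB files
#' are read as ensembles with one frame per MODEL; residue centres of
#' mass are taken over heavy atoms (hydrogens excluded).
#'
#' @param coords Numeric array `[n_frames, n_residues, 3]` (Angstrom).
#' @param resno Integer residue numbers (1-based), one per residue.
#' @param masses Residue masses (Da); default 110 (mean amino-acid
#'   residue mass) for every residue.
#' @param weights Optional frame weights, `>= 0`, normalised to sum 1.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(coords, resno = NULL, masses = NULL,
                               weights = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("`coords` must be an array [n_frames, n_residues, 3].")
  }
  n_frames <- dim(coords)[1]
  n_res <- dim(coords)[2]
  resno <- resno %||% seq_len(n_res)
  if (length(resno) != n_res) abort("`resno` must have one entry per residue.")
  masses <- masses %||% rep(110, n_res)
  if (is.null(weights)) {
    weights <- rep(1 / n_frames, n_frames)
  } else {
    if (length(weights) != n_frames || any(weights < 0)) {
      abort("`weights` must be non-negative, one per frame.")
    }
    weights <- weights / sum(weights)
  }
  structure(
    list(coords = coords, resno = resno, masses = masses,
         weights = weights, n_frames = n_frames, n_residues = n_res),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frames x %d residues\n",
              x$n_frames, x$n_residues))
  invisible(x)
}

#' @rdname conformer_ensemble
#' @param file Path to a (possibly multi-model) PDB file.
#' @export
read_ensemble <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  heavy <- is.na(at$elesy) | !(at$elesy %in% "H")
  resno_all <- at$resno
  residues <- sort(unique(resno_all[heavy]))
  xyz <- pdb$xyz                      # n_frames x (3 * n_atoms)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_res <- length(residues)
  amass <- atomic_masses(at$elesy)
  coords <- array(NA_real_, c(n_frames, n_res, 3))
  masses <- numeric(n_res)
  for (k in seq_len(n_res)) {
    idx <- which(heavy & resno_all == residues[k])
    m <- amass[idx]
    masses[k] <- sum(m)
    cols_x <- 3 * (idx - 1) + 1
    for (d in 1:3) {
      coords[, k, d] <- (xyz[, cols_x + (d - 1), drop = FALSE] %*% m) / sum(m)
    }
  }
  conformer_ensemble(coords, resno = residues, masses = masses)
}

#' Contact definition: COM cutoff and sequence separation
#'
#' Two residues are in contact when their centres of mass are closer
#' than `com_cutoff_a` Angstrom and they are separated in sequence by
#' at least `min_seq_sep` residues (`j - i >= min_seq_sep`; the
#' boundary case is included).
#'
#' @param com_cutoff_a Centre-of-mass distance cutoff, Angstrom
#'   (default 3).
#' @param min_seq_sep Minimum sequence separation, residues (default 6).
#' @return An object of class `contact_definition`.
#' @export
contact_definition <- function(com_cutoff_a = 3, min_seq_sep = 6) {
  if (com_cutoff_a <= 0) abort("`com_cutoff_a` must be positive.")
  if (min_seq_sep < 1) abort("`min_seq_sep` must be >= 1.")
  structure(list(com_cutoff_a = com_cutoff_a, min_seq_sep = min_seq_sep),
            class = "contact_definition")
}

# standard atomic masses of the elements occurring in protein PDB files;
# unknown symbols fall back to carbon
atomic_masses <- function(elesy) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)
  m <- tbl[toupper(trimws(elesy %||% ""))]
  m[is.na(m)] <- tbl["C"]
  unname(m)
}

# grid (cell-list) neighbour search: O(n) for short cutoffs
grid_pairs_within <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(cbind(i = integer(), j = integer()))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  cell_of <- cell
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(); out_j <- integer()
  for (b in buckets) {
    c0 <- cell_of[b[1], ]
    neigh_keys <- paste(c0[1] + offsets[, 1], c0[2] + offsets[, 2],
                        c0[3] + offsets[, 3])
    cand <- unlist(buckets[intersect(neigh_keys, names(buckets))],
                   use.names = FALSE)
    for (ii in b) {
      jj <- cand[cand > ii]
      if (!length(jj)) next
      d2 <- rowSums((xyz[jj, , drop = FALSE] -
                       matrix(xyz[ii, ], length(jj), 3, byrow = TRUE))^2)
      hit <- jj[d2 < cutoff^2]
      out_i <- c(out_i, rep.int(ii, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  cbind(i = out_i, j = out_j)
}

#' Residue contacts in a single frame
#'
#' Finds all residue pairs whose centres of mass lie within the cutoff
#' and that satisfy the sequence-separation rule, using a cell-list
#' spatial index (equivalent to, and tested against, the O(n^2)
#' all-pairs scan). Residues with missing coordinates are excluded with
#' a warning.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param frame Frame index (1-based).
#' @param cdef A [contact_definition()].
#' @return A tibble `res_i`, `res_j` (residue numbers, `res_i < res_j`),
#'   `dist_a` (COM distance, Angstrom), sorted canonically.
#' @export
residue_com_contacts <- function(ensemble, frame = 1,
                                 cdef = contact_definition()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (frame < 1 || frame > ensemble$n_frames) abort("frame index out of range.")
  xyz <- ensemble$coords[frame, , , drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  ok <- stats::complete.cases(xyz)
  if (!all(ok)) {
    warn(sprintf("%d residue(s) with missing coordinates excluded.", sum(!ok)))
  }
  idx_ok <- which(ok)
  pairs <- grid_pairs_within(xyz[idx_ok, , drop = FALSE], cdef$com_cutoff_a)
  if (!nrow(pairs)) {
    return(tibble(res_i = integer(), res_j = integer(), dist_a = numeric()))
  }
  ri <- ensemble$resno[idx_ok[pairs[, "i"]]]
  rj <- ensemble$resno[idx_ok[pairs[, "j"]]]
  swap <- ri > rj
  tmp <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmp
  d <- sqrt(rowSums((xyz[idx_ok[pairs[, "i"]], , drop = FALSE] -
                       xyz[idx_ok[pairs[, "j"]], , drop = FALSE])^2))
  out <- tibble(res_i = ri, res_j = rj, dist_a = d) |>
    dplyr::filter(.data$res_j - .data$res_i >= cdef$min_seq_sep) |>
    dplyr::arrange(.data$res_i, .data$res_j)
  out
}

#' Contacts persisting across an ensemble
#'
#' A contact is persistent when it occurs in at least
#' `persistence_threshold` of the (weighted) frames.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param cdef A [contact_definition()].
#' @param persistence_threshold Weighted frame fraction in `(0, 1]`.
#' @return A tibble `res_i`, `res_j`, `persistence` (weighted fraction
#'   of frames containing the contact), filtered to the threshold.
#' @export
persistent_contacts <- function(ensemble, cdef = contact_definition(),
                                persistence_threshold = 0.5) {
  if (persistence_threshold <= 0 || persistence_threshold > 1) {
    abort("`persistence_threshold` must lie in (0, 1].")
  }
  per_frame <- purrr::map(seq_len(ensemble$n_frames), function(f) {
    ct <- residue_com_contacts(ensemble, f, cdef)
    if (nrow(ct)) dplyr::mutate(ct, w = ensemble$weights[f]) else NULL
  })
  all_ct <- dplyr::bind_rows(per_frame)
  if (is.null(all_ct) || !nrow(all_ct)) {
    return(tibble(res_i = integer(), res_j = integer(), persistence = numeric()))
  }
  all_ct |>
    dplyr::group_by(.data$res_i, .data$res_j) |>
    dplyr::summarise(persistence = sum(.data$w), .groups = "drop") |>
    dplyr::filter(.data$persistence >= persistence_threshold - 1e-12) |>
    dplyr::arrange(.data$res_i, .data$res_j)
}

contact_key <- function(ct) paste(ct$res_i, ct$res_j, sep = "-")

key_to_tibble <- function(keys) {
  if (!length(keys)) return(tibble(res_i = integer(), res_j = integer()))
  parts <- strsplit(keys, "-", fixed = TRUE)
  tibble(res_i = as.integer(purrr::map_chr(parts, 1)),
         res_j = as.integer(purrr::map_chr(parts, 2))) |>
    dplyr::arrange(.data$res_i, .data$res_j)
}

#' Set algebra over named contact sets
#'
#' Evaluates a logical expression over named contact sets — e.g.
#' `"open & !closed"` (contacts in the open but not the closed
#' subpopulation) or `"open & extended & !closed"` — where each name is
#' a contact table with `res_i`/`res_j` columns and `&`, `|`, `!`, and
#' parentheses have their usual meanings over membership in the union
#' universe.
#'
#' @param sets Named list of contact tables.
#' @param expr A set expression as a string.
#' @return A tibble of the selected contacts (`res_i`, `res_j`).
#' @examples
#' a <- tibble::tibble(res_i = c(1, 2), res_j = c(10, 12))
#' b <- tibble::tibble(res_i = 2, res_j = 12)
#' contact_algebra(list(a = a, b = b), "a & !b")
#' @export
contact_algebra <- function(sets, expr) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a fully named list.")
  }
  keys <- purrr::map(sets, contact_key)
  universe <- sort(unique(unlist(keys)))
  member <- purrr::map(keys, ~ universe %in% .x)
  parsed <- tryCatch(str2lang(expr), error = function(e) {
    abort(sprintf("could not parse set expression '%s'.", expr))
  })
  used <- all.vars(parsed)
  unknown <- setdiff(used, names(sets))
  if (length(unknown)) {
    abort(paste0("unknown set name(s): ", paste(unknown, collapse = ", ")))
  }
  sel <- eval(parsed, envir = member)
  key_to_tibble(universe[sel])
}

#' Classify contacts across closed/open/extended subpopulations
#'
#' Convenience wrapper assigning every contact in the union of three
#' subpopulation contact sets to its sharing class: present in all
#' three, in exactly two (each pair), or unique to one.
#'
#' @param closed,open,extended Contact tables (`res_i`, `res_j`).
#' @return A tibble `res_i`, `res_j`, `class` with classes such as
#'   `"shared_all"`, `"open_and_extended_only"`, `"closed_only"`, ...
#' @export
contact_classes <- function(closed, open, extended) {
  sets <- list(closed = closed, open = open, extended = extended)
  keys <- purrr::map(sets, contact_key)
  universe <- sort(unique(unlist(keys)))
  inc <- sapply(keys, function(k) universe %in% k)
  if (!length(universe)) {
    return(tibble(res_i = integer(), res_j = integer(), class = character()))
  }
  inc <- matrix(inc, ncol = 3, dimnames = list(NULL, names(sets)))
  cls <- apply(inc, 1, function(row) {
    members <- names(sets)[row]
    if (length(members) == 3) "shared_all"
    else if (length(members) == 2) paste0(paste(members, collapse = "_and_"), "_only")
    else paste0(members, "_only")
  })
  dplyr::bind_cols(key_to_tibble(universe), tibble(class = cls))
}

#' Per-frame distances for chosen residue pairs
#'
#' @param ensemble A [conformer_ensemble()].
#' @param pairs A two-column table (`res_i`, `res_j`) of residue
#'   numbers; `res_i != res_j`.
#' @return A tibble with `frame` plus one column per pair named
#'   `r_<i>_<j>`, distances in nm (coordinates are Angstrom; the
#'   conversion happens here at the boundary).
#' @export
pair_distance_table <- function(ensemble, pairs) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  pairs <- as_tibble(pairs)
  if (!all(c("res_i", "res_j") %in% names(pairs))) {
    abort("`pairs` needs columns res_i, res_j.")
  }
  if (any(pairs$res_i == pairs$res_j)) abort("zero-length pair (i, i) rejected.")
  idx_i <- match(pairs$res_i, ensemble$resno)
  idx_j <- match(pairs$res_j, ensemble$resno)
  if (anyNA(idx_i) || anyNA(idx_j)) abort("unknown residue number in `pairs`.")
  out <- tibble(frame = seq_len(ensemble$n_frames))
  for (p in seq_len(nrow(pairs))) {
    di <- ensemble$coords[, idx_i[p], , drop = FALSE] -
      ensemble$coords[, idx_j[p], , drop = FALSE]
    out[[sprintf("r_%d_%d", pairs$res_i[p], pairs$res_j[p])]] <-
      sqrt(rowSums(matrix(di, ensemble$n_frames, 3)^2)) / 10
  }
  out
}

#' Axis-aligned subpopulation boxes in a distance-pair plane
#'
#' Named rectangles in the plane spanned by two pair distances,
#' delimiting conformational regimes (e.g. closed / open / extended by
#' the 86-165 distance). Boxes within one scheme may not overlap.
#'
#' @param boxes A tibble with columns `label`, `xmin`, `xmax`, `ymin`,
#'   `ymax` (nm).
#' @param pair_x,pair_y Names of the distance columns the box plane
#'   refers to (e.g. `"r_86_165"`).
#' @return An object of class `subpop_boxes`.
#' @export
subpop_boxes <- function(boxes, pair_x, pair_y) {
  boxes <- as_tibble(boxes)
  req <- c("label", "xmin", "xmax", "ymin", "ymax")
  if (!all(req %in% names(boxes))) {
    abort("`boxes` needs columns label, xmin, xmax, ymin, ymax.")
  }
  if (any(boxes$xmin >= boxes$xmax) || any(boxes$ymin >= boxes$ymax)) {
    abort("degenerate box: need xmin < xmax and ymin < ymax.")
  }
  n <- nrow(boxes)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      overlap_x <- boxes$xmin[a] < boxes$xmax[b] && boxes$xmin[b] < boxes$xmax[a]
      overlap_y <- boxes$ymin[a] < boxes$ymax[b] && boxes$ymin[b] < boxes$ymax[a]
      if (overlap_x && overlap_y) {
        abort(sprintf("boxes '%s' and '%s' overlap.", boxes$label[a], boxes$label[b]))
      }
    }
  }
  structure(list(boxes = boxes, pair_x = pair_x, pair_y = pair_y),
            class = "subpop_boxes")
}

#' Assign frames to subpopulations by distance-pair boxing
#'
#' Labels every frame by the box containing its (pair_x, pair_y)
#' distances, or `"unassigned"` when it falls outside all boxes, and
#' aggregates weighted label fractions. Labels partition the frames:
#' counts plus unassigned equal the frame number.
#'
#' @param dist_table Output of [pair_distance_table()].
#' @param boxes A [subpop_boxes()] whose plane columns exist in
#'   `dist_table`.
#' @param weights Optional frame weights (default uniform).
#' @return A list with `frames` (tibble `frame`, `label`) and `weights`
#'   (tibble `label`, `weight`; weights over assigned + unassigned sum
#'   to 1).
#' @export
assign_subpopulations <- function(dist_table, boxes, weights = NULL) {
  stopifnot(inherits(boxes, "subpop_boxes"))
  for (col in c(boxes$pair_x, boxes$pair_y)) {
    if (!col %in% names(dist_table)) {
      abort(sprintf("distance column '%s' not present in `dist_table`.", col))
    }
  }
  x <- dist_table[[boxes$pair_x]]
  y <- dist_table[[boxes$pair_y]]
  n <- nrow(dist_table)
  weights <- weights %||% rep(1 / n, n)
  weights <- weights / sum(weights)
  label <- rep("unassigned", n)
  for (b in seq_len(nrow(boxes$boxes))) {
    bx <- boxes$boxes[b, ]
    inside <- x >= bx$xmin & x < bx$xmax & y >= bx$ymin & y < bx$ymax
    label[inside] <- bx$label
  }
  frames <- tibble(frame = dist_table$frame, label = label)
  wtab <- frames |>
    dplyr::mutate(w = weights) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(weight = sum(.data$w), .groups = "drop")
  list(frames = frames, weights = wtab)
}

#' Two-dimensional distance-pair correlation map
#'
#' Weighted 2-D histogram of two pair distances over a rectangular
#' grid, normalised to total mass 1. Its marginals equal the
#' corresponding 1-D weighted histograms exactly.
#'
#' @param dist_table Output of [pair_distance_table()].
#' @param pair_x,pair_y Distance column names.
#' @param grid_x,grid_y Strictly increasing bin-edge vectors (nm);
#'   values outside are clamped into the boundary bins.
#' @param weights Optional frame weights (default uniform).
#' @return A list of class `pair_density`: `density` (matrix
#'   `length(grid_x)-1` by `length(grid_y)-1`), the edge vectors, and
#'   the pair names.
#' @export
pair_correlation_map <- function(dist_table, pair_x, pair_y,
                                 grid_x, grid_y, weights = NULL) {
  for (col in c(pair_x, pair_y)) {
    if (!col %in% names(dist_table)) abort(sprintf("column '%s' missing.", col))
  }
  if (length(grid_x) < 2 || length(grid_y) < 2 ||
      is.unsorted(grid_x, strictly = TRUE) || is.unsorted(grid_y, strictly = TRUE)) {
    abort("grids must be strictly increasing edge vectors of length >= 2.")
  }
  x <- dist_table[[pair_x]]; y <- dist_table[[pair_y]]
  n <- length(x)
  weights <- weights %||% rep(1 / n, n)
  weights <- weights / sum(weights)
  ix <- findInterval(x, grid_x, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, grid_y, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- matrix(0, length(grid_x) - 1, length(grid_y) - 1)
  for (k in seq_len(n)) dens[ix[k], iy[k]] <- dens[ix[k], iy[k]] + weights[k]
  structure(list(density = dens, grid_x = grid_x, grid_y = grid_y,
                 pair_x = pair_x, pair_y = pair_y),
            class = "pair_density")
}

#' @export
print.pair_density <- function(x, ...) {
  cat(sprintf("<pair_density> %s vs %s, %d x %d bins, mass %.6f\n",
              x$pair_x, x$pair_y, nrow(x$density), ncol(x$density),
              sum(x$density)))
  invisible(x)
}

#' Structure-based transfer-efficiency prediction
#'
#' Predicts the transfer efficiency a dye pair attached near two
#' residues would report, from the residues' C-beta separation in a
#' structure (C-alpha for glycine), via the Forster relation.
#'
#' @param pdb_file Path to a PDB file (first model used).
#' @param res_i,res_j Residue numbers of the two label sites.
#' @param r0 Forster radius in nm.
#' @param atom Atom name used as the label-site anchor (default
#'   `"CB"`, falling back to `"CA"` where absent).
#' @return A tibble: `res_i`, `res_j`, `dist_nm`, `efficiency`.
#' @export
predict_structure_efficiency <- function(pdb_file, res_i, res_j, r0 = 5.4,
                                         atom = "CB") {
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  site <- function(res) {
    sel <- pdb$atom$resno == res & pdb$atom$elety == atom
    if (!any(sel)) sel <- pdb$atom$resno == res & pdb$atom$elety == "CA"
    if (!any(sel)) abort(sprintf("residue %d has no %s/CA atom.", res, atom))
    unlist(pdb$atom[which(sel)[1], c("x", "y", "z")])
  }
  d_a <- sqrt(sum((site(res_i) - site(res_j))^2))
  tibble(res_i = res_i, res_j = res_j, dist_nm = d_a / 10,
         efficiency = forster_efficiency(d_a / 10, r0))
}
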