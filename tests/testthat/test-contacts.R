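test_that("contact definition thresholds behave literally", {
  # residues 2.9 A apart, 7 apart in sequence: a contact
  xyz <- matrix(0, 8, 3); xyz[, 1] <- (1:8) * 50
  xyz[8, ] <- xyz[1, ] + c(2.9, 0, 0)
  ens <- make_frame_ensemble(xyz)
  ct <- residue_com_contacts(ens, 1, contact_definition(3, 6))
  expect_equal(nrow(ct), 1L)
  expect_equal(c(ct$res_i, ct$res_j), c(1L, 8L))

  # same distance, sequence separation 5: excluded
  xyz2 <- matrix(0, 6, 3); xyz2[, 1] <- (1:6) * 50
  xyz2[6, ] <- xyz2[1, ] + c(2.9, 0, 0)
  ct2 <- residue_com_contacts(make_frame_ensemble(xyz2), 1,
                              contact_definition(3, 6))
  expect_equal(nrow(ct2), 0L)
  # the boundary case j - i = 6 is included
  xyz3 <- matrix(0, 7, 3); xyz3[, 1] <- (1:7) * 50
  xyz3[7, ] <- xyz3[1, ] + c(2.9, 0, 0)
  ct3 <- residue_com_contacts(make_frame_ensemble(xyz3), 1,
                              contact_definition(3, 6))
  expect_equal(nrow(ct3), 1L)
  # distance exactly at the cutoff is not a contact (strict <)
  xyz4 <- matrix(0, 7, 3); xyz4[, 1] <- (1:7) * 50
  xyz4[7, ] <- xyz4[1, ] + c(3.0, 0, 0)
  expect_equal(nrow(residue_com_contacts(make_frame_ensemble(xyz4), 1,
                                         contact_definition(3, 6))), 0L)
})

test_that("the cell-list contact finder agrees with brute force on random frames", {
  cdef <- contact_definition(6, 3)
  withr::with_seed(61, {
    for (rep in 1:200) {
      n <- 60
      xyz <- matrix(runif(n * 3, 0, 30), n, 3)
      got <- residue_com_contacts(make_frame_ensemble(xyz), 1, cdef)
      ref <- oracle_contacts(xyz, seq_len(n), 6, 3)
      expect_equal(got[, c("res_i", "res_j")], ref, ignore_attr = TRUE)
    }
  })
})

test_that("persistent contacts respect the weighted frame-fraction threshold", {
  toy <- make_toy_ensemble(40, 50,
    planted_contacts = tibble::tibble(res_i = 5, res_j = 20,
                                      persistence = 0.8), seed = 62)
  found <- persistent_contacts(toy$ensemble, contact_definition(3, 6),
                               persistence_threshold = 0.5)
  expect_true(any(found$res_i == 5 & found$res_j == 20))
  realized <- found$persistence[found$res_i == 5 & found$res_j == 20]
  dropped <- persistent_contacts(toy$ensemble, contact_definition(3, 6),
                                 persistence_threshold = min(realized + 0.1, 1))
  expect_false(any(dropped$res_i == 5 & dropped$res_j == 20))

  # identical frames at threshold 1 keep every frame contact
  xyz <- matrix(0, 10, 3); xyz[, 1] <- (1:10) * 50
  xyz[10, ] <- xyz[1, ] + c(2, 0, 0)
  coords <- array(0, c(3, 10, 3))
  for (f in 1:3) coords[f, , ] <- xyz
  ens <- conformer_ensemble(coords)
  all_ct <- persistent_contacts(ens, contact_definition(3, 6), 1.0)
  expect_equal(nrow(all_ct), 1L)
  # an ensemble with no contacts gives the empty set
  empty <- make_toy_ensemble(20, 5, seed = 63)
  expect_equal(nrow(persistent_contacts(empty$ensemble,
                                        contact_definition(3, 6), 0.5)), 0L)
  expect_error(persistent_contacts(ens, contact_definition(3, 6), 0), "0, 1")
})

test_that("contact-set algebra matches hand enumeration", {
  a <- tibble::tibble(res_i = c(1L, 2L, 3L, 4L, 5L), res_j = c(10L, 12L, 14L, 16L, 18L))
  b <- tibble::tibble(res_i = c(2L, 3L), res_j = c(12L, 14L))
  sets <- list(open = a, closed = b)
  expect_equal(nrow(contact_algebra(sets, "open & !open")), 0L)
  both <- contact_algebra(sets, "open & closed")
  expect_equal(both, b[order(b$res_i), ], ignore_attr = TRUE)
  only_open <- contact_algebra(sets, "open & !closed")
  expect_equal(only_open$res_i, c(1L, 4L, 5L))
  expect_error(contact_algebra(sets, "open & mystery"), "unknown set")

  # three identical sets: everything shared, differences empty
  cls <- contact_classes(a, a, a)
  expect_true(all(cls$class == "shared_all"))
  expect_equal(nrow(cls), nrow(a))

  cls2 <- contact_classes(closed = b, open = a, extended = b)
  expect_equal(sum(cls2$class == "shared_all"), 2L)
  expect_equal(sum(cls2$class == "open_only"), 3L)
})

test_that("pair distance tables are exact, unit-converted, and order-preserving", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 37, 0), c(0, 0, 5))
  ens <- make_frame_ensemble(xyz)
  pairs <- tibble::tibble(res_i = c(1, 2, 1), res_j = c(2, 3, 4))
  dt <- pair_distance_table(ens, pairs)
  expect_equal(dt$r_1_2, 1.0)      # 10 A = 1 nm
  expect_equal(dt$r_2_3, 3.7)
  expect_equal(dt$r_1_4, 0.5)
  # permuting the pair order permutes the columns
  dt_perm <- pair_distance_table(ens, pairs[c(3, 1, 2), ])
  expect_equal(names(dt_perm), c("frame", "r_1_4", "r_1_2", "r_2_3"))
  expect_error(pair_distance_table(ens, tibble::tibble(res_i = 2, res_j = 2)),
               "zero-length")
  expect_error(pair_distance_table(ens, tibble::tibble(res_i = 1, res_j = 99)),
               "unknown residue")
})

test_that("subpopulation boxing partitions frames and recovers planted weights", {
  toy <- make_toy_ensemble(
    40, 400,
    pair_geometry = tibble::tibble(
      label = c("closed", "open", "extended"), weight = c(0.3, 0.5, 0.2),
      res_i = 10, res_j = 30, dist_nm = c(2, 5, 9)), seed = 64)
  dt <- pair_distance_table(toy$ensemble, tibble::tibble(res_i = 10, res_j = 30))
  bx <- subpop_boxes(tibble::tibble(
    label = c("closed", "open", "extended"),
    xmin = c(0, 3.5, 7), xmax = c(3.5, 7, 12), ymin = 0, ymax = 12),
    "r_10_30", "r_10_30")
  asg <- assign_subpopulations(dt, bx)
  expect_equal(nrow(asg$frames), 400L)
  expect_equal(sum(asg$weights$weight), 1, tolerance = 1e-12)
  planted <- table(toy$truth$frame_group) / 400
  for (lbl in names(planted)) {
    expect_equal(asg$weights$weight[asg$weights$label == lbl],
                 unname(planted[lbl]), tolerance = 1e-9)
  }
  # frames outside all boxes are unassigned
  bx_tiny <- subpop_boxes(tibble::tibble(label = "nowhere", xmin = 100,
                                         xmax = 101, ymin = 100, ymax = 101),
                          "r_10_30", "r_10_30")
  asg2 <- assign_subpopulations(dt, bx_tiny)
  expect_true(all(asg2$frames$label == "unassigned"))
  expect_error(subpop_boxes(tibble::tibble(
    label = c("a", "b"), xmin = c(0, 1), xmax = c(2, 3),
    ymin = c(0, 0), ymax = c(2, 2)), "x", "y"), "overlap")
})

test_that("correlation maps normalise and their marginals equal 1-D histograms", {
  toy <- make_toy_ensemble(
    30, 300,
    pair_geometry = tibble::tibble(
      label = c("a", "b"), weight = c(0.5, 0.5),
      res_i = 5, res_j = 15, dist_nm = c(2, 6)), seed = 65)
  dt <- pair_distance_table(toy$ensemble,
                            tibble::tibble(res_i = c(5, 5), res_j = c(15, 25)))
  gx <- seq(0, 12, by = 0.5); gy <- seq(0, 15, by = 0.5)
  pm <- pair_correlation_map(dt, "r_5_15", "r_5_25", gx, gy)
  expect_equal(sum(pm$density), 1, tolerance = 1e-12)
  # marginal consistency against direct binning
  ix <- findInterval(dt$r_5_15, gx, rightmost.closed = TRUE, all.inside = TRUE)
  ref_x <- tabulate(ix, nbins = length(gx) - 1) / nrow(dt)
  expect_equal(rowSums(pm$density), ref_x, tolerance = 1e-12)
  # perfectly correlated axes put all mass on the diagonal
  pm_diag <- pair_correlation_map(dt, "r_5_15", "r_5_15", gx, gx)
  on_diag <- sum(diag(pm_diag$density))
  expect_equal(on_diag, 1, tolerance = 1e-12)
  expect_error(pair_correlation_map(dt, "r_5_15", "r_5_25", c(1, 1), gy),
               "strictly increasing")
})

test_that("ensembles round-trip through multi-model PDB with COM extraction", {
  toy <- make_toy_ensemble(25, 8, seed = 66)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(toy$ensemble, f)
  back <- read_ensemble(f)
  expect_equal(back$n_frames, 8L)
  expect_equal(back$n_residues, 25L)
  # PDB coordinates carry 3 decimals
  expect_lt(max(abs(back$coords - toy$ensemble$coords)), 1e-3)
})

test_that("structure-based efficiency prediction uses the anchor-atom separation", {
  # synthetic two-residue structure with a known CB-CB distance of 25 A
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   2      24.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   2      26.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  pred <- predict_structure_efficiency(f, 1, 2, r0 = 5.4)
  expect_equal(pred$dist_nm, 2.5)
  expect_equal(pred$efficiency, forster_efficiency(2.5, 5.4))
  expect_gt(pred$efficiency, 0.98)
})
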