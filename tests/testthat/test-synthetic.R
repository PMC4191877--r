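test_that("generation is bit-identical for identical spec and seed", {
  sp <- synthetic_spec(composition = composition_spec(n_solute = 20),
                       solute_mode = "interface_band", mixing_lambda = 0.4,
                       seed = 99)
  a <- generate_striped_membrane(sp)
  b <- generate_striped_membrane(sp)
  expect_identical(a$frame$beads, b$frame$beads)
  expect_identical(a$truth$molecules, b$truth$molecules)
  c <- generate_striped_membrane(synthetic_spec(
    composition = composition_spec(n_solute = 20),
    solute_mode = "interface_band", mixing_lambda = 0.4, seed = 100))
  expect_false(identical(a$frame$beads$x, c$frame$beads$x))
})

test_that("generated composition matches the spec exactly at every lambda", {
  for (lam in c(0, 0.3, 1)) {
    sp <- synthetic_spec(composition = composition_spec(n_solute = 64),
                         mixing_lambda = lam, seed = 41)
    g <- generate_striped_membrane(sp)
    mols <- g$frame$beads[!duplicated(g$frame$beads$molecule_index), ]
    counts <- table(mols$species)
    expect_equal(unname(counts[["DLiPC"]]), 540)
    expect_equal(unname(counts[["DPPC"]]), 828)
    expect_equal(unname(counts[["CHOL"]]), 576)
    expect_equal(unname(counts[["OCT"]]), 64)
    # one PO4 per phospholipid, one ROH per cholesterol
    expect_length(select_beads(g$frame, c("DLiPC", "DPPC"), "PO4"), 1368)
    expect_length(select_beads(g$frame, "CHOL", "ROH"), 576)
  }
})

test_that("stripe phase labels match the geometry at lambda = 0", {
  g <- generate_striped_membrane(synthetic_spec(seed = 17))
  mt <- g$truth$molecules
  expect_true(all(mt$phase[mt$species == "DLiPC"] == "Ld"))
  expect_true(all(mt$phase[mt$species == "DPPC"] == "Lo"))
  chol_ld <- sum(mt$species == "CHOL" & mt$phase == "Ld")
  expect_equal(chol_ld, round(0.1 * 576))
})

test_that("mixing at lambda = 0 is the identity and lambda raises f_mix monotonically", {
  g <- generate_striped_membrane(synthetic_spec(seed = 23))
  m0 <- mix_membrane(g$frame, g$truth, 0, seed = 5)
  expect_identical(m0$frame$beads, g$frame$beads)
  lams <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(lams, function(lam) {
    mean(vapply(1:6, function(s)
      dlipc_dppc_contact_fraction(
        mix_membrane(g$frame, g$truth, lam, seed = s)$frame)$value,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("impossibly dense packing is rejected", {
  sp <- synthetic_spec(box_xy = c(8, 8), seed = 1)
  expect_error(generate_striped_membrane(sp), class = "lipidmix_box_too_small")
})

test_that("mixing series schedules are validated", {
  sp <- synthetic_spec(seed = 2)
  expect_error(lattice_mixing_series(sp, 4, schedule = list(type = "bogus")),
               class = "lipidmix_invalid_schedule")
  expect_error(lattice_mixing_series(sp, 4,
                                     schedule = list(type = "two_stage",
                                                     stage_a_end = 1.4)),
               class = "lipidmix_invalid_schedule")
  expect_error(lattice_mixing_series(sp, 1,
                                     schedule = list(type = "constant")),
               class = "lipidmix_invalid_spec")
})

test_that("a constant schedule yields a stationary series with increasing times", {
  sp <- synthetic_spec(seed = 3)
  ser <- lattice_mixing_series(sp, n_frames = 5,
                               schedule = list(type = "constant", lambda = 0.5),
                               time_step = 2)
  expect_equal(ser$trajectory$times, seq(0, 8, by = 2))
  vals <- contact_fraction_series(ser$trajectory, "dlipc_dppc")$value
  expect_lt(stats::sd(vals), 0.05)
  expect_gt(mean(vals), 0.1)
})

test_that("ground truth serializes with interface positions and spec echo", {
  g <- generate_striped_membrane(synthetic_spec(seed = 44))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(g$truth, p)
  lines <- readLines(p)
  expect_match(lines[1], "interface_x_nm")
  tab <- utils::read.table(p, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(tab), 1944)
  expect_setequal(unique(tab$species), c("DLiPC", "DPPC", "CHOL"))
})
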