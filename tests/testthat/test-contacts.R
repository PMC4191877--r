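test_that("contact counting respects the cutoff and excludes self-pairs", {
  fr <- make_frame(mol = c(1, 2), species = c("DLiPC", "DPPC"),
                   bead = c("PO4", "PO4"),
                   x = c(1, 1.5), y = c(1, 1), z = c(1, 1))
  a <- select_beads(fr, "DLiPC"); b <- select_beads(fr, "DPPC")
  expect_equal(count_contacts(fr, a, b, 1.1, "bead_pairs"), 1)
  expect_equal(count_contacts(fr, a, b, 0.4, "bead_pairs"), 0)
  # overlapping selection, cutoff 0: self-pairs excluded, returns 0
  expect_equal(count_contacts(fr, a, a, 0, "unordered_pairs"), 0)
})

test_that("every counting mode matches the 27-image all-pairs oracle", {
  set.seed(202)
  for (rep in 1:20) {
    fr <- random_frame(n_mol = sample(8:30, 1))
    cutoff <- stats::runif(1, 0.3, 1.5)
    sp <- known_species(fr)
    sel_a <- select_beads(fr, sample(sp, 1), "ALL")
    sel_b <- select_beads(fr, sample(sp, 1), "ALL")
    if (!length(sel_a) || !length(sel_b)) next
    for (mode in c("bead_pairs", "unordered_pairs", "ordered_from_a")) {
      expect_equal(count_contacts(fr, sel_a, sel_b, cutoff, mode),
                   oracle_count(fr, sel_a, sel_b, cutoff, mode),
                   info = sprintf("rep %d mode %s", rep, mode))
    }
  }
})

test_that("f_mix on a hand-built three-lipid neighborhood equals 1/3", {
  # one DLiPC with one DPPC neighbor and one DLiPC neighbor; the second
  # DLiPC has no other neighbor: c_cross = 1, c_same(ordered) = 2
  fr <- make_frame(mol = 1:3,
                   species = c("DLiPC", "DPPC", "DLiPC"),
                   bead = rep("PO4", 3),
                   x = c(5.0, 5.9, 4.1), y = c(5, 5, 5), z = c(5, 5, 5))
  r <- dlipc_dppc_contact_fraction(fr, cutoff = 1.1)
  expect_equal(unname(r$counts["DLiPC-DPPC"]), 1)
  expect_equal(unname(r$counts["DLiPC-DLiPC"]), 2)
  expect_equal(r$value, 1 / 3)
})

test_that("fully separated stripes with a buffer beyond the cutoff give f_mix = 0", {
  g <- generate_striped_membrane(synthetic_spec(stripe_buffer = 1.2, seed = 6))
  r <- dlipc_dppc_contact_fraction(g$frame)
  expect_identical(r$value, 0)
  expect_gt(unname(r$counts["DLiPC-DLiPC"]), 0)
})

test_that("contact fractions live in [0,1] and are translation/wrap invariant", {
  sp <- synthetic_spec(composition = composition_spec(n_solute = 48),
                       mixing_lambda = 0.5, seed = 12)
  g <- generate_striped_membrane(sp)
  for (stat_fun in list(function(f) dlipc_dppc_contact_fraction(f)$value,
                        function(f) solute_dlipc_contact_fraction(f, "OCT")$value,
                        function(f) chol_dlipc_contact_fraction(f)$value)) {
    v0 <- stat_fun(g$frame)
    expect_gte(v0, 0); expect_lte(v0, 1)
    moved <- translate_frame(g$frame, dx = 7.3, dy = -2.1, dz = 11.4)
    expect_equal(stat_fun(moved), v0, tolerance = 1e-12)
  }
})

test_that("solute and cholesterol statistics hit their constructed limits", {
  # all solutes buried in the DLiPC stripe: fraction 1
  sp <- synthetic_spec(composition = composition_spec(n_solute = 40),
                       solute_mode = "ld_partition", seed = 4)
  g <- generate_striped_membrane(sp)
  expect_equal(solute_dlipc_contact_fraction(g$frame, "OCT")$value, 1)
  # cholesterol fully in the Lo stripe, beyond cutoff from DLiPC: fraction 0
  sp0 <- synthetic_spec(chol_ld_fraction = 0, seed = 4)
  g0 <- generate_striped_membrane(sp0)
  expect_equal(chol_dlipc_contact_fraction(g0$frame)$value, 0)
})

test_that("contact statistics signal absent species and empty denominators", {
  fr <- make_frame(mol = 1:2, species = c("DLiPC", "DPPC"),
                   bead = rep("PO4", 2),
                   x = c(1, 5), y = c(1, 5), z = c(1, 5))
  expect_error(solute_dlipc_contact_fraction(fr, "OCT"),
               class = "lipidmix_unknown_species")
  # isolated lipids: zero total contacts is an undefined statistic
  expect_error(dlipc_dppc_contact_fraction(fr),
               class = "lipidmix_undefined_statistic")
})

test_that("contact-fraction series evaluate per frame and flag undefined frames", {
  g <- generate_striped_membrane(synthetic_spec(mixing_lambda = 1, seed = 9))
  traj <- const_trajectory(g$frame, n = 3)
  s <- contact_fraction_series(traj, "dlipc_dppc")
  expect_equal(nrow(s), 3)
  expect_equal(s$value, rep(s$value[1], 3))
  one <- membrane_trajectory(list(g$frame))
  expect_equal(nrow(contact_fraction_series(one, "chol_dlipc")), 1)
  expect_error(contact_fraction_series(traj, "voronoi"),
               class = "lipidmix_unknown_statistic")
})
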