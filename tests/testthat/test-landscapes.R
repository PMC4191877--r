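small_traj <- function(n_solute = 0, solute_mode = "uniform_midplane",
                       n_frames = 4, lambda = 0, seed = 15,
                       stripe_buffer = 1.2) {
  sp <- synthetic_spec(composition = composition_spec(n_solute = n_solute),
                       solute_mode = solute_mode, stripe_buffer = stripe_buffer,
                       seed = seed)
  lattice_mixing_series(sp, n_frames = n_frames,
                        schedule = list(type = "constant", lambda = lambda))
}

test_that("a point mass lands in exactly one grid cell", {
  fr <- make_frame(mol = 1:5, species = "OCT", bead = "S1",
                   x = rep(3.33, 5), y = rep(7.77, 5), z = rep(5, 5))
  traj <- const_trajectory(fr, n = 2)
  l <- partial_density_landscape(traj, "OCT", window = 1:2, bins = 50)
  expect_equal(sum(l$values > 0), 1)
  expect_equal(sum(l$values) * prod(l$cell_size), 5)
})

test_that("density landscapes conserve bead counts exactly", {
  ser <- small_traj(n_solute = 64)
  traj <- ser$trajectory
  for (spc in c("DLiPC", "DPPC", "CHOL", "OCT")) {
    l <- partial_density_landscape(traj, spc, window = 1:4)
    n_per_frame <- length(select_beads(traj$frames[[1]], spc, "ALL"))
    expect_equal(sum(l$values) * prod(l$cell_size), n_per_frame)
  }
})

test_that("uniformly placed beads give Poisson-compatible cell statistics", {
  set.seed(77)
  n <- 5000
  fr <- make_frame(mol = seq_len(n), species = "OCT", bead = "S1",
                   x = stats::runif(n, 0, 10), y = stats::runif(n, 0, 10),
                   z = rep(5, n))
  l <- partial_density_landscape(const_trajectory(fr, 1), "OCT",
                                 window = 1, bins = 20)
  counts <- l$values * prod(l$cell_size)
  # Poisson: variance/mean near 1 (index of dispersion, 400 cells)
  expect_lt(abs(stats::var(as.numeric(counts)) / mean(counts) - 1), 0.25)
})

test_that("the density-fraction landscape separates pure stripes and water gaps", {
  ser <- small_traj()
  fl <- dlipc_density_fraction_landscape(ser$trajectory, window = 1:4)
  v <- fl$values[!fl$undefined_mask]
  expect_true(all(v >= 0 & v <= 1))
  # cells well inside the stripes are pure
  geo <- ser$truth$geometry
  dx <- fl$box_xy[1] / fl$bins
  ld_cols <- which((seq_len(fl$bins) - 0.5) * dx > geo$x_ld[1] + 1 &
                     (seq_len(fl$bins) - 0.5) * dx < geo$x_ld[2] - 1)
  lo_cols <- which((seq_len(fl$bins) - 0.5) * dx > geo$x_lo[1] + 1 &
                     (seq_len(fl$bins) - 0.5) * dx < geo$x_lo[2] - 1)
  expect_true(all(fl$values[ld_cols, ] == 1, na.rm = TRUE))
  expect_true(all(fl$values[lo_cols, ] == 0, na.rm = TRUE))
  # lipid-free buffer columns are undefined
  gap_col <- round((geo$x_ld[2] + geo$x_lo[1]) / 2 / dx)
  expect_true(all(fl$undefined_mask[gap_col, ]))
})

test_that("an ideally mixed membrane clusters around the DLiPC molar fraction", {
  ser <- small_traj(lambda = 1, n_frames = 6)
  fl <- dlipc_density_fraction_landscape(ser$trajectory, window = 1:6)
  expect_lt(abs(mean(fl$values[!fl$undefined_mask]) - 540 / 1368), 0.04)
})

test_that("normalized solute density has unit mean and flags enrichment", {
  ser <- small_traj(n_solute = 200, solute_mode = "interface_band")
  nl <- normalized_solute_density_landscape(ser$trajectory, "OCT", window = 1:4)
  expect_equal(mean(nl$values), 1, tolerance = 1e-12)
  fl <- dlipc_density_fraction_landscape(ser$trajectory, window = 1:4)
  ic <- interface_cells(fl)
  expect_gt(solute_interface_enrichment(nl, ic, band_width = 2), 2)
  # uniformly placed solute: enrichment ratio near 1
  seru <- small_traj(n_solute = 400, solute_mode = "uniform_midplane")
  nlu <- normalized_solute_density_landscape(seru$trajectory, "OCT", window = 1:4)
  flu <- dlipc_density_fraction_landscape(seru$trajectory, window = 1:4)
  icu <- interface_cells(flu)
  expect_lt(abs(solute_interface_enrichment(nlu, icu, band_width = 2) - 1), 0.35)
})

test_that("interface detection follows the 0.5 crossing rule", {
  ser <- small_traj()
  fl <- dlipc_density_fraction_landscape(ser$trajectory, window = 1:4)
  # uniform fraction below the level: nothing marked
  uni <- fl; uni$values[] <- 0.39; uni$undefined_mask[] <- FALSE
  expect_equal(sum(interface_cells(uni)), 0)
  # one 0-cell adjacent to one 1-cell: both marked
  two <- fl; two$values[] <- 0.39; two$undefined_mask[] <- FALSE
  two$values[10, 10] <- 0; two$values[11, 10] <- 1
  ic <- interface_cells(two)
  expect_true(ic[10, 10] && ic[11, 10])
})

test_that("recovered interface bands sit at the generator's stripe boundaries", {
  for (buf in c(0, 1.2)) {
    ser <- small_traj(n_frames = 10, stripe_buffer = buf, seed = 13)
    fl <- dlipc_density_fraction_landscape(ser$trajectory, window = 1:10)
    ic <- interface_cells(fl)
    dx <- fl$box_xy[1] / fl$bins
    marked <- which(apply(ic, 1, any))
    for (ix in ser$truth$interface_x) {
      true_col <- ix / dx + 0.5
      near <- marked[pmin(abs(marked - true_col),
                          fl$bins - abs(marked - true_col)) <= 6]
      expect_gt(length(near), 0)
      # band center within one cell of the true interface (periodic mean)
      ang <- 2 * pi * near / fl$bins
      ctr <- atan2(mean(sin(ang)), mean(cos(ang))) * fl$bins / (2 * pi)
      dev <- abs(ctr - true_col) %% fl$bins
      expect_lte(min(dev, fl$bins - dev), 1.25)
    }
  }
})

test_that("fraction landscapes are invariant under lattice-vector translation", {
  ser <- small_traj(n_frames = 3)
  traj <- ser$trajectory
  dx <- traj$frames[[1]]$box[1] / 50
  shifted <- membrane_trajectory(lapply(traj$frames, translate_frame, dx = 3 * dx))
  f0 <- dlipc_density_fraction_landscape(traj, window = 1:3)
  f1 <- dlipc_density_fraction_landscape(shifted, window = 1:3)
  # rolling the original by 3 cells reproduces the shifted landscape
  rolled <- f0$values[((seq_len(50) - 1 - 3) %% 50) + 1, ]
  expect_equal(f1$values, rolled, tolerance = 1e-9)
})

test_that("landscapes serialize to matrix + sidecar and read back", {
  ser <- small_traj(n_solute = 64)
  l <- dlipc_density_fraction_landscape(ser$trajectory, window = 1:4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(l, p)
  back <- read_landscape(p)
  expect_equal(back$values, l$values, tolerance = 1e-9)
  expect_equal(back$quantity, l$quantity)
  expect_equal(back$cell_size, l$cell_size, tolerance = 1e-6)
  expect_equal(back$undefined_mask, l$undefined_mask)
})
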