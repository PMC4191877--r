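test_that("a minimal well-formed .gro file parses into beads and box", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("two beads t= 1.5",
               "    2",
               "    1DPPC   PO4    1   1.000   2.000   3.000",
               "    2CHOL   ROH    2   4.500   5.500   6.500",
               "  10.00000  10.00000   8.00000"), p)
  fr <- read_gro(p)
  expect_s3_class(fr, "membrane_frame")
  expect_equal(nrow(fr$beads), 2)
  expect_equal(fr$box, c(10, 10, 8))
  expect_equal(fr$time, 1.5)
  expect_equal(fr$beads$species, c("DPPC", "CHOL"))
  expect_equal(fr$beads$bead_name, c("PO4", "ROH"))
  expect_equal(fr$beads$x, c(1, 4.5))
})

test_that("write_gro / read_gro round-trips positions to 1e-3 nm", {
  g <- generate_striped_membrane(synthetic_spec(seed = 3))
  p <- withr::local_tempfile(fileext = ".gro")
  write_gro(g$frame, p)
  back <- read_gro(p)
  expect_equal(back$beads$x, round(g$frame$beads$x, 3), tolerance = 1e-9)
  expect_equal(back$beads$z, round(g$frame$beads$z, 3), tolerance = 1e-9)
  expect_identical(back$beads$species, g$frame$beads$species)
  expect_identical(back$beads$bead_name, g$frame$beads$bead_name)
  # 1944 lipid molecules carry 1944 distinct molecule indices
  expect_equal(length(unique(back$beads$molecule_index)), 1944)
})

test_that("malformed files raise parse errors naming the offending line", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("bad count", "    3",
               "    1DPPC   PO4    1   1.000   2.000   3.000",
               "  10.0 10.0 10.0"), p)
  err <- tryCatch(read_gro(p), error = identity)
  expect_s3_class(err, "lipidmix_parse_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c("bad box", "    1",
               "    1DPPC   PO4    1   1.000   2.000   3.000",
               "  ten ten ten"), p)
  expect_error(read_gro(p), class = "lipidmix_parse_error")
})

test_that("triclinic boxes are rejected, 9-field diagonal boxes accepted", {
  p <- withr::local_tempfile(fileext = ".gro")
  base <- c("f", "    1", "    1DPPC   PO4    1   1.000   2.000   3.000")
  writeLines(c(base, " 10.0 10.0 10.0 0.0 0.0 0.0 0.0 2.5 0.0"), p)
  expect_error(read_gro(p), class = "lipidmix_unsupported_box")
  writeLines(c(base, " 10.0 11.0 12.0 0.0 0.0 0.0 0.0 0.0 0.0"), p)
  expect_equal(read_gro(p)$box, c(10, 11, 12))
})

test_that("an empty frame writes an atom count of 0 plus a box line", {
  fr <- make_frame(integer(0), character(0), character(0),
                   numeric(0), numeric(0), numeric(0), box = c(5, 5, 5))
  p <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, p)
  lines <- readLines(p)
  expect_length(lines, 3)
  expect_equal(as.integer(trimws(lines[2])), 0)
  expect_equal(read_gro(p)$box, c(5, 5, 5))
})

test_that("multi-frame concatenated .gro round-trips as a trajectory", {
  sp <- synthetic_spec(composition = composition_spec(n_dlipc = 20, n_dppc = 30,
                                                      n_chol = 10),
                       box_xy = c(8, 8), seed = 5)
  ser <- lattice_mixing_series(sp, n_frames = 3,
                               schedule = list(type = "constant", lambda = 0))
  p <- withr::local_tempfile(fileext = ".gro")
  write_gro_trajectory(ser$trajectory, p)
  back <- read_gro_trajectory(p)
  expect_equal(n_frames(back), 3)
  expect_equal(back$times, ser$trajectory$times)
  expect_equal(back$frames[[2]]$beads$x,
               round(ser$trajectory$frames[[2]]$beads$x, 3), tolerance = 1e-9)
})
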