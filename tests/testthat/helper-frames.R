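# fixtures built in code: tiny hand-laid frames and random bead soups

# frame from parallel vectors; one row per bead
make_frame <- function(mol, species, bead, x, y, z, box = c(10, 10, 10),
                       time = 0, wrap = TRUE) {
  membrane_frame(data.frame(
    particle_index = seq_along(mol), molecule_index = mol,
    species = species, bead_name = bead, x = x, y = y, z = z,
    stringsAsFactors = FALSE), box = box, time = time, wrap = wrap)
}

# flat two-leaflet test bilayer: n x n PO4 lattice per leaflet at z0 +/- t/2
flat_bilayer <- function(n = 6, species = "DPPC", t = 4, z0 = 5,
                         box = c(10, 10, 10)) {
  g <- expand.grid(x = seq(0.5, box[1] - 0.5, length.out = n),
                   y = seq(0.5, box[2] - 0.5, length.out = n))
  nm <- nrow(g)
  make_frame(mol = seq_len(2 * nm),
             species = rep(species, 2 * nm),
             bead = rep("PO4", 2 * nm),
             x = rep(g$x, 2), y = rep(g$y, 2),
             z = c(rep(z0 + t / 2, nm), rep(z0 - t / 2, nm)),
             box = box)
}

# random multi-bead soup for oracle cross-checks
random_frame <- function(n_mol = 25, max_beads = 3, box = c(4, 5, 6),
                         species_pool = c("DLiPC", "DPPC", "CHOL", "OCT")) {
  nb <- sample.int(max_beads, n_mol, replace = TRUE)
  mol <- rep(seq_len(n_mol), nb)
  n <- length(mol)
  make_frame(mol = mol,
             species = rep(sample(species_pool, n_mol, replace = TRUE), nb),
             bead = paste0("B", sequence(nb)),
             x = stats::runif(n, 0, box[1]),
             y = stats::runif(n, 0, box[2]),
             z = stats::runif(n, 0, box[3]),
             box = box)
}

# rigid translation (with wrapping) of a whole frame
translate_frame <- function(frame, dx = 0, dy = 0, dz = 0) {
  frame$beads$x <- frame$beads$x + dx
  frame$beads$y <- frame$beads$y + dy
  frame$beads$z <- frame$beads$z + dz
  wrap_frame(frame)
}

const_trajectory <- function(frame, n = 3, dt = 1) {
  frames <- lapply(seq_len(n), function(i) { frame$time <- (i - 1) * dt; frame })
  membrane_trajectory(frames)
}
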