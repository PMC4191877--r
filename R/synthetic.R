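# Synthetic striped-membrane generator with known ground truth: stands in
# for microsecond MD trajectories so every analysis stage is testable.

#' Composition of the ternary membrane system
#'
#' Defaults to the reference ternary mixture of 540 DLiPC, 828 DPPC and
#' 576 cholesterol molecules.
#'
#' @param n_dlipc,n_dppc,n_chol,n_solute molecule counts.
#' @param solute_species solute species label (residue naming is
#'   force-field specific; the default is an octane-like label).
#' @return a `composition_spec` list.
#' @export
composition_spec <- function(n_dlipc = 540, n_dppc = 828, n_chol = 576,
                             n_solute = 0, solute_species = "OCT") {
  n <- c(n_dlipc, n_dppc, n_chol, n_solute)
  if (any(n < 0) || sum(n[1:3]) == 0)
    lm_stop("counts must be >= 0 with at least one lipid",
            "lipidmix_invalid_spec")
  structure(list(n_dlipc = as.integer(n_dlipc), n_dppc = as.integer(n_dppc),
                 n_chol = as.integer(n_chol), n_solute = as.integer(n_solute),
                 solute_species = solute_species),
            class = "composition_spec")
}

#' Specification of a synthetic striped membrane
#'
#' Ground-truth parameters for [generate_striped_membrane()]. The defaults
#' emulate the reference study conditions: the 540/828/576 ternary
#' composition on a ~20 x 20 nm bilayer (about 0.4 nm grid cells at 50
#' bins per axis), two stripe domains separated by a lipid-free buffer
#' wider than the 1.1 nm contact cutoff, liquid-ordered / liquid-
#' disordered thicknesses of 4.2 / 3.8 nm, and 10% of cholesterol in the
#' Ld stripe.
#'
#' @param composition a [composition_spec()].
#' @param box_xy lateral box lengths (Lx, Ly), nm.
#' @param box_z box height, nm.
#' @param mixing_lambda degree of lipid mixing in `[0, 1]`: 0 is fully
#'   phase-separated stripes, 1 a fully random lateral arrangement.
#' @param solute_mode solute placement: `"uniform_midplane"` (square grid
#'   at the bilayer midplane), `"interface_band"` (uniform within
#'   `interface_band_width` of either stripe interface) or
#'   `"ld_partition"` (uniform in the Ld stripe interior).
#' @param interface_band_width width of the interface placement band, nm.
#' @param phase_thickness named vector `c(Lo =, Ld =)` of per-phase
#'   bilayer thicknesses, nm.
#' @param position_jitter standard deviation of Gaussian positional
#'   noise applied to every bead coordinate, nm.
#' @param chol_ld_fraction fraction of cholesterol placed in the Ld
#'   stripe (the remainder goes to the Lo stripe).
#' @param beads_per_lipid beads per phospholipid (identical for DPPC and
#'   DLiPC, which preserves the analytic 0.39 bead-counting limit of the
#'   solute statistic).
#' @param stripe_buffer lipid-free gap between the stripes at each
#'   interface, nm; the default exceeds the 1.1 nm lipid contact cutoff
#'   so a fully separated membrane scores exactly 0 lipid mixing.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(composition = composition_spec(),
                           box_xy = c(20, 20), box_z = 10,
                           mixing_lambda = 0,
                           solute_mode = c("uniform_midplane",
                                           "interface_band", "ld_partition"),
                           interface_band_width = 1.0,
                           phase_thickness = c(Lo = 4.2, Ld = 3.8),
                           position_jitter = 0.05,
                           chol_ld_fraction = 0.1,
                           beads_per_lipid = 12L,
                           stripe_buffer = 1.2,
                           seed = 1L) {
  solute_mode <- match.arg(solute_mode)
  if (mixing_lambda < 0 || mixing_lambda > 1)
    lm_stop("mixing_lambda must lie in [0, 1]", "lipidmix_invalid_spec")
  if (any(phase_thickness <= 0) || !all(c("Lo", "Ld") %in% names(phase_thickness)))
    lm_stop("phase_thickness must be positive and name Lo and Ld",
            "lipidmix_invalid_spec")
  if (position_jitter < 0)
    lm_stop("position_jitter must be >= 0", "lipidmix_invalid_spec")
  if (chol_ld_fraction < 0 || chol_ld_fraction > 1)
    lm_stop("chol_ld_fraction must lie in [0, 1]", "lipidmix_invalid_spec")
  structure(list(composition = composition, box_xy = as.numeric(box_xy),
                 box_z = box_z, mixing_lambda = mixing_lambda,
                 solute_mode = solute_mode,
                 interface_band_width = interface_band_width,
                 phase_thickness = phase_thickness,
                 position_jitter = position_jitter,
                 chol_ld_fraction = chol_ld_fraction,
                 beads_per_lipid = as.integer(beads_per_lipid),
                 stripe_buffer = stripe_buffer,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic small-integer stream of derived seeds, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

# stripe geometry shared by the generator and ground-truth bookkeeping
stripe_geometry <- function(spec) {
  comp <- spec$composition
  n_chol_ld <- round(spec$chol_ld_fraction * comp$n_chol)
  n_ld <- comp$n_dlipc + n_chol_ld
  n_lo <- comp$n_dppc + (comp$n_chol - n_chol_ld)
  usable <- spec$box_xy[1] - 2 * spec$stripe_buffer
  if (usable <= 0)
    lm_stop("box too small for the stripe buffer", "lipidmix_box_too_small")
  w_ld <- usable * n_ld / (n_ld + n_lo)
  w_lo <- usable - w_ld
  list(n_chol_ld = n_chol_ld,
       x_ld = c(0, w_ld),
       x_lo = c(w_ld + spec$stripe_buffer,
                w_ld + spec$stripe_buffer + w_lo),
       interface_x = c(w_ld + spec$stripe_buffer / 2,
                       spec$box_xy[1] - spec$stripe_buffer / 2))
}

# lattice of >= n sites filling [x0, x1) x [0, Ly); same lattice is reused
# for both leaflets so thickness grid cells are sampled in both
stripe_lattice <- function(n, x0, x1, ly) {
  w <- x1 - x0
  n_cols <- max(1L, round(sqrt(n * w / ly)))
  n_rows <- ceiling(n / n_cols)
  dx <- w / n_cols; dy <- ly / n_rows
  if (min(dx, dy) < 0.55)
    lm_stop("box too small for the composition at physical packing (< 0.55 nm lattice spacing)",
            "lipidmix_box_too_small")
  g <- expand.grid(i = seq_len(n_cols), j = seq_len(n_rows))
  list(x = x0 + (g$i - 0.5) * dx, y = (g$j - 0.5) * dy, dx = dx, dy = dy)
}

# one stripe's molecules for both leaflets: species assignment is seeded
# by the caller's RNG state
stripe_molecules <- function(species_counts, xr, ly) {
  n_tot <- sum(species_counts)
  n_up <- ceiling(n_tot / 2)
  n_low <- n_tot - n_up
  lat <- stripe_lattice(max(n_up, n_low), xr[1], xr[2], ly)
  pool <- sample(rep(names(species_counts), species_counts))
  up <- data.frame(species = pool[seq_len(n_up)],
                   x = lat$x[seq_len(n_up)], y = lat$y[seq_len(n_up)],
                   leaflet = "upper", stringsAsFactors = FALSE)
  low <- data.frame(species = pool[n_up + seq_len(n_low)],
                    x = lat$x[seq_len(n_low)], y = lat$y[seq_len(n_low)],
                    leaflet = "lower", stringsAsFactors = FALSE)
  rbind(up, low)
}

# expand one molecule row into its bead stack
lipid_bead_stack <- function(species, beads_per_lipid) {
  if (species == "CHOL") {
    list(names = c("ROH", paste0("R", 1:7)), n = 8L)
  } else {
    list(names = c("PO4", paste0("C", seq_len(beads_per_lipid - 1L))),
         n = beads_per_lipid)
  }
}

#' Generate a two-stripe synthetic membrane with ground truth
#'
#' Builds one membrane frame with two phase stripes along x whose areas
#' are proportional to their lipid counts, separated by a lipid-free
#' buffer at both interfaces (the box is periodic). At `mixing_lambda = 0`
#' the Ld stripe holds all DLiPC plus `chol_ld_fraction` of the
#' cholesterol and the Lo stripe holds all DPPC plus the remaining
#' cholesterol. Lipids sit on jittered lattices in both leaflets; each
#' phospholipid carries a PO4 bead at the leaflet surface (z from the
#' per-phase thickness) with its remaining beads stacked toward the
#' midplane, cholesterol an ROH bead plus 7 stacked beads. Solutes are
#' placed according to `solute_mode`. Generation is deterministic given
#' the spec (including its seed). If `mixing_lambda > 0` the frame is
#' passed through [mix_membrane()].
#'
#' @param spec a [synthetic_spec()].
#' @return list with `frame` (a [membrane_frame()] with leaflet labels)
#'   and `truth` (per-molecule phase and leaflet table, interface
#'   x-positions, stripe geometry, and the spec).
#' @export
generate_striped_membrane <- function(spec) {
  base <- striped_membrane_ideal(spec)
  fr <- apply_position_jitter(base$frame, spec$position_jitter,
                              derive_seed(spec$seed, 1))
  out <- list(frame = fr, truth = base$truth)
  if (spec$mixing_lambda > 0)
    out <- mix_membrane(out$frame, out$truth, spec$mixing_lambda,
                        derive_seed(spec$seed, 2))
  out
}

# ideal (jitter-free) frame + ground truth; all randomness under spec$seed
striped_membrane_ideal <- function(spec) {
  comp <- spec$composition
  geo <- stripe_geometry(spec)
  with_seed(spec$seed, {
    ld <- stripe_molecules(c(DLiPC = comp$n_dlipc, CHOL = geo$n_chol_ld),
                           geo$x_ld, spec$box_xy[2])
    lo <- stripe_molecules(c(DPPC = comp$n_dppc,
                             CHOL = comp$n_chol - geo$n_chol_ld),
                           geo$x_lo, spec$box_xy[2])
    ld$phase <- "Ld"; lo$phase <- "Lo"
    mols <- rbind(ld, lo)
    sol <- solute_positions(spec, geo)
    build_frame_from_molecules(spec, mols, sol, geo)
  })
}

solute_positions <- function(spec, geo) {
  n <- spec$composition$n_solute
  if (n == 0) return(NULL)
  lx <- spec$box_xy[1]; ly <- spec$box_xy[2]
  if (spec$solute_mode == "uniform_midplane") {
    n_cols <- ceiling(sqrt(n * lx / ly))
    n_rows <- ceiling(n / n_cols)
    g <- expand.grid(i = seq_len(n_cols), j = seq_len(n_rows))
    x <- ((g$i - 0.5) * lx / n_cols)[seq_len(n)]
    y <- ((g$j - 0.5) * ly / n_rows)[seq_len(n)]
  } else if (spec$solute_mode == "interface_band") {
    which_if <- sample(1:2, n, replace = TRUE)
    x <- geo$interface_x[which_if] +
      stats::runif(n, -spec$interface_band_width / 2,
                   spec$interface_band_width / 2)
    x <- x %% lx
    y <- stats::runif(n, 0, ly)
  } else { # ld_partition: stripe interior, clear of both interfaces
    margin <- min(1.0, diff(geo$x_ld) / 4)
    x <- stats::runif(n, geo$x_ld[1] + margin, geo$x_ld[2] - margin)
    y <- stats::runif(n, 0, ly)
  }
  data.frame(species = spec$composition$solute_species, x = x, y = y,
             leaflet = "none", phase = NA_character_,
             stringsAsFactors = FALSE)
}

build_frame_from_molecules <- function(spec, mols, sol, geo) {
  z0 <- spec$box_z / 2
  all_mols <- rbind(mols, sol)
  n_mol <- nrow(all_mols)
  is_lipid <- all_mols$species %in% c("DLiPC", "DPPC", "CHOL")
  is_chol <- all_mols$species == "CHOL"
  nb <- ifelse(!is_lipid, 1L, ifelse(is_chol, 8L, spec$beads_per_lipid))
  mol_of_bead <- rep(seq_len(n_mol), nb)
  k <- sequence(nb) - 1L
  # leaflet-surface and innermost-bead z per molecule
  sgn <- ifelse(all_mols$leaflet == "upper", 1, -1)
  thick <- ifelse(is.na(all_mols$phase), 0,
                  unname(spec$phase_thickness[all_mols$phase]))
  zs <- ifelse(is_lipid, z0 + sgn * thick / 2, z0)
  z_end <- ifelse(is_lipid, z0 + sgn * 0.15, z0)
  denom <- pmax(nb - 1L, 1L)
  z <- zs[mol_of_bead] +
    (z_end[mol_of_bead] - zs[mol_of_bead]) * k / denom[mol_of_bead]
  pl_names <- c("PO4", paste0("C", seq_len(spec$beads_per_lipid - 1L)))
  chol_names <- c("ROH", paste0("R", 1:7))
  name_of <- function(m) {
    if (!is_lipid[m]) "S1" else if (is_chol[m]) chol_names else pl_names
  }
  bead_name <- unlist(lapply(seq_len(n_mol), name_of), use.names = FALSE)
  beads <- data.frame(
    particle_index = seq_along(mol_of_bead),
    molecule_index = mol_of_bead,
    species = all_mols$species[mol_of_bead],
    bead_name = bead_name,
    x = all_mols$x[mol_of_bead],
    y = all_mols$y[mol_of_bead],
    z = z,
    leaflet = all_mols$leaflet[mol_of_bead],
    stringsAsFactors = FALSE)
  fr <- membrane_frame(beads, box = c(spec$box_xy, spec$box_z), time = 0)
  truth <- structure(
    list(molecules = data.frame(molecule_index = seq_len(n_mol),
                                species = all_mols$species,
                                phase = all_mols$phase,
                                leaflet = all_mols$leaflet,
                                stringsAsFactors = FALSE),
         interface_x = geo$interface_x,
         geometry = geo,
         spec = spec),
    class = "membrane_ground_truth")
  list(frame = fr, truth = truth)
}

# Gaussian positional noise on every bead coordinate; seeded, wrapped
apply_position_jitter <- function(frame, sd, seed) {
  if (sd <= 0) return(frame)
  n <- nrow(frame$beads)
  with_seed(seed, {
    frame$beads$x <- frame$beads$x + stats::rnorm(n, 0, sd)
    frame$beads$y <- frame$beads$y + stats::rnorm(n, 0, sd)
    frame$beads$z <- frame$beads$z + stats::rnorm(n, 0, sd)
  })
  wrap_frame(frame)
}

#' Mix a striped membrane by random exchange of phospholipid sites
#'
#' Selects a fraction `lambda` of the DLiPC and of the DPPC molecules in
#' each leaflet and randomly permutes the selected molecules over the
#' selected lattice sites; whole molecules exchange sites (a relocated
#' lipid adopts the site geometry, including the local leaflet-surface
#' height) and leaflets are preserved. Because both phospholipids carry
#' identical bead stacks, this is realized as a species-label permutation
#' over the selected sites. `lambda = 0` is the identity; `lambda = 1`
#' permutes every phospholipid over every phospholipid site of its
#' leaflet, a fully random lateral arrangement whose expected
#' lipid-mixing fraction is the DPPC phospholipid molar fraction
#' (828/1368 = 0.605 at the reference composition). Ground-truth phase
#' labels are refreshed from the stripe each molecule ends up in (`NA`
#' inside the buffer gaps).
#'
#' @param frame a generated [membrane_frame()].
#' @param truth its ground truth (from [generate_striped_membrane()]).
#' @param lambda mixing degree in `[0, 1]`.
#' @param seed integer seed.
#' @return list with the mixed `frame` and updated `truth`.
#' @export
mix_membrane <- function(frame, truth, lambda, seed) {
  if (lambda < 0 || lambda > 1)
    lm_stop("lambda must lie in [0, 1]", "lipidmix_invalid_spec")
  if (lambda == 0) return(list(frame = frame, truth = truth))
  b <- frame$beads
  mt <- truth$molecules
  nb_per_pl <- sum(b$molecule_index == mt$molecule_index[
    match("DLiPC", mt$species)])
  first_row <- match(mt$molecule_index, b$molecule_index)
  names(first_row) <- mt$molecule_index
  with_seed(seed, {
    for (lf in c("upper", "lower")) {
      dl <- mt$molecule_index[mt$species == "DLiPC" & mt$leaflet == lf]
      dp <- mt$molecule_index[mt$species == "DPPC" & mt$leaflet == lf]
      pick <- function(v, k) if (k == 0) integer(0) else
        v[sample.int(length(v), k)]
      sel <- c(pick(dl, round(lambda * length(dl))),
               pick(dp, round(lambda * length(dp))))
      if (length(sel) < 2) next
      perm <- sample.int(length(sel))
      off <- seq_len(nb_per_pl) - 1L
      tgt <- rep(first_row[as.character(sel)], each = nb_per_pl) + off
      src <- rep(first_row[as.character(sel[perm])], each = nb_per_pl) + off
      b[tgt, c("x", "y", "z")] <- b[src, c("x", "y", "z")]
    }
  })
  frame$beads <- b
  # refresh phase labels from final lateral positions
  geo <- truth$geometry
  x <- b$x[first_row]
  is_lipid <- mt$species %in% c("DLiPC", "DPPC", "CHOL")
  ph <- rep(NA_character_, nrow(mt))
  ph[x >= geo$x_ld[1] & x < geo$x_ld[2]] <- "Ld"
  ph[x >= geo$x_lo[1] & x < geo$x_lo[2]] <- "Lo"
  ph[!is_lipid] <- NA_character_
  truth$molecules$phase <- ph
  list(frame = frame, truth = truth)
}

#' Validate a mixing-series schedule
#'
#' Two schedule shapes are understood: `list(type = "two_stage",
#' stage_a_end =, lambda_max =)`, in which solutes first relocate from a
#' uniform midplane grid to the interface band (stage A) and lipid mixing
#' then ramps from 0 to `lambda_max` (stage B); and `list(type =
#' "constant", lambda =)`, a statistically stationary series.
#'
#' @param schedule schedule list.
#' @return the schedule, with defaults filled in.
#' @keywords internal
validate_schedule <- function(schedule) {
  if (!is.list(schedule) || is.null(schedule$type) ||
      !schedule$type %in% c("two_stage", "constant"))
    lm_stop("malformed schedule: need list(type = 'two_stage'|'constant', ...)",
            "lipidmix_invalid_schedule")
  if (schedule$type == "two_stage") {
    if (is.null(schedule$stage_a_end)) schedule$stage_a_end <- 0.3
    if (is.null(schedule$lambda_max)) schedule$lambda_max <- 1
    if (schedule$stage_a_end <= 0 || schedule$stage_a_end >= 1 ||
        schedule$lambda_max < 0 || schedule$lambda_max > 1)
      lm_stop("malformed schedule: stage_a_end must be in (0,1), lambda_max in [0,1]",
              "lipidmix_invalid_schedule")
  } else {
    if (is.null(schedule$lambda)) schedule$lambda <- 0
    if (schedule$lambda < 0 || schedule$lambda > 1)
      lm_stop("malformed schedule: lambda must be in [0,1]",
              "lipidmix_invalid_schedule")
  }
  schedule
}

#' Generate a frame series tracing the linactant mechanism
#'
#' Produces a deterministic trajectory that emulates the two-stage
#' mechanism seen for aliphatic (line-active) solutes on phase-separated
#' membranes: in stage A the solutes relocate from a uniform in-plane
#' distribution to the stripe interfaces while the lipids stay fully
#' separated; in stage B the solutes remain interfacial while lipid
#' mixing ramps up. Each frame is built from the same ideal lattice with
#' fresh positional jitter and an independently seeded mixing draw, so a
#' constant schedule yields a statistically stationary series.
#'
#' @param spec a [synthetic_spec()]; for the two-stage schedule its
#'   composition must include solutes.
#' @param n_frames number of frames (>= 2).
#' @param schedule see [validate_schedule()].
#' @param time_step frame spacing, ns.
#' @return list with `trajectory` (a [membrane_trajectory()]) and `truth`
#'   (ground truth of the underlying lattice).
#' @export
lattice_mixing_series <- function(spec, n_frames,
                                  schedule = list(type = "two_stage",
                                                  stage_a_end = 0.3,
                                                  lambda_max = 1),
                                  time_step = 1) {
  if (n_frames < 2)
    lm_stop("n_frames must be >= 2", "lipidmix_invalid_spec")
  schedule <- validate_schedule(schedule)
  two_stage <- schedule$type == "two_stage"
  if (two_stage) spec$solute_mode <- "uniform_midplane"
  base <- striped_membrane_ideal(spec)
  geo <- base$truth$geometry
  sol_mols <- base$truth$molecules$molecule_index[
    !base$truth$molecules$species %in% c("DLiPC", "DPPC", "CHOL")]
  n_sol <- length(sol_mols)
  sol_rows <- base$frame$beads$molecule_index %in% sol_mols
  start_x <- base$frame$beads$x[sol_rows]
  start_y <- base$frame$beads$y[sol_rows]
  if (two_stage && n_sol > 0) {
    tgt <- with_seed(derive_seed(spec$seed, 3), {
      spec_if <- spec; spec_if$solute_mode <- "interface_band"
      solute_positions(spec_if, geo)
    })
  }
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    frac <- (i - 1) / (n_frames - 1)
    fr <- base$frame
    if (two_stage) {
      lambda_i <- if (frac <= schedule$stage_a_end) 0 else
        schedule$lambda_max * (frac - schedule$stage_a_end) /
          (1 - schedule$stage_a_end)
      if (n_sol > 0) {
        # relocation completes at 70% of stage A so the trace shows an
        # interfacial plateau at constant mixing before stage B begins
        p <- min(1, frac / (0.7 * schedule$stage_a_end))
        fr$beads$x[sol_rows] <- (1 - p) * start_x + p * tgt$x
        fr$beads$y[sol_rows] <- (1 - p) * start_y + p * tgt$y
      }
    } else {
      lambda_i <- schedule$lambda
    }
    fr <- apply_position_jitter(fr, spec$position_jitter,
                                derive_seed(spec$seed, 10 + 2 * i))
    if (lambda_i > 0)
      fr <- mix_membrane(fr, base$truth, lambda_i,
                         derive_seed(spec$seed, 11 + 2 * i))$frame
    fr$time <- (i - 1) * time_step
    frames[[i]] <- fr
  }
  list(trajectory = membrane_trajectory(frames), truth = base$truth)
}

#' Write the per-molecule ground truth as a tab-separated table
#'
#' The table has one row per molecule (index, species, phase, leaflet);
#' `#`-prefixed header lines record the interface x-positions and the
#' main spec parameters.
#'
#' @param truth ground truth from [generate_striped_membrane()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  spec <- truth$spec
  hdr <- c(
    sprintf("# interface_x_nm: %s", paste(sprintf("%.4f", truth$interface_x), collapse = " ")),
    sprintf("# mixing_lambda: %g", spec$mixing_lambda),
    sprintf("# solute_mode: %s", spec$solute_mode),
    sprintf("# phase_thickness_nm: Lo=%g Ld=%g",
            spec$phase_thickness[["Lo"]], spec$phase_thickness[["Ld"]]),
    sprintf("# seed: %d", spec$seed))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(truth$molecules, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
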