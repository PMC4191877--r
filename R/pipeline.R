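# Pipeline layer: one-call analysis into a summary report, landscapes and
# thickness results; mechanism phase plane; mixing-vs-molar-fraction curve.

#' Analysis configuration
#'
#' Collects every analysis parameter in one serializable object: contact
#' cutoffs (1.1 nm for lipid-lipid and cholesterol statistics, 0.8 nm for
#' the all-particle solute statistic), the 50-bin landscape grid, and the
#' averaging windows (contacts: final 5000 ns of a run or, for short
#' synthetic series, the final half of the frames; landscapes and
#' thickness: final 500 ns or the final tenth).
#'
#' @param input path to a `.gro` file or concatenated `.gro` trajectory
#'   (optional when a trajectory object is passed to [analyze()]).
#' @param solute solute species label, or `NULL` for a solute-free system.
#' @param species_map residue-name to species mapping.
#' @param lipid_cutoff,solute_cutoff,chol_cutoff contact cutoffs, nm.
#' @param bins landscape grid bins per axis.
#' @param contact_window,landscape_window averaging windows,
#'   `list(last_ns =, last_frac =)`.
#' @param out_dir output directory for serialized results, or `NULL` to
#'   skip writing.
#' @param system_label label for the report row.
#' @param temperature temperature in K, carried as metadata only.
#' @param seed integer seed (pipeline stages are deterministic; the seed
#'   is recorded for provenance).
#' @param quiet suppress per-stage log lines.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, solute = NULL,
                            species_map = default_species_map(),
                            lipid_cutoff = 1.1, solute_cutoff = 0.8,
                            chol_cutoff = 1.1, bins = 50L,
                            contact_window = list(last_ns = 5000, last_frac = 0.5),
                            landscape_window = list(last_ns = 500, last_frac = 0.1),
                            out_dir = NULL, system_label = "system",
                            temperature = 295, seed = 1L, quiet = TRUE) {
  if (any(c(lipid_cutoff, solute_cutoff, chol_cutoff) <= 0))
    lm_stop("cutoffs must be > 0", "lipidmix_invalid_config")
  if (bins < 2) lm_stop("bins must be >= 2", "lipidmix_invalid_config")
  structure(list(input = input, solute = solute, species_map = species_map,
                 lipid_cutoff = lipid_cutoff, solute_cutoff = solute_cutoff,
                 chol_cutoff = chol_cutoff, bins = as.integer(bins),
                 contact_window = contact_window,
                 landscape_window = landscape_window,
                 out_dir = out_dir, system_label = system_label,
                 temperature = temperature, seed = as.integer(seed),
                 quiet = isTRUE(quiet)),
            class = "analysis_config")
}

stage_log <- function(config, fmt, ...) {
  if (!config$quiet) message(sprintf(paste0("[lipidmix] ", fmt), ...))
}

run_stage <- function(config, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    lm_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "lipidmix_stage_error")
  })
  stage_log(config, "stage %-12s done in %.2f s", stage,
            proc.time()[["elapsed"]] - t0)
  out
}

#' Solute/lipid molar ratio in percent
#'
#' `100 * n_solute / (n_dlipc + n_dppc + n_chol)`, reported to 2 decimals.
#' At the reference composition (1944 lipids) 64 solutes give 3.29% and
#' 547 give 28.14%.
#'
#' @param n_solute solute molecule count.
#' @param composition a [composition_spec()].
#' @return percent, rounded to 2 decimals.
#' @export
molar_ratio <- function(n_solute, composition = composition_spec()) {
  tot <- composition$n_dlipc + composition$n_dppc + composition$n_chol
  if (tot <= 0) lm_stop("total lipid count must be > 0", "lipidmix_invalid_spec")
  round_half_up(100 * n_solute / tot, 2)
}

#' Run the full analysis pipeline on a trajectory
#'
#' Computes the three contact-fraction statistics with block-averaged
#' errors over the contact window, the partial-density, density-fraction
#' and (if a solute is configured) normalized-solute landscapes over the
#' landscape window, and the thickness landscape with per-phase thickness
#' and Lo-Ld mismatch; optionally serializes everything under
#' `config$out_dir`. Deterministic given inputs and configuration.
#'
#' @param config an [analysis_config()].
#' @param traj a [membrane_trajectory()]; when `NULL`, read from
#'   `config$input`.
#' @return list with `report` (one-row data.frame), `contacts` (list of
#'   `contact_fraction_result`), `landscapes` (named list), and
#'   `thickness` (landscape, per-phase thickness, mismatch, histograms).
#' @export
analyze <- function(config, traj = NULL) {
  if (is.null(traj)) {
    if (is.null(config$input))
      lm_stop("no input: set config$input or pass a trajectory",
              "lipidmix_invalid_config")
    traj <- run_stage(config, "read",
                      read_gro_trajectory(config$input, config$species_map))
  }
  traj <- run_stage(config, "leaflets", {
    needs <- vapply(traj$frames,
                    function(f) all(is.na(f$beads$leaflet)) ||
                      all(f$beads$leaflet == "none"), logical(1))
    if (any(needs))
      traj$frames[needs] <- lapply(traj$frames[needs], assign_leaflets)
    traj
  })
  fr1 <- traj$frames[[1]]
  has_chol <- "CHOL" %in% known_species(fr1)
  solute <- config$solute
  if (!is.null(solute) && !solute %in% known_species(fr1))
    lm_stop(sprintf("configured solute '%s' absent from input", solute),
            "lipidmix_unknown_species")

  cw <- resolve_window(traj, config$contact_window, last_ns = 5000,
                       last_frac = 0.5)
  # block averaging needs at least 4 window frames; widen on short series
  if (length(cw) < 4 && n_frames(traj) >= 4)
    cw <- seq.int(n_frames(traj) - 3L, n_frames(traj))
  contacts <- run_stage(config, "contacts", {
    out <- list()
    blk_of <- function(statistic, cutoff, sol = NULL) {
      s <- contact_fraction_series(traj, statistic, solute = sol,
                                   cutoff = cutoff)
      blk <- if (length(cw) >= 4) {
        block_average_error(s$value[cw], tail_fraction = 1)
      } else {
        list(mean = mean(s$value[cw], na.rm = TRUE), error = NA_real_)
      }
      counts <- stats::setNames(integer(0), character(0))
      contact_fraction_result(statistic, blk$mean, cutoff, counts,
                              n_frames = length(cw), error = blk$error)
    }
    out$dlipc_dppc <- blk_of("dlipc_dppc", config$lipid_cutoff)
    if (!is.null(solute))
      out$solute_dlipc <- blk_of("solute_dlipc", config$solute_cutoff, solute)
    if (has_chol)
      out$chol_dlipc <- blk_of("chol_dlipc", config$chol_cutoff)
    out
  })
  stage_log(config, "contacts used %d frames", length(cw))

  lw <- config$landscape_window
  landscapes <- run_stage(config, "landscapes", {
    out <- list(
      dlipc_density = partial_density_landscape(traj, "DLiPC", "ALL", lw, config$bins),
      dppc_density = partial_density_landscape(traj, "DPPC", "ALL", lw, config$bins),
      fraction = dlipc_density_fraction_landscape(traj, lw, config$bins))
    if (has_chol)
      out$chol_density <- partial_density_landscape(traj, "CHOL", "ALL", lw, config$bins)
    if (!is.null(solute))
      out$solute_normalized <-
        normalized_solute_density_landscape(traj, solute, lw, config$bins)
    out
  })

  thickness <- run_stage(config, "thickness", {
    tl <- thickness_landscape(traj, lw, config$bins)
    pt <- tryCatch(phase_thickness(tl, landscapes$fraction),
                   lipidmix_empty_phase = function(e) phase_thickness(tl))
    list(landscape = tl, phase_thickness = pt$thickness,
         mismatch = pt$mismatch, histograms = pt$histograms)
  })

  comp_counts <- table(fr1$beads$species[!duplicated(fr1$beads$molecule_index)])
  n_of <- function(sp) if (sp %in% names(comp_counts)) as.integer(comp_counts[[sp]]) else 0L
  comp <- composition_spec(n_of("DLiPC"), n_of("DPPC"), n_of("CHOL"),
                           if (is.null(solute)) 0L else n_of(solute),
                           if (is.null(solute)) "none" else solute)
  val_of <- function(r) if (is.null(r)) NA_real_ else r$value
  err_of <- function(r) if (is.null(r)) NA_real_ else r$error
  report <- data.frame(
    system = config$system_label,
    solute = if (is.null(solute)) "none" else solute,
    n_solute = comp$n_solute,
    molar_ratio = molar_ratio(comp$n_solute, comp),
    temperature = config$temperature,
    f_mix = val_of(contacts$dlipc_dppc),
    f_mix_err = err_of(contacts$dlipc_dppc),
    solute_dlipc = val_of(contacts$solute_dlipc),
    solute_dlipc_err = err_of(contacts$solute_dlipc),
    chol_dlipc = val_of(contacts$chol_dlipc),
    chol_dlipc_err = err_of(contacts$chol_dlipc),
    stringsAsFactors = FALSE)

  if (!is.null(config$out_dir)) {
    run_stage(config, "write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(config$out_dir, f)
      utils::write.table(report, p("report.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_contact_table(contacts, p("contacts.tsv"))
      for (nm in names(landscapes))
        write_landscape(landscapes[[nm]], p(paste0("landscape_", nm, ".tsv")))
      write_landscape(thickness$landscape, p("landscape_thickness.tsv"))
      for (nm in names(thickness$histograms))
        write_thickness_histogram(thickness$histograms[[nm]],
                                  p(paste0("thickness_hist_", nm, ".tsv")))
      invisible(NULL)
    })
  }
  list(report = report, contacts = contacts, landscapes = landscapes,
       thickness = thickness)
}

#' Mechanism phase plane: lipid mixing vs. solute partitioning over time
#'
#' Pairs the per-frame solute-DLiPC contact fraction with the per-frame
#' DLiPC-DPPC mixing fraction, the trace that separates the linactant
#' mechanism (solute first moves to the interface, solute fraction
#' approaching 0.5 at constant mixing, then mixing rises) from direct
#' phase partitioning. Reference values are attached: 0.5 (solute fully
#' interfacial) and 0.39 (ideal solute mixing at the reference
#' composition).
#'
#' @param traj a [membrane_trajectory()].
#' @param solute solute species label.
#' @param config an [analysis_config()].
#' @return data.frame with columns `time`, `solute_dlipc`, `f_mix`;
#'   attribute `reference` holds the 0.5 / 0.39 guide values.
#' @export
phase_plane <- function(traj, solute, config = analysis_config()) {
  s_sol <- contact_fraction_series(traj, "solute_dlipc", solute = solute,
                                   cutoff = config$solute_cutoff)
  s_mix <- contact_fraction_series(traj, "dlipc_dppc",
                                   cutoff = config$lipid_cutoff)
  out <- data.frame(time = traj$times, solute_dlipc = s_sol$value,
                    f_mix = s_mix$value)
  attr(out, "reference") <- c(interface = 0.5, ideal_mixing = 0.39)
  out
}

#' Write a phase-plane series as a 3-column table
#'
#' @param series output of [phase_plane()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_phase_plane <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Lipid mixing as a function of solute molar fraction
#'
#' Builds the mixing-vs-linactant-concentration curve on generator input:
#' for each solute count the mixing degree lambda is set by a
#' user-supplied response function of the solute molar fraction
#' (clamped to `[0, 1]`), membranes are generated over several seeds, and
#' the mean lipid-mixing fraction with its seed-to-seed standard error is
#' reported. The curve demonstrates the aggregation path; the response of
#' real membranes to a linactant is an outcome of molecular dynamics, not
#' of this generator.
#'
#' @param n_solutes vector (length >= 2, distinct) of solute counts.
#' @param response function mapping solute molar fraction
#'   `n / (n + n_lipids)` to a mixing degree lambda.
#' @param spec a [synthetic_spec()] template.
#' @param n_seeds seeds per point.
#' @return data.frame with `n_solute`, `molar_fraction`, `lambda`,
#'   `f_mix`, `f_mix_err`.
#' @export
mixing_curve <- function(n_solutes, response = function(mf) pmin(1, 10 * mf),
                         spec = synthetic_spec(), n_seeds = 3) {
  if (length(n_solutes) < 2)
    lm_stop("mixing_curve needs at least 2 points", "lipidmix_invalid_spec")
  comp <- spec$composition
  n_lip <- comp$n_dlipc + comp$n_dppc + comp$n_chol
  mf <- n_solutes / (n_solutes + n_lip)
  if (anyDuplicated(mf))
    lm_stop("duplicate solute molar fractions", "lipidmix_invalid_spec")
  rows <- lapply(seq_along(n_solutes), function(i) {
    lam <- min(1, max(0, response(mf[i])))
    vals <- vapply(seq_len(n_seeds), function(s) {
      sp <- spec
      sp$composition$n_solute <- as.integer(n_solutes[i])
      sp$mixing_lambda <- lam
      sp$seed <- derive_seed(spec$seed, 100 + 37 * i + s)
      g <- generate_striped_membrane(sp)
      r <- tryCatch(dlipc_dppc_contact_fraction(g$frame),
                    lipidmix_undefined_statistic = function(e) NULL)
      if (is.null(r)) NA_real_ else r$value
    }, numeric(1))
    data.frame(n_solute = n_solutes[i], molar_fraction = mf[i],
               lambda = lam, f_mix = mean(vals, na.rm = TRUE),
               f_mix_err = stats::sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals))))
  })
  do.call(rbind, rows)
}
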