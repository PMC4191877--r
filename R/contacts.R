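#' Count inter-molecular contacts between two bead selections
#'
#' A contact is a bead pair (i in `sel_a`, j in `sel_b`, belonging to
#' different molecules) whose minimum-image distance is at most `cutoff`
#' (inclusive). Three counting modes cover the conventions used by the
#' contact-fraction statistics:
#'
#' * `"bead_pairs"`: each qualifying bead pair counts once (used for
#'   all-particle solute contacts and headgroup-bead partitioning).
#' * `"unordered_pairs"`: each unordered molecule pair with at least one
#'   qualifying bead pair counts once (cross-species lipid contacts).
#' * `"ordered_from_a"`: each ordered (molecule-of-a, molecule-of-b) pair
#'   with at least one qualifying bead pair counts once; with
#'   `sel_a == sel_b` this counts every neighbor of every molecule, i.e.
#'   each unordered pair twice (same-species lipid contacts).
#'
#' @param frame a [membrane_frame()].
#' @param sel_a,sel_b integer bead index sets (see [select_beads()]).
#' @param cutoff contact distance threshold, nm (> 0).
#' @param counting counting mode, see Details.
#' @return integer contact count.
#' @export
count_contacts <- function(frame, sel_a, sel_b, cutoff,
                           counting = c("bead_pairs", "unordered_pairs",
                                        "ordered_from_a")) {
  counting <- match.arg(counting)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)
    lm_stop("cutoff must be a single non-negative length in nm",
            "lipidmix_invalid_cutoff")
  sel_a <- as.integer(sel_a); sel_b <- as.integer(sel_b)
  pairs <- pbc_pairs(bead_xyz(frame, sel_a), bead_xyz(frame, sel_b),
                     frame$box, cutoff)
  if (!nrow(pairs)) return(0L)
  mol <- frame$beads$molecule_index
  ma <- mol[sel_a[pairs[, 1]]]
  mb <- mol[sel_b[pairs[, 2]]]
  keep <- ma != mb
  if (!any(keep)) return(0L)
  ma <- ma[keep]; mb <- mb[keep]
  K <- max(mol) + 1
  if (counting == "bead_pairs") {
    ga <- sel_a[pairs[keep, 1]]
    gb <- sel_b[pairs[keep, 2]]
    if (!length(intersect(sel_a, sel_b))) return(sum(keep))
    nb <- nrow(frame$beads) + 1
    return(length(unique(pmin(ga, gb) * nb + pmax(ga, gb))))
  }
  if (counting == "unordered_pairs")
    return(length(unique(pmin(ma, mb) * K + pmax(ma, mb))))
  length(unique(ma * K + mb))
}

contact_fraction_result <- function(statistic_name, value, cutoff, counts,
                                    n_frames = 1L, error = NA_real_) {
  structure(list(statistic_name = statistic_name, value = value,
                 error = error, cutoff = cutoff, counts = counts,
                 n_frames = as.integer(n_frames)),
            class = "contact_fraction_result")
}

#' @export
print.contact_fraction_result <- function(x, ...) {
  cat(sprintf("%s contact fraction: %.4f%s (cutoff %.2f nm, %d frame%s)\n",
              x$statistic_name, x$value,
              if (is.na(x$error)) "" else sprintf(" +/- %.4f", x$error),
              x$cutoff, x$n_frames, if (x$n_frames == 1) "" else "s"))
  cat("counts:", paste(sprintf("%s=%d", names(x$counts), as.integer(x$counts)),
                       collapse = ", "), "\n")
  invisible(x)
}

fraction_or_undefined <- function(num, den, statistic) {
  if (den <= 0)
    lm_stop(sprintf("%s contact fraction is undefined: zero total contacts",
                    statistic),
            "lipidmix_undefined_statistic")
  num / den
}

#' DLiPC-DPPC contact fraction (lipid mixing statistic f_mix)
#'
#' The order parameter for lipid mixing: the fraction of DLiPC-DPPC
#' contacts over all phospholipid contacts of DLiPC (cholesterol is not
#' included). Contacts are evaluated between PO4 headgroup beads only,
#' with an inclusive distance cutoff (default 1.1 nm). Cross-species
#' contacts count once per DLiPC-DPPC molecule pair; same-species
#' DLiPC-DLiPC contacts count once per ordered (molecule, neighbor) pair,
#' i.e. twice per unordered pair. Under this convention the statistic is 0
#' at complete phase separation and its ideal-mixing expectation equals
#' the DPPC molar fraction among phospholipids, 828/1368 = 0.605 at the
#' reference composition.
#'
#' @param frame a [membrane_frame()] containing DLiPC and DPPC molecules
#'   with PO4 beads.
#' @param cutoff contact cutoff, nm.
#' @return a `contact_fraction_result`.
#' @export
dlipc_dppc_contact_fraction <- function(frame, cutoff = 1.1) {
  sel_d <- select_beads(frame, "DLiPC", "PO4")
  sel_p <- select_beads(frame, "DPPC", "PO4")
  c_cross <- count_contacts(frame, sel_d, sel_p, cutoff, "unordered_pairs")
  c_same <- count_contacts(frame, sel_d, sel_d, cutoff, "ordered_from_a")
  val <- fraction_or_undefined(c_cross, c_cross + c_same, "DLiPC-DPPC")
  contact_fraction_result("dlipc_dppc", val, cutoff,
                          c("DLiPC-DPPC" = c_cross, "DLiPC-DLiPC" = c_same))
}

#' Solute-DLiPC contact fraction (solute partitioning statistic)
#'
#' Fraction of solute contacts made with DLiPC over solute contacts with
#' all phospholipids, using every bead of the solute and of the lipids
#' (bead-pair counting) and a 0.8 nm cutoff. 1 means the solute sits
#' entirely in the DLiPC-rich (Ld) phase; the ideal-mixing expectation is
#' the DLiPC molar fraction among phospholipids (540/1368 = 0.39 at the
#' reference composition) when both phospholipids have equal bead counts;
#' values near 0.5 indicate interfacial (linactant-like) localization on a
#' phase-separated membrane.
#'
#' @param frame a [membrane_frame()].
#' @param solute solute species label.
#' @param cutoff contact cutoff, nm.
#' @return a `contact_fraction_result`.
#' @export
solute_dlipc_contact_fraction <- function(frame, solute, cutoff = 0.8) {
  sel_s <- select_beads(frame, solute, "ALL")
  sel_d <- select_beads(frame, "DLiPC", "ALL")
  sel_p <- select_beads(frame, "DPPC", "ALL")
  c_d <- count_contacts(frame, sel_s, sel_d, cutoff, "bead_pairs")
  c_p <- count_contacts(frame, sel_s, sel_p, cutoff, "bead_pairs")
  val <- fraction_or_undefined(c_d, c_d + c_p,
                               paste0(solute, "-DLiPC"))
  res <- contact_fraction_result("solute_dlipc", val, cutoff,
                                 stats::setNames(c(c_d, c_p),
                                                 paste0(solute, c("-DLiPC", "-DPPC"))))
  res
}

#' Cholesterol-DLiPC contact fraction (cholesterol partitioning statistic)
#'
#' Fraction of cholesterol-DLiPC contacts over cholesterol contacts with
#' both phospholipids, computed between the ROH bead of cholesterol and
#' the PO4 beads of the lipids with a 1.1 nm cutoff. Low values indicate
#' that cholesterol resides mostly in the DPPC-rich Lo phase.
#'
#' @param frame a [membrane_frame()].
#' @param cutoff contact cutoff, nm.
#' @return a `contact_fraction_result`.
#' @export
chol_dlipc_contact_fraction <- function(frame, cutoff = 1.1) {
  sel_c <- select_beads(frame, "CHOL", "ROH")
  sel_d <- select_beads(frame, "DLiPC", "PO4")
  sel_p <- select_beads(frame, "DPPC", "PO4")
  c_d <- count_contacts(frame, sel_c, sel_d, cutoff, "bead_pairs")
  c_p <- count_contacts(frame, sel_c, sel_p, cutoff, "bead_pairs")
  val <- fraction_or_undefined(c_d, c_d + c_p, "CHOL-DLiPC")
  contact_fraction_result("chol_dlipc", val, cutoff,
                          c("CHOL-DLiPC" = c_d, "CHOL-DPPC" = c_p))
}

#' Per-frame contact-fraction time series
#'
#' Evaluates one of the three contact-fraction statistics on every frame
#' of a trajectory. Frames on which the statistic is undefined (zero total
#' contacts) carry `NA`.
#'
#' @param traj a [membrane_trajectory()].
#' @param statistic one of `"dlipc_dppc"`, `"solute_dlipc"`, `"chol_dlipc"`.
#' @param solute solute species label (required for `"solute_dlipc"`).
#' @param cutoff contact cutoff, nm; defaults to the statistic's standard
#'   value (1.1 nm for lipid and cholesterol statistics, 0.8 nm for the
#'   solute statistic).
#' @return data.frame with columns `time` (ns) and `value`.
#' @export
contact_fraction_series <- function(traj, statistic, solute = NULL,
                                    cutoff = NULL) {
  if (!statistic %in% c("dlipc_dppc", "solute_dlipc", "chol_dlipc"))
    lm_stop(paste0("unknown statistic '", statistic,
                   "'; expected dlipc_dppc, solute_dlipc or chol_dlipc"),
            "lipidmix_unknown_statistic")
  if (statistic == "solute_dlipc" && is.null(solute))
    lm_stop("solute species label required for the solute_dlipc statistic",
            "lipidmix_unknown_statistic")
  if (is.null(cutoff))
    cutoff <- if (statistic == "solute_dlipc") 0.8 else 1.1
  one <- function(fr) {
    r <- tryCatch(switch(statistic,
                         dlipc_dppc = dlipc_dppc_contact_fraction(fr, cutoff),
                         solute_dlipc = solute_dlipc_contact_fraction(fr, solute, cutoff),
                         chol_dlipc = chol_dlipc_contact_fraction(fr, cutoff)),
                  lipidmix_undefined_statistic = function(e) NULL)
    if (is.null(r)) NA_real_ else r$value
  }
  data.frame(time = traj$times,
             value = vapply(traj$frames, one, numeric(1)))
}

#' Block-averaged mean and error of a correlated series
#'
#' Estimates the mean of the tail of a time series together with a
#' standard error that accounts for serial correlation, by block
#' averaging with block-length doubling: starting from block length 1 the
#' block standard error of the mean is computed, the block length doubled,
#' and the procedure repeated while at least 4 blocks remain; the reported
#' error is the maximum (plateau) over that progression. For uncorrelated
#' data this reduces to the ordinary standard error of the mean; for
#' correlated data it converges to the effective-sample-size corrected
#' error once blocks exceed the correlation time.
#'
#' @param series numeric vector, time-ordered.
#' @param tail_fraction fraction of the series (taken from the end) to
#'   average over; the analysis convention is the final half of a
#'   production run.
#' @return list with `mean`, `error`, and `n` (tail length used).
#' @export
block_average_error <- function(series, tail_fraction = 0.5) {
  series <- as.numeric(series)
  series <- series[!is.na(series)]
  n <- length(series)
  m <- max(1L, ceiling(tail_fraction * n))
  x <- series[seq.int(n - m + 1L, n)]
  if (m < 4L)
    lm_stop("series too short for block averaging: need at least 4 points in the tail window",
            "lipidmix_series_too_short")
  mu <- mean(x)
  err <- 0
  b <- 1L
  while (m %/% b >= 4L) {
    nb <- m %/% b
    used <- x[seq.int(m - nb * b + 1L, m)]
    bm <- colMeans(matrix(used, nrow = b))
    err <- max(err, stats::sd(bm) / sqrt(nb))
    b <- b * 2L
  }
  list(mean = mu, error = err, n = m)
}

#' Write contact-fraction results as a tab-separated table
#'
#' One row per statistic with columns `statistic`, `value`, `error`,
#' `cutoff`, `n_frames`, mirroring the layout of a simulation summary
#' table.
#'
#' @param results list of `contact_fraction_result` objects.
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
write_contact_table <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(statistic = r$statistic_name, value = r$value,
               error = r$error, cutoff = r$cutoff, n_frames = r$n_frames,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
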