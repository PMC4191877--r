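# Grid-based bilayer thickness, per-phase thickness (most-frequent-value
# rule) and Lo/Ld thickness mismatch.

#' Gridded membrane-thickness landscape
#'
#' Per grid cell, the mean z of upper-leaflet PO4 beads minus the mean z
#' of lower-leaflet PO4 beads, computed per frame and averaged over the
#' analysis window. Cells that never hold PO4 beads in both leaflets are
#' undefined (no extrapolation). Frames must carry leaflet labels (run
#' [assign_leaflets()] first).
#'
#' @inheritParams partial_density_landscape
#' @return a `membrane_landscape` with `quantity = "thickness"` (nm).
#' @export
thickness_landscape <- function(traj, window = NULL, bins = 50L) {
  if (bins < 2) lm_stop("bins must be >= 2", "lipidmix_invalid_grid")
  idx <- resolve_window(traj, window, last_ns = 500, last_frac = 0.1)
  f0 <- traj$frames[[idx[1]]]
  if (all(is.na(f0$beads$leaflet)))
    lm_stop("frames carry no leaflet labels; run assign_leaflets() first",
            "lipidmix_no_leaflets")
  acc <- matrix(0, bins, bins)
  nobs <- matrix(0L, bins, bins)
  for (i in idx) {
    fr <- traj$frames[[i]]
    b <- fr$beads
    po4 <- which(b$bead_name == "PO4")
    if (!length(po4))
      lm_stop("no PO4 beads in frame", "lipidmix_not_a_membrane")
    fx <- b$x[po4] / fr$box[1]; fx <- fx - floor(fx)
    fy <- b$y[po4] / fr$box[2]; fy <- fy - floor(fy)
    cell <- (pmin(floor(fx * bins), bins - 1L) + 1L) +
      (pmin(floor(fy * bins), bins - 1L)) * bins
    up <- b$leaflet[po4] == "upper"
    zsum_u <- rep(0, bins * bins); zsum_l <- rep(0, bins * bins)
    n_u <- tabulate(cell[up], nbins = bins * bins)
    n_l <- tabulate(cell[!up], nbins = bins * bins)
    if (any(up)) {
      su <- rowsum(b$z[po4][up], cell[up])
      zsum_u[as.integer(rownames(su))] <- su[, 1]
    }
    if (any(!up)) {
      sl <- rowsum(b$z[po4][!up], cell[!up])
      zsum_l[as.integer(rownames(sl))] <- sl[, 1]
    }
    both <- n_u > 0 & n_l > 0
    th <- rep(NA_real_, bins * bins)
    th[both] <- zsum_u[both] / n_u[both] - zsum_l[both] / n_l[both]
    thm <- matrix(th, bins, bins)
    has <- !is.na(thm)
    acc[has] <- acc[has] + thm[has]
    nobs <- nobs + has
  }
  vals <- matrix(NA_real_, bins, bins)
  def <- nobs > 0
  vals[def] <- acc[def] / nobs[def]
  box_xy <- rowMeans(vapply(traj$frames[idx], function(f) f$box[1:2], numeric(2)))
  new_landscape(vals, "thickness", box_xy / bins, NA_character_,
                length(idx), !def, box_xy, bins)
}

#' Partition grid cells into Lo and Ld phase masks
#'
#' Cells are attributed to phases by the DLiPC density-fraction landscape
#' at its 0.5 interface level: fraction >= 0.5 is Ld (DLiPC-rich), < 0.5
#' is Lo (DPPC-rich). Undefined fraction cells belong to neither mask.
#'
#' @param fraction a `density_fraction` landscape.
#' @param level phase-attribution level (default 0.5).
#' @return list of logical matrices `Lo` and `Ld`.
#' @export
phase_masks <- function(fraction, level = 0.5) {
  if (!inherits(fraction, "membrane_landscape") ||
      fraction$quantity != "density_fraction")
    lm_stop("phase_masks requires a density_fraction landscape",
            "lipidmix_invalid_landscape")
  v <- fraction$values
  def <- !fraction$undefined_mask
  list(Lo = def & !is.na(v) & v < level,
       Ld = def & !is.na(v) & v >= level)
}

# most frequent value of v discretized with the given bin width; bin
# centers are anchored at min(v) so a constant sample returns itself;
# ties break toward the thicker bin
mode_by_histogram <- function(v, bin_width) {
  v <- v[!is.na(v)]
  centers <- min(v) + bin_width * seq(0, ceiling(diff(range(v)) / bin_width))
  idx <- pmax(1L, pmin(length(centers),
                       as.integer(round((v - min(v)) / bin_width)) + 1L))
  counts <- tabulate(idx, nbins = length(centers))
  best <- max(which(counts == max(counts)))
  list(value = centers[best],
       histogram = data.frame(center = centers, count = counts))
}

#' Per-phase thickness by the most-frequent-value rule
#'
#' The characteristic thickness of a phase is the most frequent local
#' thickness in the thickness landscape: defined cells of each phase are
#' histogrammed with the given bin width and the center of the maximal
#' bin is returned (ties broken toward the thicker bin). Phases are the
#' cell partitions of [phase_masks()]; with `fraction = NULL` a single
#' whole-membrane value is returned instead.
#'
#' @param thickness a `thickness` landscape ([thickness_landscape()]).
#' @param fraction a `density_fraction` landscape used to partition cells
#'   into phases, or `NULL` for whole-membrane mode.
#' @param bin_width histogram bin width, nm (default 0.02).
#' @return list with `thickness` (named vector: `Lo` and `Ld`, or
#'   `membrane`), `mismatch` (Lo - Ld, nm; `NA` in whole-membrane mode)
#'   and `histograms` (per-phase bin center/count tables).
#' @export
phase_thickness <- function(thickness, fraction = NULL, bin_width = 0.02) {
  if (!inherits(thickness, "membrane_landscape") ||
      thickness$quantity != "thickness")
    lm_stop("phase_thickness requires a thickness landscape",
            "lipidmix_invalid_landscape")
  def <- !thickness$undefined_mask
  if (is.null(fraction)) {
    m <- mode_by_histogram(thickness$values[def], bin_width)
    return(list(thickness = c(membrane = m$value), mismatch = NA_real_,
                histograms = list(membrane = m$histogram)))
  }
  masks <- phase_masks(fraction)
  out <- c(Lo = NA_real_, Ld = NA_real_)
  hists <- list()
  for (ph in c("Lo", "Ld")) {
    cells <- thickness$values[masks[[ph]] & def]
    if (!length(cells))
      lm_stop(sprintf("phase mask %s holds no defined thickness cells", ph),
              "lipidmix_empty_phase")
    m <- mode_by_histogram(cells, bin_width)
    out[ph] <- m$value
    hists[[ph]] <- m$histogram
  }
  list(thickness = out, mismatch = thickness_mismatch(out["Lo"], out["Ld"]),
       histograms = hists)
}

#' Lo-Ld thickness mismatch
#'
#' Signed difference between the liquid-ordered and liquid-disordered
#' phase thicknesses; a positive value means the Lo phase is thicker.
#'
#' @param lo,ld phase thicknesses, nm.
#' @return mismatch in nm (`lo - ld`).
#' @export
thickness_mismatch <- function(lo, ld) unname(lo - ld)

#' Write a thickness histogram as a two-column table
#'
#' @param histogram data.frame with columns `center` and `count` (as
#'   returned in `phase_thickness()$histograms`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_thickness_histogram <- function(histogram, path) {
  utils::write.table(histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
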