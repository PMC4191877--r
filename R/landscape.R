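# Planar gridded landscapes: partial density, DLiPC density fraction,
# normalized solute density, interface localization.

new_landscape <- function(values, quantity, cell_size, species, n_frames,
                          undefined_mask, box_xy, bins) {
  structure(list(values = values, quantity = quantity,
                 cell_size = cell_size, species = species,
                 n_frames = as.integer(n_frames),
                 undefined_mask = undefined_mask,
                 box_xy = box_xy, bins = bins),
            class = "membrane_landscape")
}

#' @export
print.membrane_landscape <- function(x, ...) {
  rng <- range(x$values[!x$undefined_mask])
  cat(sprintf("membrane_landscape (%s%s): %dx%d cells of %.3f x %.3f nm, %d frame%s\n",
              x$quantity,
              if (is.null(x$species) || is.na(x$species)) "" else paste0(", ", x$species),
              x$bins, x$bins, x$cell_size[1], x$cell_size[2],
              x$n_frames, if (x$n_frames == 1) "" else "s"))
  cat(sprintf("defined cells: %d/%d, value range %.4g .. %.4g\n",
              sum(!x$undefined_mask), length(x$values), rng[1], rng[2]))
  invisible(x)
}

# per-frame 2D histogram of selected beads in box-fractional coordinates
cell_counts <- function(frame, sel, bins) {
  fx <- frame$beads$x[sel] / frame$box[1]
  fy <- frame$beads$y[sel] / frame$box[2]
  fx <- fx - floor(fx); fy <- fy - floor(fy)
  ix <- pmin(floor(fx * bins), bins - 1L) + 1L
  iy <- pmin(floor(fy * bins), bins - 1L) + 1L
  matrix(tabulate(ix + (iy - 1L) * bins, nbins = bins * bins),
         nrow = bins, ncol = bins)
}

# time-mean cell count matrix and mean cell area over a window
mean_cell_counts <- function(traj, sel, idx, bins) {
  acc <- matrix(0, bins, bins)
  area <- 0
  for (i in idx) {
    fr <- traj$frames[[i]]
    acc <- acc + cell_counts(fr, sel, bins)
    area <- area + fr$box[1] * fr$box[2] / bins^2
  }
  list(counts = acc / length(idx), cell_area = area / length(idx))
}

#' Planar partial-density landscape of one species
#'
#' Time-averaged density of the selected beads on a grid in the membrane
#' (XY) plane. Binning is done in box-fractional coordinates so frames
#' with fluctuating boxes share one grid; densities are counts divided by
#' the time-mean cell area (beads/nm^2). The grid sum times the mean cell
#' area therefore equals the mean selected-bead count per frame exactly.
#'
#' @param traj a [membrane_trajectory()].
#' @param species species label.
#' @param bead_names bead-name filter, or `"ALL"` (default).
#' @param window frame window: `NULL` for the default rule (final 500 ns
#'   when the time span covers it, else the final 10% of frames), a vector
#'   of frame indices, or `list(last_ns =, last_frac =)`.
#' @param bins grid bins per axis (default 50).
#' @param leaflet optionally restrict to `"upper"` or `"lower"` leaflet
#'   beads (frames must carry leaflet labels); default whole bilayer.
#' @return a `membrane_landscape` with `quantity = "partial_density"`.
#' @export
partial_density_landscape <- function(traj, species, bead_names = "ALL",
                                      window = NULL, bins = 50L,
                                      leaflet = NULL) {
  if (bins < 2) lm_stop("bins must be >= 2", "lipidmix_invalid_grid")
  idx <- resolve_window(traj, window, last_ns = 500, last_frac = 0.1)
  sel0 <- select_beads(traj$frames[[idx[1]]], species, bead_names)
  acc <- matrix(0, bins, bins); area <- 0
  for (i in idx) {
    fr <- traj$frames[[i]]
    sel <- sel0
    if (!is.null(leaflet)) sel <- sel[fr$beads$leaflet[sel] == leaflet]
    acc <- acc + cell_counts(fr, sel, bins)
    area <- area + fr$box[1] * fr$box[2] / bins^2
  }
  counts <- acc / length(idx)
  cell_area <- area / length(idx)
  box_xy <- rowMeans(vapply(traj$frames[idx], function(f) f$box[1:2], numeric(2)))
  new_landscape(counts / cell_area, "partial_density",
                cell_size = box_xy / bins, species = species,
                n_frames = length(idx),
                undefined_mask = matrix(FALSE, bins, bins),
                box_xy = box_xy, bins = bins)
}

#' DLiPC density-fraction landscape
#'
#' Per cell, the DLiPC partial density divided by the total phosphatidyl-
#' choline (DLiPC + DPPC) density: 0 where DPPC is the only lipid, 1 where
#' DLiPC is. Cells with zero total PC density are marked undefined. The
#' 0.5 level set of this landscape defines the Lo-Ld domain interface.
#'
#' @inheritParams partial_density_landscape
#' @return a `membrane_landscape` with `quantity = "density_fraction"`.
#' @export
dlipc_density_fraction_landscape <- function(traj, window = NULL, bins = 50L,
                                             leaflet = NULL) {
  d <- partial_density_landscape(traj, "DLiPC", "ALL", window, bins, leaflet)
  p <- partial_density_landscape(traj, "DPPC", "ALL", window, bins, leaflet)
  tot <- d$values + p$values
  undef <- tot <= 0
  vals <- matrix(NA_real_, bins, bins)
  vals[!undef] <- d$values[!undef] / tot[!undef]
  new_landscape(vals, "density_fraction", d$cell_size, "DLiPC", d$n_frames,
                undef, d$box_xy, bins)
}

#' Normalized solute-density landscape
#'
#' Solute partial density divided by its spatial mean over all cells, so
#' the landscape averages to exactly 1; values above 1 mark enrichment,
#' below 1 depletion.
#'
#' @inheritParams partial_density_landscape
#' @param solute solute species label.
#' @return a `membrane_landscape` with `quantity = "normalized_density"`.
#' @export
normalized_solute_density_landscape <- function(traj, solute, window = NULL,
                                                bins = 50L, leaflet = NULL) {
  d <- partial_density_landscape(traj, solute, "ALL", window, bins, leaflet)
  mu <- mean(d$values)
  if (mu <= 0)
    lm_stop("zero total solute density in the analysis window",
            "lipidmix_undefined_statistic")
  new_landscape(d$values / mu, "normalized_density", d$cell_size, solute,
                d$n_frames, d$undefined_mask, d$box_xy, d$bins)
}

# periodic shifts of a matrix by one cell in the 4 grid directions
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(p) - 1 - dc) %% p) + 1]
}

# for each cell, the value of the nearest defined cell in direction
# (dr, dc) within max_skip steps, scanning periodically; NA if none
nearest_defined <- function(vals, dr, dc, max_skip) {
  out <- shift_mat(vals, dr, dc)
  step <- 1L
  while (anyNA(out) && step < max_skip) {
    step <- step + 1L
    fill <- shift_mat(vals, dr * step, dc * step)
    na <- is.na(out)
    out[na] <- fill[na]
  }
  out
}

#' Locate interface cells on a density-fraction landscape
#'
#' Marks defined cells where the density fraction crosses `level` against
#' a neighboring cell: for each of the four periodic grid directions the
#' nearest defined neighbor is compared (for a fully defined landscape
#' this is the ordinary 4-neighborhood; runs of undefined cells, e.g. a
#' lipid-free gap, are skipped so the two cells facing each other across
#' the gap are still compared). On a two-stripe membrane this yields two
#' connected interface bands.
#'
#' @param fraction a `density_fraction` landscape
#'   ([dlipc_density_fraction_landscape()]).
#' @param level crossing level (default 0.5, the domain-interface value).
#' @param max_skip farthest defined neighbor considered, in cells; bounds
#'   the undefined-gap width that can be bridged so that unrelated
#'   regions across large unsampled voids are not compared (the default
#'   spans a lipid-free gap slightly wider than the default stripe
#'   buffer).
#' @return logical matrix marking interface cells.
#' @export
interface_cells <- function(fraction, level = 0.5, max_skip = 5L) {
  if (!inherits(fraction, "membrane_landscape") ||
      fraction$quantity != "density_fraction")
    lm_stop("interface_cells requires a density_fraction landscape",
            "lipidmix_invalid_landscape")
  v <- fraction$values
  if (all(fraction$undefined_mask))
    lm_stop("landscape has no defined cells", "lipidmix_invalid_landscape")
  hi <- v >= level
  marked <- matrix(FALSE, nrow(v), ncol(v))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- nearest_defined(v, d[1], d[2], max_skip)
    cross <- !is.na(v) & !is.na(nb) & (hi != (nb >= level))
    marked <- marked | cross
  }
  marked
}

# periodic 4-neighbor dilation of a logical mask, `width` steps
dilate_mask <- function(mask, width) {
  out <- mask
  for (k in seq_len(width)) {
    out <- out | shift_mat(out, 1, 0) | shift_mat(out, -1, 0) |
      shift_mat(out, 0, 1) | shift_mat(out, 0, -1)
  }
  out
}

#' Solute enrichment at the domain interface
#'
#' Mean normalized solute density within `band_width` cells of the
#' interface divided by the mean outside that band. Values well above 1
#' indicate interfacial (linactant-like) localization; a solute that
#' partitions into one phase but avoids the interface scores near 1 here
#' while its solute-DLiPC contact fraction is extreme, separating the two
#' mechanisms.
#'
#' @param solute_landscape a `normalized_density` landscape
#'   ([normalized_solute_density_landscape()]).
#' @param interface logical interface mask from [interface_cells()].
#' @param band_width band half-width around interface cells, in cells.
#' @return dimensionless enrichment ratio.
#' @export
solute_interface_enrichment <- function(solute_landscape, interface,
                                        band_width = 2L) {
  v <- solute_landscape$values
  if (!identical(dim(v), dim(interface)))
    lm_stop("landscape and interface mask shapes differ",
            "lipidmix_invalid_landscape")
  band <- dilate_mask(interface, band_width)
  def <- !solute_landscape$undefined_mask
  inside <- v[band & def]
  outside <- v[!band & def]
  if (!length(inside) || !length(outside))
    lm_stop("interface band or its complement is empty",
            "lipidmix_invalid_landscape")
  mean(inside) / mean(outside)
}

#' Write a landscape as a plain-text matrix plus a header sidecar
#'
#' The matrix file holds one grid row per line (tab-separated, `NA` for
#' undefined cells); `<path>.meta` records quantity, species, cell size,
#' grid size and frame count as `key: value` lines.
#'
#' @param landscape a `membrane_landscape`.
#' @param path output path for the matrix file.
#' @return invisibly, `path`.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(landscape$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- c(
    sprintf("quantity: %s", landscape$quantity),
    sprintf("species: %s", if (is.null(landscape$species)) "none" else landscape$species),
    sprintf("cell_size_nm: %.6f %.6f", landscape$cell_size[1], landscape$cell_size[2]),
    sprintf("bins: %d", landscape$bins),
    sprintf("n_frames: %d", landscape$n_frames),
    sprintf("box_xy_nm: %.6f %.6f", landscape$box_xy[1], landscape$box_xy[2]))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param path path to the matrix file (with `<path>.meta` alongside).
#' @return a `membrane_landscape`.
#' @export
read_landscape <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(vals) <- NULL
  meta <- readLines(paste0(path, ".meta"))
  get_meta <- function(key) sub(paste0("^", key, ": "), "",
                                grep(paste0("^", key, ": "), meta, value = TRUE))
  cell <- as.numeric(strsplit(get_meta("cell_size_nm"), " ")[[1]])
  box <- as.numeric(strsplit(get_meta("box_xy_nm"), " ")[[1]])
  new_landscape(vals, get_meta("quantity"), cell, get_meta("species"),
                as.integer(get_meta("n_frames")), is.na(vals), box,
                as.integer(get_meta("bins")))
}
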