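#' Membrane frame: one snapshot of a coarse-grained bilayer
#'
#' A `membrane_frame` holds one time point of a coarse-grained membrane
#' system: a bead table (one row per particle), an orthorhombic periodic
#' box, and the frame time in ns. Beads of one molecule must be contiguous
#' in the table. Positions are in nm.
#'
#' @param beads data.frame with columns `particle_index`, `molecule_index`,
#'   `species`, `bead_name`, `x`, `y`, `z` and optionally `leaflet`
#'   (per-molecule label in `"upper"`, `"lower"`, `"none"`).
#' @param box numeric length-3 vector of box edge lengths (Lx, Ly, Lz), nm.
#'   Only rectangular (orthorhombic) boxes are supported.
#' @param time frame time, ns.
#' @param wrap logical; wrap positions into `[0, L)` per axis (default TRUE).
#' @return an object of class `membrane_frame`.
#' @seealso [read_gro()], [assign_leaflets()], [select_beads()]
#' @export
membrane_frame <- function(beads, box, time = 0, wrap = TRUE) {
  need <- c("particle_index", "molecule_index", "species", "bead_name",
            "x", "y", "z")
  miss <- setdiff(need, names(beads))
  if (length(miss))
    lm_stop(paste0("bead table lacks column(s): ", paste(miss, collapse = ", ")),
            "lipidmix_invalid_frame")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    lm_stop("box must be 3 strictly positive finite edge lengths (nm)",
            "lipidmix_invalid_box")
  pos <- c(beads$x, beads$y, beads$z)
  if (length(pos) && any(!is.finite(pos)))
    lm_stop("bead positions must be finite", "lipidmix_invalid_frame")
  if (any(!nzchar(beads$species)) || any(!nzchar(beads$bead_name)))
    lm_stop("species and bead_name labels must be non-empty",
            "lipidmix_invalid_frame")
  if (nrow(beads)) {
    runs <- rle(as.integer(beads$molecule_index))$values
    if (anyDuplicated(runs))
      lm_stop("molecule_index must group beads contiguously per molecule",
              "lipidmix_invalid_frame")
  }
  if (!"leaflet" %in% names(beads))
    beads$leaflet <- rep(NA_character_, nrow(beads))
  beads <- as.data.frame(beads, stringsAsFactors = FALSE)
  rownames(beads) <- NULL
  fr <- structure(list(beads = beads, box = box, time = as.numeric(time)),
                  class = "membrane_frame")
  if (wrap) fr <- wrap_frame(fr)
  fr
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("membrane_frame: %d beads, %d molecules, box %.2f x %.2f x %.2f nm, t = %g ns\n",
              nrow(x$beads), n_molecules(x), x$box[1], x$box[2], x$box[3], x$time))
  sp <- table(x$beads$species[!duplicated(x$beads$molecule_index)])
  cat("molecules:", paste(sprintf("%s=%d", names(sp), as.integer(sp)), collapse = ", "), "\n")
  invisible(x)
}

#' Wrap all bead positions into the primary box
#'
#' @param frame a [membrane_frame()].
#' @return the frame with positions wrapped into `[0, L)` per axis.
#' @export
wrap_frame <- function(frame) {
  b <- frame$beads
  if (nrow(b)) {
    b$x <- b$x - frame$box[1] * floor(b$x / frame$box[1])
    b$y <- b$y - frame$box[2] * floor(b$y / frame$box[2])
    b$z <- b$z - frame$box[3] * floor(b$z / frame$box[3])
  }
  frame$beads <- b
  frame
}

#' Number of molecules in a frame
#' @param frame a [membrane_frame()].
#' @return integer molecule count.
#' @export
n_molecules <- function(frame) {
  length(unique(frame$beads$molecule_index))
}

#' Species present in a frame
#' @param frame a [membrane_frame()].
#' @return character vector of distinct species labels.
#' @export
known_species <- function(frame) unique(frame$beads$species)

#' Default residue-name to species mapping
#'
#' Maps coordinate-file residue names to the species labels used throughout
#' the package. MARTINI-style aliases for dilinoleyl-PC (`DIPC`, `DLIP`,
#' `DLIPC`) map to `DLiPC`; anything not in the table (solute residues,
#' whose naming is force-field specific) maps to itself, so the table is
#' user-extensible: `c(default_species_map(), OCT = "OCT")`.
#'
#' @return named character vector (residue name -> species label).
#' @export
default_species_map <- function() {
  c(DPPC = "DPPC", DLIPC = "DLiPC", DIPC = "DLiPC", DLIP = "DLiPC",
    DLiPC = "DLiPC", CHOL = "CHOL")
}

map_species <- function(resnames, species_map = default_species_map()) {
  out <- species_map[resnames]
  out[is.na(out)] <- resnames[is.na(out)]
  unname(out)
}

#' Select bead indices by species and bead name
#'
#' @param frame a [membrane_frame()].
#' @param species character vector of species labels to match.
#' @param bead_names character vector of bead names, or `"ALL"` to match
#'   every bead of the selected species.
#' @return integer vector of bead (row) indices.
#' @export
select_beads <- function(frame, species, bead_names = "ALL") {
  known <- known_species(frame)
  bad <- setdiff(species, known)
  if (length(bad))
    lm_stop(sprintf("unknown species %s; known species: %s",
                    paste(bad, collapse = ", "),
                    paste(known, collapse = ", ")),
            "lipidmix_unknown_species")
  sel <- frame$beads$species %in% species
  if (!(length(bead_names) == 1 && identical(bead_names, "ALL")))
    sel <- sel & frame$beads$bead_name %in% bead_names
  which(sel)
}

#' Assign upper/lower leaflet labels from headgroup bead positions
#'
#' The bilayer midplane is the mean z of all PO4 beads in the frame. Each
#' phospholipid is labelled by the sign of its PO4 z relative to the
#' midplane, each cholesterol by the sign of its ROH z; molecules with
#' neither marker bead (solutes) are labelled `"none"`. A single global
#' midplane per frame is used, which is adequate for flat stripe-domain
#' membranes.
#'
#' @param frame a [membrane_frame()] containing PO4 beads.
#' @return the frame with the per-bead `leaflet` column filled in.
#' @export
assign_leaflets <- function(frame) {
  b <- frame$beads
  po4 <- b$bead_name == "PO4"
  if (!any(po4))
    lm_stop("no PO4 beads found: input does not look like a phospholipid membrane",
            "lipidmix_not_a_membrane")
  mid <- mean(b$z[po4])
  marker <- po4 | (b$bead_name == "ROH")
  lab <- rep(NA_character_, nrow(b))
  lab[marker] <- ifelse(b$z[marker] >= mid, "upper", "lower")
  # propagate the marker-bead label to all beads of the molecule
  mol_lab <- tapply(lab, b$molecule_index, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[1] else "none"
  })
  b$leaflet <- as.vector(mol_lab[as.character(b$molecule_index)])
  frame$beads <- b
  frame
}

#' Build a trajectory from a list of frames
#'
#' @param frames list of [membrane_frame()] objects with strictly
#'   increasing times and identical particle counts and labels.
#' @return an object of class `membrane_trajectory` with elements `frames`
#'   and `times` (ns).
#' @export
membrane_trajectory <- function(frames) {
  if (!length(frames))
    lm_stop("trajectory must contain at least one frame",
            "lipidmix_invalid_trajectory")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0))
    lm_stop("frame times must be strictly increasing",
            "lipidmix_invalid_trajectory")
  n0 <- nrow(frames[[1]]$beads)
  lab0 <- paste(frames[[1]]$beads$species, frames[[1]]$beads$bead_name)
  for (f in frames[-1]) {
    if (nrow(f$beads) != n0 ||
        !identical(paste(f$beads$species, f$beads$bead_name), lab0))
      lm_stop("all frames must share identical particle count and labels",
              "lipidmix_invalid_trajectory")
  }
  structure(list(frames = frames, times = times),
            class = "membrane_trajectory")
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat(sprintf("membrane_trajectory: %d frames, t = %g .. %g ns, %d beads/frame\n",
              length(x$frames), min(x$times), max(x$times),
              nrow(x$frames[[1]]$beads)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [membrane_trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# resolve a window specification to frame indices.
# window: NULL -> default rule (last `last_ns` ns when the time span covers
# it, else the last `last_frac` of frames); or integer indices; or a list
# with `last_ns` / `last_frac`.
resolve_window <- function(traj, window, last_ns, last_frac) {
  nf <- n_frames(traj)
  if (is.numeric(window) && length(window)) {
    idx <- as.integer(window)
    if (any(idx < 1 | idx > nf))
      lm_stop("window indices out of range", "lipidmix_invalid_window")
    return(idx)
  }
  if (is.list(window)) {
    if (!is.null(window$last_ns)) last_ns <- window$last_ns
    if (!is.null(window$last_frac)) last_frac <- window$last_frac
  } else if (!is.null(window)) {
    lm_stop("window must be NULL, frame indices, or list(last_ns=, last_frac=)",
            "lipidmix_invalid_window")
  }
  span <- max(traj$times) - min(traj$times)
  if (span >= last_ns && nf > 1) {
    idx <- which(traj$times > max(traj$times) - last_ns)
  } else {
    idx <- seq.int(nf - max(1L, ceiling(last_frac * nf)) + 1L, nf)
  }
  idx
}
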