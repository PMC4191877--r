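#' Read a GROMOS-87 (.gro) coordinate file
#'
#' Parses the fixed-column GROMOS-87 layout (title line, atom count, atom
#' lines, box line) into a [membrane_frame()]. The residue name maps to a
#' species label through `species_map`, the atom name becomes the bead
#' name. Velocities, if present, are ignored. Coordinates are in nm and are
#' wrapped into the primary box. A time in ns is taken from a `t=` token in
#' the title line when present.
#'
#' Only rectangular boxes are supported: a 9-field box line with any
#' nonzero off-diagonal component is rejected.
#'
#' @param path path to a `.gro` file.
#' @param species_map residue-name to species mapping, see
#'   [default_species_map()].
#' @param wrap wrap positions into the box (default TRUE).
#' @return a [membrane_frame()].
#' @export
read_gro <- function(path, species_map = default_species_map(), wrap = TRUE) {
  if (!file.exists(path))
    lm_stop(paste0("file not found: ", path), "lipidmix_io_error")
  lines <- readLines(path, warn = FALSE)
  fr <- parse_gro_frame(lines, 1L, species_map = species_map, wrap = wrap)$frame
  if (is.na(fr$time)) fr$time <- 0
  fr
}

#' Read a multi-frame concatenated .gro trajectory
#'
#' Reads a file holding several `.gro` frames back to back (the package's
#' multi-frame interchange format, produced by [write_gro_trajectory()]).
#' Frames must share particle counts and labels. If the title lines carry
#' no `t=` times, frames are numbered 0, 1, 2, ... ns.
#'
#' @inheritParams read_gro
#' @return a [membrane_trajectory()].
#' @export
read_gro_trajectory <- function(path, species_map = default_species_map(),
                                wrap = TRUE) {
  if (!file.exists(path))
    lm_stop(paste0("file not found: ", path), "lipidmix_io_error")
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  at <- 1L
  while (at <= length(lines) && nzchar(trimws(paste(lines[at:min(at + 1L, length(lines))], collapse = "")))) {
    res <- parse_gro_frame(lines, at, species_map = species_map, wrap = wrap)
    frames[[length(frames) + 1L]] <- res$frame
    at <- res$next_line
    while (at <= length(lines) && !nzchar(trimws(lines[at]))) at <- at + 1L
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(times) || (length(times) > 1 && any(diff(times) <= 0))) {
    for (i in seq_along(frames)) frames[[i]]$time <- i - 1
  }
  membrane_trajectory(frames)
}

parse_gro_frame <- function(lines, at, species_map, wrap) {
  if (at + 1L > length(lines))
    lm_stop(sprintf("line %d: truncated file, expected title and atom count", at),
            "lipidmix_parse_error")
  title <- lines[at]
  nat <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
  if (is.na(nat) || nat < 0)
    lm_stop(sprintf("line %d: malformed atom count '%s'", at + 1L, lines[at + 1L]),
            "lipidmix_parse_error")
  box_line_no <- at + 2L + nat
  if (box_line_no > length(lines))
    lm_stop(sprintf("line %d: declared atom count %d disagrees with the number of atom lines",
                    at + 1L, nat),
            "lipidmix_parse_error")
  box <- parse_gro_box(lines[box_line_no], box_line_no)

  if (nat > 0L) {
    al <- lines[(at + 2L):(at + 1L + nat)]
    resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
    resname <- trimws(substr(al, 6, 10))
    atomname <- trimws(substr(al, 11, 15))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z) |
                   !nzchar(resname) | !nzchar(atomname))
    if (length(bad))
      lm_stop(sprintf("line %d: malformed atom line '%s'",
                      at + 1L + bad[1], al[bad[1]]),
              "lipidmix_parse_error")
    # rebuild molecule indices: residue numbers wrap at 99999
    molecule_index <- cumsum(c(TRUE, resid[-1] != resid[-nat]))
    beads <- data.frame(
      particle_index = seq_len(nat),
      molecule_index = molecule_index,
      species = map_species(resname, species_map),
      bead_name = atomname,
      x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  } else {
    beads <- data.frame(particle_index = integer(0), molecule_index = integer(0),
                        species = character(0), bead_name = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        stringsAsFactors = FALSE)
  }
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  time <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
  fr <- membrane_frame(beads, box, time = if (is.na(time)) 0 else time,
                       wrap = wrap)
  fr$time <- time  # NA when the title carries no t=; callers renumber
  list(frame = fr, next_line = box_line_no + 1L)
}

parse_gro_box <- function(line, line_no) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (!length(v) || anyNA(v) || !(length(v) %in% c(3L, 9L)))
    lm_stop(sprintf("line %d: malformed box line '%s'", line_no, line),
            "lipidmix_parse_error")
  if (length(v) == 9L && any(v[4:9] != 0))
    lm_stop(sprintf("line %d: non-rectangular (triclinic) box is not supported",
                    line_no),
            "lipidmix_unsupported_box")
  v[1:3]
}

#' Write a membrane frame in GROMOS-87 (.gro) layout
#'
#' Positions are written with the format's 3-decimal precision;
#' [read_gro()] of the result reproduces positions to 1e-3 nm. Residue
#' numbers come from `molecule_index` (modulo the format's 5-digit field),
#' species labels are written as residue names.
#'
#' @param frame a [membrane_frame()].
#' @param path output path.
#' @param append append to an existing file (used for multi-frame output).
#' @param title title line; the frame time is appended as `t= <ns>`.
#' @return invisibly, `path`.
#' @export
write_gro <- function(frame, path, append = FALSE, title = "lipidmix frame") {
  b <- frame$beads
  n <- nrow(b)
  con <- tryCatch(file(path, if (append) "a" else "w"),
                  error = function(e) lm_stop(paste0("cannot open for writing: ", path),
                                              "lipidmix_io_error"))
  on.exit(close(con))
  writeLines(sprintf("%s t= %.6f", title, frame$time), con)
  writeLines(sprintf("%5d", n), con)
  if (n > 0) {
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$molecule_index %% 100000L,
                       substr(b$species, 1, 5),
                       substr(b$bead_name, 1, 5),
                       b$particle_index %% 100000L,
                       b$x, b$y, b$z), con)
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]), con)
  invisible(path)
}

#' Write a trajectory as concatenated .gro frames
#'
#' @param traj a [membrane_trajectory()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gro_trajectory <- function(traj, path) {
  for (i in seq_along(traj$frames))
    write_gro(traj$frames[[i]], path, append = i > 1)
  invisible(path)
}
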