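#' Minimum-image distance in a rectangular periodic box
#'
#' Euclidean distance between two points minimized over all periodic
#' images. Symmetric in its arguments and never larger than half the box
#' diagonal. Accepts either two length-3 vectors or two n x 3 matrices
#' (row-wise distances).
#'
#' @param a,b length-3 position vectors (nm), or n x 3 matrices.
#' @param box length-3 vector of box edge lengths (nm).
#' @return distance(s) in nm.
#' @export
minimum_image_distance <- function(a, b, box) {
  box <- as.numeric(box)
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    d <- a - b
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    return(sqrt(rowSums(d * d)))
  }
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# All ordered index pairs (i over rows of A, j over rows of B) whose
# minimum-image distance is <= cutoff. Chunked over rows of A to bound
# memory. Returns a 2-column integer matrix.
pbc_pairs <- function(A, B, box, cutoff, max_cells = 4e6) {
  nA <- nrow(A); nB <- nrow(B)
  out <- vector("list", 0L)
  if (nA == 0L || nB == 0L)
    return(matrix(integer(0), ncol = 2))
  c2 <- cutoff^2
  chunk <- max(1L, as.integer(max_cells / nB))
  starts <- seq.int(1L, nA, by = chunk)
  bx <- B[, 1]; by <- B[, 2]; bz <- B[, 3]
  for (s in starts) {
    e <- min(s + chunk - 1L, nA)
    idx <- s:e
    dx <- outer(A[idx, 1], bx, "-"); dx <- dx - box[1] * round(dx / box[1])
    dy <- outer(A[idx, 2], by, "-"); dy <- dy - box[2] * round(dy / box[2])
    dz <- outer(A[idx, 3], bz, "-"); dz <- dz - box[3] * round(dz / box[3])
    hit <- which(dx * dx + dy * dy + dz * dz <= c2, arr.ind = TRUE)
    if (nrow(hit)) {
      hit[, 1] <- hit[, 1] + s - 1L
      out[[length(out) + 1L]] <- hit
    }
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

bead_xyz <- function(frame, sel) {
  as.matrix(frame$beads[sel, c("x", "y", "z"), drop = FALSE])
}
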