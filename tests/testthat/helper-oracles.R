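# independent brute-force oracles: explicit 27-image enumeration, kept
# deliberately separate from the package's single-round minimum-image path

oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# full pairwise minimum-over-27-images distance matrix
oracle_dist_matrix <- function(A, B, box) {
  D <- NULL
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    dx <- outer(A[, 1], B[, 1] + i * box[1], "-")
    dy <- outer(A[, 2], B[, 2] + j * box[2], "-")
    dz <- outer(A[, 3], B[, 3] + k * box[3], "-")
    d <- sqrt(dx^2 + dy^2 + dz^2)
    D <- if (is.null(D)) d else pmin(D, d)
  }
  D
}

oracle_count <- function(frame, sel_a, sel_b, cutoff, counting) {
  A <- as.matrix(frame$beads[sel_a, c("x", "y", "z"), drop = FALSE])
  B <- as.matrix(frame$beads[sel_b, c("x", "y", "z"), drop = FALSE])
  if (!nrow(A) || !nrow(B)) return(0L)
  D <- oracle_dist_matrix(A, B, frame$box)
  mol <- frame$beads$molecule_index
  ok <- D <= cutoff & outer(mol[sel_a], mol[sel_b], "!=")
  hit <- which(ok, arr.ind = TRUE)
  if (!nrow(hit)) return(0L)
  ga <- sel_a[hit[, 1]]; gb <- sel_b[hit[, 2]]
  ma <- mol[ga]; mb <- mol[gb]
  if (counting == "bead_pairs")
    return(length(unique(paste(pmin(ga, gb), pmax(ga, gb)))))
  if (counting == "unordered_pairs")
    return(length(unique(paste(pmin(ma, mb), pmax(ma, mb)))))
  length(unique(paste(ma, mb)))
}
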