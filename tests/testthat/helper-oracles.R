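# Independent brute-force oracles used across tests. These deliberately do
# not share code with the package implementation.

# Published H+4 census counts for the HPt family (~10k non-redundant
# sequences), used as a fixed input table.
H4_COUNTS <- c(G = 8757, S = 1051, P = 98, A = 76, T = 31, N = 28, H = 12,
               E = 6, D = 4, R = 3, V = 2, I = 1, C = 1, L = 1, Q = 1,
               Y = 1, W = 0)

# column-by-column identity scan: matches over columns where both rows carry
# a non-X residue
bruteIdentity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  num <- 0L; den <- 0L
  for (j in seq_along(ca)) {
    if (ca[j] != "-" && cb[j] != "-" && ca[j] != "X" && cb[j] != "X") {
      den <- den + 1L
      if (ca[j] == cb[j]) num <- num + 1L
    }
  }
  if (den == 0L) 0 else num / den
}

# greedy first-match clustering driven by an exhaustively computed all-pairs
# identity matrix
bruteGreedyClusters <- function(rows, ids, threshold) {
  n <- length(rows)
  im <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    im[i, j] <- bruteIdentity(rows[i], rows[j])
  reps <- integer(0)
  members <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (im[i, reps[k]] >= threshold) {
        members[[k]] <- c(members[[k]], ids[i]); placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- ids[i]
    }
  }
  names(members) <- ids[reps]
  members
}

# all-pairs vdW overlap scan over two atom tables
bruteClashPairs <- function(A, B, radii, threshold) {
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
              (A$z[i] - B$z[j])^2)
    ov <- radii[[toupper(A$element[i])]] + radii[[toupper(B$element[j])]] - d
    if (ov > threshold)
      out <- rbind(out, data.frame(i = i, j = j, overlap = ov))
  }
  out
}

# random proper rotation matrix (QR of a Gaussian matrix, det corrected)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
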