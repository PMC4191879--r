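# Independent brute-force oracles used to cross-check the package's
# implementations.  Each is written from the definition, not by calling
# the code under test.

# --- two-round hierarchical ranking, as one lexicographic sort ----------
# r1, r2: named numeric vectors (Inf = no pose).  Returns channel names in
# final order.
oracle_rank <- function(r1, r2, tie = 1.0) {
  ch <- names(r1)
  if (all(!is.finite(r1))) return(character())
  best <- min(r1)
  bucket <- is.finite(r1) & (r1 - best < tie)
  # lexicographic key: (outside-bucket flag, round-2 score inside the
  # bucket / round-1 score outside, round-1 score, original position)
  key1 <- as.numeric(!bucket)
  key2 <- ifelse(bucket, r2, r1)
  ord <- order(key1, key2, r1, seq_along(ch))
  ch[ord]
}

# random representative-score tables over channels A, B, C
random_rep_scores <- function(p_no_pose = 0.1) {
  ch <- c("A", "B", "C")
  r1 <- round(stats::runif(3, -80, -20), 2)
  r2 <- round(stats::runif(3, -80, -20), 2)
  np1 <- stats::runif(3) < p_no_pose
  np2 <- stats::runif(3) < p_no_pose
  r1[np1] <- Inf
  r2[np2] <- Inf
  names(r1) <- names(r2) <- ch
  list(r1 = r1, r2 = r2)
}

# build a one-enzyme table directly from named intermediate scores
make_table <- function(scores, enzyme = "E", mode = "absolute") {
  score_table(enzyme, names(scores), unname(scores), mode = mode)
}

# --- endpoint first-non-binder scan -------------------------------------
# scores: numeric in channel order (NA = no pose), idx: 1-based indices.
# Returns list(best_i, terminate_after, ruled_out_idx).
oracle_endpoint <- function(scores, idx, binder_threshold = 0) {
  cand <- which(idx >= 2 & !is.na(scores))
  best_i <- cand[which.min(scores[cand])]
  nb <- is.na(scores) | scores > binder_threshold
  term <- idx[length(idx)]
  for (k in seq_along(idx)) {
    if (k > best_i && nb[k]) { term <- idx[k] - 1; break }
  }
  list(best_i = best_i, terminate_after = term,
       ruled_out_idx = idx[idx > term])
}

# --- dihedral via an independent formula --------------------------------
# projects the outer bonds onto the plane normal to the central bond and
# takes the signed angle between the projections
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b2 / sqrt(sum(b2^2))
  v1 <- -b1 + sum(b1 * u) * u   # component of p1 direction perp to axis
  v2 <- b3 - sum(b3 * u) * u
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sum(cr * u) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# --- optimal-superposition RMSD via Horn's quaternion method ------------
oracle_kabsch_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  M <- t(A0) %*% B0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
                Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
                Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
                Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz),
              4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ssd <- sum(A0^2) + sum(B0^2) - 2 * lam
  sqrt(max(ssd, 0) / nrow(A))
}

# --- Smith-Waterman local alignment via an independent Gotoh DP ---------
# gap of length L costs open + L * extend; X scores 0 against everything
oracle_sw <- function(a, b, mat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (deletion from b)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - extend,
                             E[i + 1, j] - extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - extend,
                             F[i, j + 1] - extend)
      s <- mat[a[i], b[j]]
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# --- connected components via union-find --------------------------------
oracle_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, "")
  unname(lapply(split(ids, roots), sort))
}

# small helper: coordinates of a pose (tests poke at geometry a lot)
coords_of <- function(pose) as.matrix(pose$atoms[, c("x", "y", "z")])
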