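# Independent oracles used across the suite. They share no code with the
# package solver: brute-force grid search for the constrained objective,
# exhaustive pair counting for AUC, closed forms where they exist.

# Literal objective of a coefficient vector: 0.5*RSS + lambda*sum|w|
literal_objective <- function(w, x, y, lambda) {
  0.5 * sum((y - x %*% w)^2) + lambda * sum(abs(w))
}

# Brute-force constrained minimum of the literal objective by iteratively
# refined grid search over the region {|w_j1| >= ... >= |w_j,l_max|}.
oracle_grid_min <- function(x, y, lambda, l_max, monotone = TRUE,
                            n_grid = 9, refine = 6) {
  P <- ncol(x)
  ls <- qr.solve(crossprod(x) + diag(1e-6 * max(1, sum(diag(crossprod(x)))), P),
                 crossprod(x, y))
  half <- max(1, max(abs(ls))) * 1.5
  centers <- rep(0, P)
  best <- Inf
  for (r in seq_len(refine)) {
    grids <- lapply(seq_len(P), function(j) {
      seq(centers[j] - half, centers[j] + half, length.out = n_grid)
    })
    W <- as.matrix(expand.grid(grids))
    if (monotone && l_max > 1) {
      keep <- rep(TRUE, nrow(W))
      for (j in seq_len(P %/% l_max)) {
        blk <- abs(W[, ((j - 1) * l_max + 1):(j * l_max), drop = FALSE])
        for (k in seq_len(l_max - 1)) {
          keep <- keep & (blk[, k] >= blk[, k + 1] - 1e-12)
        }
      }
      W <- W[keep, , drop = FALSE]
    }
    resid <- matrix(y, nrow(x), nrow(W)) - x %*% t(W)
    obj <- 0.5 * colSums(resid^2) + lambda * rowSums(abs(W))
    i <- which.min(obj)
    best <- obj[i]
    centers <- W[i, ]
    half <- 2 * half / (n_grid - 1)   # zoom to one coarse-grid step
  }
  list(objective = best, w = centers)
}

# Exhaustive Mann-Whitney AUC with half credit for ties; scores NA = bottom.
oracle_pair_auc <- function(score, is_true) {
  score[is.na(score)] <- -Inf
  s_t <- score[is_true]
  s_f <- score[!is_true]
  tot <- 0
  for (a in s_t) for (b in s_f) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s_t) * length(s_f))
}

# Fine-grid projection oracle: minimise ||u - v||^2 over non-increasing u
# with coordinates on a grid.
oracle_projection <- function(v, n_grid = 61) {
  rng <- range(v)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  combos <- as.matrix(expand.grid(rep(list(grid), length(v))))
  keep <- rep(TRUE, nrow(combos))
  for (k in seq_len(length(v) - 1)) {
    keep <- keep & combos[, k] >= combos[, k + 1]
  }
  combos <- combos[keep, , drop = FALSE]
  d <- colSums((t(combos) - v)^2)
  combos[which.min(d), ]
}
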