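# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small random lagged design with block structure (p predictors x l_max lags)
random_problem <- function(n, p, l_max, seed, sd_noise = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p * l_max), n, p * l_max)
  w <- rnorm(p * l_max)
  y <- drop(x %*% w) + rnorm(n, sd = sd_noise)
  list(x = x, y = y, l_max = l_max)
}

# tiny lagged problem drawn from actual lagged time-series data, the model
# class the method targets (lag blocks are autocorrelated, not iid)
random_lagged_problem <- function(p, l_max, n_time, seed) {
  if (p == 1) {
    set.seed(seed)
    x <- numeric(n_time + 1)
    for (t in seq_len(n_time)) {
      x[t + 1] <- 0.6 * x[t] + rnorm(1, sd = 0.3)
    }
    d <- expr_ts(tibble::tibble(time = seq_len(n_time), gene = "g1",
                                expression = x[-1]))
  } else {
    m <- sparse_var_model(p, max(1, p - 1), l_max_true = 1, noise_sd = 0.3,
                          seed = seed)
    d <- simulate_var(m, n_time, seed = seed + 1000)
  }
  pr <- build_lagged_problem(d, sample(genes(d), 1), l_max)
  list(x = pr$x, y = pr$y, l_max = l_max)
}

# weakly coupled VAR dataset with its generating model
var_dataset <- function(seed, noise_sd = 0.1, p = 6, n_edges = 6,
                        n_time = 200, n_series = 1) {
  m <- sparse_var_model(p, n_edges, noise_sd = noise_sd, seed = seed)
  d <- simulate_var(m, n_time, n_series = n_series, seed = seed + 100)
  list(model = m, data = d)
}

# lasso irrepresentable condition on the realized design, per target:
# identifiability certificate for exact support recovery, computable
# without running the solver
irrepresentable_ok <- function(data, model) {
  gn <- genes(data)
  all(vapply(seq_along(gn), function(i) {
    pr <- build_lagged_problem(data, gn[i], 1)
    x <- scale(pr$x)
    a <- model$A[, i, 1]
    S <- which(abs(a) > 0)
    if (length(S) == 0 || length(S) == ncol(x)) return(TRUE)
    xs <- x[, S, drop = FALSE]
    xc <- x[, -S, drop = FALSE]
    v <- abs(t(xc) %*% xs %*% solve(crossprod(xs), sign(a[S])))
    max(v) < 1
  }, logical(1)))
}

edge_key <- function(edges) paste(edges$source, edges$target)
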