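#' Simulate a repressilator time course
#'
#' Integrates the three-gene cyclic-repression oscillator
#' \deqn{\dot x = \alpha/(1+z^n) - x,\quad \dot y = \alpha/(1+x^n) - y,\quad
#'       \dot z = \alpha/(1+y^n) - z}
#' with an adaptive solver (deSolve's lsoda, rtol 1e-8 / atol 1e-10) and
#' samples the trajectory every `dt` time units. Each gene represses the
#' next around the cycle, so the ground truth is the directed ring
#' z -> x -> y -> z, attached to the result as the `truth` attribute.
#'
#' With production strength `alpha = 4` and Hill coefficient `hill = 3` the
#' system oscillates for generic starting points; the default initial state
#' is slightly asymmetric because on the symmetric manifold x = y = z the
#' dynamics collapse to a single decaying coordinate. Choose `dt` away from
#' integer multiples of the oscillation period, otherwise the samples are
#' effectively constant.
#'
#' @param alpha Production strength (expression units per time).
#' @param hill Hill coefficient of the repression (dimensionless).
#' @param t_end Total simulated time.
#' @param dt Sampling interval; must not exceed `t_end`.
#' @param init Length-3 non-negative initial state `(x, y, z)`.
#' @param rtol,atol Integrator tolerances.
#' @return An [expr_ts] with genes `x`, `y`, `z` and one series; the
#'   `truth` attribute holds the 3-edge ring.
#' @examples
#' sim <- simulate_repressilator(t_end = 6 * pi, dt = 6 * pi / 64)
#' truth_network(sim)
#' @export
simulate_repressilator <- function(alpha = 4, hill = 3,
                                   t_end = 6 * pi, dt = 6 * pi / 256,
                                   init = c(x = 1, y = 1.2, z = 1.5),
                                   rtol = 1e-8, atol = 1e-10) {
  stopifnot(alpha > 0, hill > 0, t_end > 0, dt > 0, dt <= t_end,
            length(init) == 3L, all(init >= 0))
  names(init) <- c("x", "y", "z")
  deriv <- function(t, state, parms) {
    x <- state[1]; y <- state[2]; z <- state[3]
    list(c(alpha / (1 + z^hill) - x,
           alpha / (1 + x^hill) - y,
           alpha / (1 + y^hill) - z))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  m <- t(unclass(sol)[, c("x", "y", "z"), drop = FALSE])
  out <- as_expr_ts(list(`1` = m), dt = dt, gene_names = c("x", "y", "z"))
  attr(out, "truth") <- tibble::tibble(source = c("z", "x", "y"),
                                       target = c("x", "y", "z"))
  out
}

#' Sparse stable vector-autoregression model
#'
#' Draws a random sparse coefficient tensor `A[source, target, lag]` for a
#' VAR process and rescales it until the companion matrix has spectral
#' radius below `spectral_target`, so the process is stationary. When
#' `monotone_truth` is set, coefficient magnitudes within each (source,
#' target) pair are sorted to be non-increasing in the lag, matching the
#' model class the ordered lasso assumes.
#'
#' The defaults put the process in a weak-coupling regime — a first-lag
#' self-memory of `self_coef` on every gene (mRNA persistence; it also
#' guarantees every trajectory stays excited even without innovations) with
#' cross-gene coefficients of smaller magnitude. This is the regime in
#' which sparse support recovery is well posed: strongly coupled draws
#' frequently violate the lasso irrepresentable condition and no method can
#' recover their support exactly.
#'
#' @param p Number of genes.
#' @param n_edges Number of directed cross-gene edges (coefficients drawn
#'   for lag 1..`l_max_true`).
#' @param l_max_true True maximum lag of the process.
#' @param noise_sd Innovation standard deviation.
#' @param coef_range Magnitude range for drawn cross coefficients before
#'   rescaling.
#' @param self_coef First-lag autoregressive coefficient given to every
#'   gene. Self-pairs are not listed in the truth edge set: predicted
#'   networks and ROC candidate sets exclude self-edges by default.
#' @param spectral_target Upper bound imposed on the companion spectral
#'   radius.
#' @param monotone_truth Sort magnitudes within each pair to decay with lag?
#' @param seed Integer seed for the draw.
#' @return A `var_model`: list with array `A` (`p x p x l_max_true`),
#'   `noise_sd`, `gene_names`, and the cross-gene edge list of its support.
#' @export
sparse_var_model <- function(p, n_edges, l_max_true = 1, noise_sd = 0.1,
                             coef_range = c(0.25, 0.45),
                             self_coef = 0.5,
                             spectral_target = 0.95,
                             monotone_truth = TRUE, seed = 1) {
  stopifnot(p >= 2, n_edges >= 1, n_edges <= p * (p - 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pairs <- expand.grid(source = seq_len(p), target = seq_len(p))
  pairs <- pairs[pairs$source != pairs$target, ]
  picked <- pairs[sample(nrow(pairs), n_edges), ]
  A <- array(0, dim = c(p, p, l_max_true))
  for (r in seq_len(nrow(picked))) {
    mags <- stats::runif(l_max_true, coef_range[1], coef_range[2])
    if (monotone_truth) mags <- sort(mags, decreasing = TRUE)
    signs <- sample(c(-1, 1), l_max_true, replace = TRUE)
    A[picked$source[r], picked$target[r], ] <- signs * mags
  }
  for (i in seq_len(p)) A[i, i, 1] <- self_coef
  rho <- var_spectral_radius(A)
  if (rho >= spectral_target) {
    A <- A * (spectral_target / rho) * 0.999
  }
  gn <- paste0("g", seq_len(p))
  edges <- tibble::tibble(source = gn[picked$source],
                          target = gn[picked$target])
  edges <- dplyr::arrange(edges, match(.data$target, gn),
                          match(.data$source, gn))
  structure(list(A = A, noise_sd = noise_sd, gene_names = gn,
                 edges = edges),
            class = "var_model")
}

#' Simulate time series from a VAR model
#'
#' Generates `x_t = sum_k A[,,k]' x_{t-k} + eps_t` with Gaussian
#' innovations after a burn-in, one or more independent replicate series.
#' The model's support is attached as the `truth` attribute: edge
#' `(j, i)` iff any `A[j, i, k]` is non-zero.
#'
#' @param model A `var_model` (see [sparse_var_model()]).
#' @param n_time Sampled time points per series.
#' @param n_series Number of replicate series.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param burn_in Initial steps discarded before sampling. Defaults to 100
#'   for noisy models; for noiseless models the default is 0, since the
#'   signal is the decaying transient from the random initial state.
#' @return An [expr_ts] with `dt = 1` and a `truth` attribute.
#' @export
simulate_var <- function(model, n_time, n_series = 1, seed = 1,
                         burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- if (model$noise_sd > 0) 100L else 0L
  stopifnot(inherits(model, "var_model"), n_time >= 2, n_series >= 1)
  rho <- var_spectral_radius(model$A)
  if (rho >= 1) {
    stop("VAR model is non-stationary (companion spectral radius ",
         format(rho, digits = 4), ")", call. = FALSE)
  }
  p <- dim(model$A)[1]
  K <- dim(model$A)[3]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  series <- lapply(seq_len(n_series), function(s) {
    total <- burn_in + n_time
    xm <- matrix(0, p, total + K)
    if (model$noise_sd > 0) {
      xm[, seq_len(K)] <- stats::rnorm(p * K, sd = model$noise_sd)
    } else {
      xm[, seq_len(K)] <- stats::rnorm(p * K, sd = 1)
    }
    for (t in (K + 1L):(total + K)) {
      acc <- numeric(p)
      for (k in seq_len(K)) {
        acc <- acc + crossprod(model$A[, , k], xm[, t - k])[, 1]
      }
      eps <- if (model$noise_sd > 0) {
        stats::rnorm(p, sd = model$noise_sd)
      } else numeric(p)
      xm[, t] <- acc + eps
    }
    m <- xm[, (K + burn_in + 1L):(K + total), drop = FALSE]
    rownames(m) <- model$gene_names
    m
  })
  names(series) <- as.character(seq_len(n_series))
  out <- as_expr_ts(series, dt = 1, gene_names = model$gene_names)
  attr(out, "truth") <- model$edges
  out
}

#' AUC table over simulation-design settings
#'
#' For every combination of series length, sampling interval, and maximum
#' lag, simulates a repressilator time course, runs each requested method's
#' edge-ranking path, and scores it against the true ring with the
#' merged-lambda ROC AUC. Cells where the sampled series is too short for
#' the requested lag (or, for Granger, leaves no residual degrees of
#' freedom) are reported as skipped.
#'
#' @param t_values,dt_values,l_max_values Grids of series length, sampling
#'   interval, and maximum lag.
#' @param methods Subset of `"ordered_lasso"`, `"lasso_granger"`,
#'   `"granger"`.
#' @param alpha,hill Repressilator parameters.
#' @param n_lambda Penalty-grid size for the lasso-type methods.
#' @return Long tibble with columns `t_end`, `dt`, `l_max`, `method`,
#'   `auc`, `skipped`.
#' @export
experiment_grid <- function(t_values, dt_values, l_max_values,
                            methods = c("ordered_lasso", "lasso_granger",
                                        "granger"),
                            alpha = 4, hill = 3, n_lambda = 100) {
  stopifnot(length(t_values) >= 1, length(dt_values) >= 1,
            length(l_max_values) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- tidyr::expand_grid(t_end = t_values, dt = dt_values,
                              l_max = l_max_values, method = methods)
  purrr::pmap_dfr(cells, function(t_end, dt, l_max, method) {
    res <- tibble::tibble(t_end = t_end, dt = dt, l_max = l_max,
                          method = method, auc = NA_real_, skipped = TRUE)
    if (dt > t_end) return(res)
    n_points <- length(seq(0, t_end, by = dt))
    if (n_points < l_max + 2) return(res)
    sim <- simulate_repressilator(alpha = alpha, hill = hill,
                                  t_end = t_end, dt = dt)
    auc <- tryCatch({
      if (method == "granger") {
        gr <- pairwise_granger(sim, l_max)
        roc_edges(gr, truth_network(sim))$auc
      } else {
        path <- edge_entry_path(sim, l_max, n_lambda = n_lambda,
                                monotone = method == "ordered_lasso")
        roc_edges(path, truth_network(sim))$auc
      }
    }, error = function(e) NA_real_)
    res$auc <- auc
    res$skipped <- is.na(auc)
    res
  })
}

# ---- internals -------------------------------------------------------------

# spectral radius of the VAR companion matrix
var_spectral_radius <- function(A) {
  p <- dim(A)[1]
  K <- dim(A)[3]
  comp <- matrix(0, p * K, p * K)
  for (k in seq_len(K)) {
    comp[seq_len(p), ((k - 1) * p + 1):(k * p)] <- t(A[, , k])
  }
  if (K > 1) {
    comp[(p + 1):(p * K), seq_len(p * (K - 1))] <- diag(p * (K - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# save/restore the global RNG state so simulators are seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
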