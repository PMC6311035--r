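#' Time-lagged Ordered Lasso solver
#'
#' Fits the l1-penalised least-squares model in which each predictor
#' contributes `l_max` lagged columns and, within each predictor, the
#' coefficient magnitudes are constrained to be non-increasing in the lag:
#' `|w[j,1]| >= |w[j,2]| >= ... >= |w[j,l_max]|`. The objective is
#'
#' \deqn{\tfrac12 \sum_t \big(y_t - \sum_{j,k} w_{jk} x_{t,jk}\big)^2 +
#'       \lambda \sum_j m_j \sum_k |w_{jk}|}
#'
#' where `m_j` is an optional per-predictor penalty multiplier (used by the
#' semi-supervised variant to penalise prior edges and non-edges differently).
#' With `monotone = FALSE` the constraint is dropped and the fit is an
#' ordinary lasso (the Lasso-Granger model).
#'
#' The solver is accelerated proximal gradient descent in the coefficient
#' space. The proximal step for one lag block is exact: the optimal signs
#' equal the signs of the gradient-step point, and the optimal magnitudes
#' are the non-increasing isotonic regression of the point's magnitudes
#' shifted by the penalty, clipped at zero. Every iterate therefore
#' satisfies the magnitude constraint exactly. The constraint region (a
#' union of sign cones) is non-convex, so the fit is a stationary point;
#' on small problems it matches brute-force global search (see the test
#' suite). Momentum is discarded whenever it would increase the objective,
#' so the recorded objective history is non-increasing.
#'
#' @param x Numeric matrix with `p * l_max` columns: predictor blocks are
#'   consecutive, ordered by increasing lag within a block.
#' @param y Numeric response vector, `length(y) == nrow(x)`.
#' @param lambda Non-negative penalty level.
#' @param l_max Number of lagged columns per predictor block.
#' @param penalty Optional non-negative per-predictor multipliers (length
#'   `p`); defaults to 1 for every block.
#' @param monotone Enforce the non-increasing magnitude constraint?
#' @param standardize Centre `y` and all columns and scale each predictor
#'   block by its pooled standard deviation before fitting (the penalty then
#'   acts on the standardised scale); coefficients are mapped back. An
#'   intercept is implied by the centring and returned separately.
#' @param maxit,tol Iteration cap and relative objective-change tolerance.
#' @param init Optional warm start: a previous `ordered_lasso_fit` on the
#'   same problem (typically at a larger lambda).
#' @return An object of class `ordered_lasso_fit`: coefficient matrix `w`
#'   (`p` rows, `l_max` columns), `intercept`, `lambda`, objective history,
#'   convergence flag, and solver internals used for warm starts.
#' @seealso [lambda_zero()] for the smallest lambda with an all-zero fit,
#'   [infer_network_denovo()] for the network-level pipeline.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x[, 1] - 0.5 * x[, 2] + rnorm(20, sd = 0.1)
#' fit <- ordered_lasso(x, y, lambda = 1, l_max = 1)
#' coef(fit)
#' @export
ordered_lasso <- function(x, y, lambda, l_max,
                          penalty = NULL,
                          monotone = TRUE,
                          standardize = TRUE,
                          maxit = 10000L,
                          tol = 1e-8,
                          init = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1L)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  }
  l_max <- as.integer(l_max)
  if (l_max < 1L || ncol(x) %% l_max != 0L) {
    stop("`ncol(x)` must be a multiple of `l_max`", call. = FALSE)
  }
  p <- ncol(x) %/% l_max
  if (is.null(penalty)) penalty <- rep(1, p)
  if (length(penalty) != p || any(penalty < 0)) {
    stop("`penalty` must be ", p, " non-negative multipliers", call. = FALSE)
  }

  std <- ol_standardize(x, y, l_max, standardize)
  n_col <- ncol(x)
  lam_col <- lambda * rep(penalty, each = l_max)   # per-column penalty level

  XtX <- crossprod(std$x)
  Xty <- crossprod(std$x, std$y)[, 1]
  yty <- sum(std$y^2)
  lips <- ol_spectral_norm(XtX)

  if (!is.null(init)) {
    if (!inherits(init, "ordered_lasso_fit") ||
        length(init$.w_std) != n_col) {
      stop("`init` must be an ordered_lasso_fit on the same problem",
           call. = FALSE)
    }
    b0 <- init$.w_std
  } else {
    b0 <- numeric(n_col)
  }

  sol <- ol_prox_solve(XtX, Xty, yty, lam_col, l_max, monotone,
                       b0, lips, maxit, tol)
  if (monotone && l_max > 1L && is.null(init)) {
    # second start seeded by the unconstrained lasso: the constraint region
    # is a union of sign cones, and a cold start can settle in the wrong
    # cone; the lasso solution usually identifies the right one
    seed_fit <- ol_prox_solve(XtX, Xty, yty, lam_col, l_max, FALSE,
                              b0, lips, maxit, tol)
    sol2 <- ol_prox_solve(XtX, Xty, yty, lam_col, l_max, monotone,
                          seed_fit$w, lips, maxit, tol)
    if (sol2$history[length(sol2$history)] <
        sol$history[length(sol$history)]) {
      sol <- sol2
    }
  }

  b <- sol$w
  w <- b / rep(std$scale, each = l_max)            # back to original units
  wmat <- matrix(w, nrow = p, ncol = l_max, byrow = TRUE)
  pred_names <- ol_block_names(x, p, l_max)
  rownames(wmat) <- pred_names
  colnames(wmat) <- paste0("lag", seq_len(l_max))
  intercept <- std$y_center - sum(std$x_center * w)

  structure(
    list(
      w = wmat,
      intercept = intercept,
      lambda = lambda,
      penalty = penalty,
      l_max = l_max,
      monotone = monotone,
      standardize = standardize,
      objective = sol$history[length(sol$history)],
      objective_history = sol$history,
      converged = sol$converged,
      n_iter = sol$n_iter,
      .w_std = sol$w
    ),
    class = "ordered_lasso_fit"
  )
}

#' @export
coef.ordered_lasso_fit <- function(object, ...) object$w

#' @export
print.ordered_lasso_fit <- function(x, ...) {
  nz <- sum(rowSums(abs(x$w)) > 1e-10)
  cat("Time-lagged ", if (x$monotone) "Ordered " else "", "Lasso fit\n",
      "  predictors: ", nrow(x$w), " (", nz, " active), l_max = ", x$l_max,
      ", lambda = ", format(x$lambda, digits = 4), "\n",
      "  objective = ", format(x$objective, digits = 6),
      ", iterations = ", x$n_iter, "\n", sep = "")
  invisible(x)
}

#' Smallest penalty yielding the all-zero solution
#'
#' Returns the threshold `L` such that the (ordered) lasso fit is identically
#' zero for every `lambda >= L` and has at least one active coefficient just
#' below `L`. The threshold is exact: the zero vector is optimal iff, for
#' every predictor block, the penalty dominates every prefix mean of the
#' magnitudes of the column-response inner products (the extreme rays of the
#' constraint cone are prefix indicators), so `L` is the largest such prefix
#' mean divided by the block multiplier. Without the monotone constraint the
#' prefix reduces to single columns and this is the familiar `max |x_j' y|`
#' rule.
#'
#' @inheritParams ordered_lasso
#' @return A single non-negative number; 0 (with a warning) when the centred
#'   response has no variance.
#' @export
lambda_zero <- function(x, y, l_max,
                        penalty = NULL,
                        monotone = TRUE,
                        standardize = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  l_max <- as.integer(l_max)
  stopifnot(nrow(x) == length(y), ncol(x) %% l_max == 0L)
  p <- ncol(x) %/% l_max
  if (is.null(penalty)) penalty <- rep(1, p)
  if (any(penalty <= 0)) {
    stop("`penalty` multipliers must be positive for lambda_zero",
         call. = FALSE)
  }
  std <- ol_standardize(x, y, l_max, standardize)
  if (sum(std$y^2) == 0) {
    warning("response has zero variance; lambda_zero is 0")
    return(0)
  }
  cc <- crossprod(std$x, std$y)[, 1]
  per_block <- vapply(seq_len(p), function(j) {
    cj <- cc[((j - 1L) * l_max + 1L):(j * l_max)]
    if (monotone) {
      max(cumsum(abs(cj)) / seq_along(cj)) / penalty[j]
    } else {
      max(abs(cj)) / penalty[j]
    }
  }, numeric(1))
  max(per_block)
}

# ---- internals -------------------------------------------------------------

# Centre y/columns; scale each predictor block by one pooled sd so the
# monotone constraint and penalty act on a common within-block scale.
ol_standardize <- function(x, y, l_max, standardize) {
  n <- nrow(x)
  p <- ncol(x) %/% l_max
  if (!standardize) {
    return(list(x = x, y = y, x_center = rep(0, ncol(x)),
                y_center = 0, scale = rep(1, p)))
  }
  x_center <- colMeans(x)
  xc <- sweep(x, 2L, x_center)
  y_center <- mean(y)
  yc <- y - y_center
  scale <- vapply(seq_len(p), function(j) {
    blk <- xc[, ((j - 1L) * l_max + 1L):(j * l_max), drop = FALSE]
    s <- sqrt(mean(blk^2))
    if (s > 0) s else 1
  }, numeric(1))
  xs <- sweep(xc, 2L, rep(scale, each = l_max), `/`)
  list(x = xs, y = yc, x_center = x_center, y_center = y_center,
       scale = scale)
}

ol_spectral_norm <- function(XtX) {
  if (nrow(XtX) == 0L) return(0)
  max(0, eigen(XtX, symmetric = TRUE, only.values = TRUE)$values[1])
}

# Exact prox of lam*sum|w| + indicator{|w| non-increasing within block}:
# optimal signs follow the input point; optimal magnitudes are the
# non-increasing isotonic fit of |v| - lam, clipped at zero (clipping the
# monotone projection is exact for order constraints with bounds).
ol_prox <- function(z, step_lam, l_max, monotone) {
  if (!monotone || l_max == 1L) {
    return(sign(z) * pmax(abs(z) - step_lam, 0))
  }
  n_blk <- length(z) %/% l_max
  out <- numeric(length(z))
  for (j in seq_len(n_blk)) {
    idx <- ((j - 1L) * l_max + 1L):(j * l_max)
    u <- pmax(project_nonincreasing(abs(z[idx]) - step_lam[idx]), 0)
    out[idx] <- sign(z[idx]) * u
  }
  out
}

ol_objective <- function(b, XtX, Xty, yty, lam_col) {
  0.5 * (sum(b * (XtX %*% b)) - 2 * sum(b * Xty) + yty) +
    sum(lam_col * abs(b))
}

ol_prox_solve <- function(XtX, Xty, yty, lam_col, l_max, monotone,
                          b, lips, maxit, tol) {
  if (lips <= 0) {
    # design has no signal; the zero vector is optimal
    return(list(w = numeric(length(b)), history = 0.5 * yty,
                converged = TRUE, n_iter = 0L))
  }
  step <- 1 / lips
  step_lam <- step * lam_col
  v <- b
  t_mom <- 1
  f_cur <- ol_objective(b, XtX, Xty, yty, lam_col)
  history <- numeric(maxit + 1L)
  history[1L] <- f_cur
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    g <- (XtX %*% v)[, 1] - Xty
    b_new <- ol_prox(v - step * g, step_lam, l_max, monotone)
    f_new <- ol_objective(b_new, XtX, Xty, yty, lam_col)
    if (f_new > f_cur) {
      # momentum overshoot: plain proximal step, which cannot ascend
      g <- (XtX %*% b)[, 1] - Xty
      b_new <- ol_prox(b - step * g, step_lam, l_max, monotone)
      f_new <- ol_objective(b_new, XtX, Xty, yty, lam_col)
      t_mom <- 1
      v <- b_new
    } else {
      t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
      v <- b_new + ((t_mom - 1) / t_next) * (b_new - b)
      t_mom <- t_next
    }
    history[iter + 1L] <- f_new
    if (abs(f_cur - f_new) <= tol * max(1, abs(f_cur))) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
    f_cur <- f_new
  }
  history <- history[seq_len(iter + 1L)]
  if (!converged) {
    cond <- structure(
      class = c("lagnet_convergence_error", "error", "condition"),
      list(message = sprintf(
        "ordered lasso solver did not converge in %d iterations (last relative change %.3g)",
        maxit, abs(diff(utils::tail(history, 2))) / max(1, abs(history[length(history) - 1L]))),
        call = NULL,
        last_w = b, objective_history = history)
    )
    stop(cond)
  }
  list(w = b, history = history, converged = TRUE, n_iter = iter)
}

ol_block_names <- function(x, p, l_max) {
  cn <- colnames(x)
  if (!is.null(cn)) {
    first <- cn[seq(1L, by = l_max, length.out = p)]
    base <- sub("[._]lag[0-9]+$", "", first)
    if (!anyDuplicated(base)) return(base)
  }
  paste0("p", seq_len(p))
}
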