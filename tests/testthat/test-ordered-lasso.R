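test_that("non-increasing projection handles trivial and pooled cases", {
  expect_equal(project_nonincreasing(c(3, 1)), c(3, 1))
  expect_equal(project_nonincreasing(c(1, 3)), c(2, 2))
  expect_equal(project_nonincreasing(5), 5)
  expect_error(project_nonincreasing(c(1, NA)), "non-finite")
  expect_error(project_nonincreasing(numeric(0)), "length")
})

test_that("projection matches a brute-force grid oracle", {
  expect_equal(project_nonincreasing(c(1, 5, 3)), c(3, 3, 3))
  expect_equal(oracle_projection(c(1, 5, 3)), c(3, 3, 3),
               ignore_attr = TRUE)
  set.seed(11)
  for (i in 1:5) {
    v <- round(runif(3, -2, 2), 2)
    got <- project_nonincreasing(v)
    ora <- oracle_projection(v)
    # the oracle is grid-limited; compare achieved squared distances
    expect_lte(sum((got - v)^2), sum((ora - v)^2) + 1e-3)
    expect_true(all(diff(got) <= 1e-12))
  }
})

test_that("projection output is always non-increasing and idempotent", {
  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(sample(1:8, 1), sd = 3)
    u <- project_nonincreasing(v)
    expect_true(all(diff(u) <= 1e-12))
    expect_equal(project_nonincreasing(u), u, tolerance = 1e-12)
  }
})

test_that("penalty at or above lambda_zero yields the zero fit, just below it does not", {
  for (seed in 1:5) {
    pr <- random_problem(n = 20, p = 3, l_max = 2, seed = seed)
    lz <- lambda_zero(pr$x, pr$y, pr$l_max)
    hi <- ordered_lasso(pr$x, pr$y, lz * 1.01, pr$l_max)
    lo <- ordered_lasso(pr$x, pr$y, lz * 0.9, pr$l_max)
    expect_true(all(abs(hi$w) <= 1e-10))
    expect_gt(max(abs(lo$w)), 1e-10)
  }
  # without the constraint too
  pr <- random_problem(n = 15, p = 2, l_max = 2, seed = 9)
  lz <- lambda_zero(pr$x, pr$y, pr$l_max, monotone = FALSE)
  expect_true(all(abs(ordered_lasso(pr$x, pr$y, lz * 1.01, pr$l_max,
                                    monotone = FALSE)$w) <= 1e-10))
  expect_gt(max(abs(ordered_lasso(pr$x, pr$y, lz * 0.9, pr$l_max,
                                  monotone = FALSE)$w)), 1e-10)
})

test_that("lambda_zero is zero for an orthogonal or constant response", {
  # response orthogonal to the single column, no standardization
  x <- matrix(c(1, -1, 1, -1), 4, 1)
  y <- c(1, 1, -1, -1)
  expect_equal(lambda_zero(x, y, 1, standardize = FALSE), 0)
  expect_warning(lz <- lambda_zero(x, rep(2, 4), 1), "zero variance")
  expect_equal(lz, 0)
})

test_that("single unit-norm predictor reduces to soft thresholding", {
  set.seed(3)
  x <- matrix(rnorm(30), 30, 1)
  x <- x / sqrt(sum(x^2))
  y <- rnorm(30)
  cc <- sum(x * y)
  expect_equal(lambda_zero(x, y, 1, standardize = FALSE), abs(cc))
  for (lam in c(0.1, 0.5, 0.9) * abs(cc)) {
    fit <- ordered_lasso(x, y, lam, 1, standardize = FALSE)
    expect_equal(drop(fit$w), sign(cc) * (abs(cc) - lam) / sum(x^2),
                 tolerance = 1e-6)
  }
})

test_that("with one lag the constrained fit matches an unconstrained lasso oracle", {
  skip_if_not_installed("glmnet")
  for (seed in 1:4) {
    pr <- random_problem(n = 30, p = 4, l_max = 1, seed = seed)
    xc <- scale(pr$x, scale = FALSE)
    yc <- pr$y - mean(pr$y)
    lam <- 0.3 * lambda_zero(xc, yc, 1, standardize = FALSE)
    mine <- ordered_lasso(xc, yc, lam, 1, standardize = FALSE)
    gfit <- glmnet::glmnet(xc, yc, lambda = lam / length(yc),
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-14)
    expect_equal(drop(mine$w), as.numeric(gfit$beta),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("solver matches the constrained grid-search oracle on tiny problems", {
  for (seed in 1:8) {
    pr <- if (seed %% 2 == 0) {
      random_problem(n = 12, p = 2, l_max = 2, seed = seed)
    } else {
      random_lagged_problem(p = 2, l_max = 2, n_time = 8, seed = seed)
    }
    lam <- 0.3 * lambda_zero(pr$x, pr$y, pr$l_max, standardize = FALSE)
    fit <- ordered_lasso(pr$x, pr$y, lam, pr$l_max, standardize = FALSE)
    mine <- literal_objective(as.numeric(t(fit$w)), pr$x, pr$y, lam)
    ora <- oracle_grid_min(pr$x, pr$y, lam, pr$l_max)$objective
    # one-sided: the solver may legitimately undercut the grid resolution
    expect_lt(mine - ora, 1e-3)
  }
})

test_that("coefficient magnitudes never increase with lag", {
  for (seed in 1:10) {
    pr <- random_lagged_problem(p = 3, l_max = 3, n_time = 15, seed = seed)
    lam <- 0.2 * lambda_zero(pr$x, pr$y, pr$l_max)
    fit <- ordered_lasso(pr$x, pr$y, lam, pr$l_max)
    mags <- abs(fit$w)
    expect_true(all(mags[, -ncol(mags)] - mags[, -1] >= -1e-8))
  }
})

test_that("objective history is non-increasing and warm starts converge faster", {
  pr <- random_problem(n = 25, p = 3, l_max = 2, seed = 31)
  lam <- 0.2 * lambda_zero(pr$x, pr$y, pr$l_max)
  fit <- ordered_lasso(pr$x, pr$y, lam, pr$l_max)
  expect_true(all(diff(fit$objective_history) <= 1e-12))
  # objective no worse than the zero vector's
  zero_obj <- 0.5 * sum((pr$y - mean(pr$y))^2)
  expect_lte(fit$objective, zero_obj + 1e-8)
  warm <- ordered_lasso(pr$x, pr$y, lam * 0.9, pr$l_max, init = fit)
  cold <- ordered_lasso(pr$x, pr$y, lam * 0.9, pr$l_max)
  expect_equal(warm$objective, cold$objective, tolerance = 1e-6)
  expect_lte(warm$n_iter, cold$n_iter + 5)
})

test_that("non-convergence raises a classed error carrying the history", {
  pr <- random_problem(n = 25, p = 3, l_max = 2, seed = 5)
  lam <- 0.1 * lambda_zero(pr$x, pr$y, pr$l_max)
  err <- tryCatch(
    ordered_lasso(pr$x, pr$y, lam, pr$l_max, maxit = 2L, tol = 1e-14),
    lagnet_convergence_error = function(e) e)
  expect_s3_class(err, "lagnet_convergence_error")
  expect_true(length(err$objective_history) >= 2)
  expect_true(is.numeric(err$last_w))
})

test_that("penalty weights rescale the per-block threshold", {
  pr <- random_problem(n = 20, p = 2, l_max = 2, seed = 77)
  lz_even <- lambda_zero(pr$x, pr$y, pr$l_max, penalty = c(1, 1))
  lz_half <- lambda_zero(pr$x, pr$y, pr$l_max, penalty = c(2, 2))
  expect_equal(lz_half, lz_even / 2, tolerance = 1e-12)
  expect_error(lambda_zero(pr$x, pr$y, pr$l_max, penalty = c(0, 1)),
               "positive")
})
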