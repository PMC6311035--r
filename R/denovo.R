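# tolerance below which a back-scaled coefficient counts as zero
ACTIVE_TOL <- 1e-10

#' Shared log-spaced penalty grid for a dataset
#'
#' Computes, for every target gene, the smallest penalty at which its lagged
#' model is entirely zero, and returns a strictly decreasing log-spaced grid
#' from the dataset-wide maximum down to `lambda_min_ratio` times it. A
#' single grid shared across targets makes entry-at-lambda rankings
#' comparable between edges with different targets.
#'
#' @inheritParams build_lagged_problem
#' @param n_lambda Number of grid points.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value.
#' @param monotone Use the ordered-lasso threshold (`TRUE`) or the plain
#'   lasso one.
#' @return Strictly decreasing positive numeric vector.
#' @export
network_lambda_grid <- function(data, l_max, n_lambda = 100,
                                lambda_min_ratio = 1e-4, monotone = TRUE) {
  data <- as_expr_ts(data)
  lz <- vapply(genes(data), function(g) {
    pr <- build_lagged_problem(data, g, l_max)
    suppressWarnings(lambda_zero(pr$x, pr$y, l_max, monotone = monotone))
  }, numeric(1))
  top <- max(lz)
  if (top <= 0) stop("all responses are constant; no informative grid",
                     call. = FALSE)
  exp(seq(log(top), log(top * lambda_min_ratio), length.out = n_lambda))
}

#' De novo network inference at a single penalty
#'
#' Fits the time-lagged Ordered Lasso for every target gene at one penalty
#' level and predicts an edge `source -> target` whenever any lagged
#' coefficient of the source is non-zero. Under the monotone constraint this
#' reduces to checking the first-lag coefficient.
#'
#' @inheritParams build_lagged_problem
#' @param lambda Positive penalty level.
#' @param include_self Keep self-edges (a gene's own lags predicting itself)
#'   in the output? The target's own lags are always part of the design;
#'   this flag only controls reporting.
#' @param monotone Enforce the monotone lag constraint (`FALSE` gives the
#'   Lasso-Granger baseline).
#' @return Tibble with columns `source`, `target`, one row per predicted
#'   edge, with the dataset's gene order in the `gene_names` attribute.
#' @examples
#' sim <- simulate_repressilator(t_end = 6 * pi, dt = 6 * pi / 64)
#' infer_network_denovo(sim, l_max = 1, lambda = 1)
#' @export
infer_network_denovo <- function(data, l_max, lambda, include_self = FALSE,
                                 monotone = TRUE) {
  data <- as_expr_ts(data)
  stopifnot(lambda > 0)
  gn <- genes(data)
  rows <- purrr::map_dfr(gn, function(tg) {
    pr <- build_lagged_problem(data, tg, l_max)
    fit <- tryCatch(
      ordered_lasso(pr$x, pr$y, lambda, l_max, monotone = monotone),
      error = function(e) {
        stop("fit failed for target gene ", tg, ": ", conditionMessage(e),
             call. = FALSE)
      })
    act <- edge_active(fit$w, monotone)
    tibble::tibble(source = gn[act], target = tg)
  })
  if (!include_self) rows <- dplyr::filter(rows, .data$source != .data$target)
  rows <- dplyr::arrange(rows, match(.data$target, gn), match(.data$source, gn))
  attr(rows, "gene_names") <- gn
  rows
}

#' Edge entry values along the penalty path
#'
#' Runs the per-target fits over a decreasing penalty grid (warm-starting
#' each fit from the previous one) and records, for every ordered gene pair,
#' the largest grid penalty at which the edge is active. An edge that leaves
#' and re-enters as the penalty decreases keeps its first (largest) entry
#' value, so thresholding the path at any penalty produces nested predicted
#' edge sets. Pairs that never enter get `NA`.
#'
#' @inheritParams infer_network_denovo
#' @param lambda_grid Strictly decreasing positive grid; computed by
#'   [network_lambda_grid()] when `NULL`.
#' @param n_lambda,lambda_min_ratio Grid parameters when `lambda_grid` is
#'   `NULL`.
#' @return A `lagged_path` object: `entries` tibble
#'   (`source`, `target`, `entry_lambda`), the grid, `l_max`, the method
#'   label, and flags.
#' @export
edge_entry_path <- function(data, l_max, lambda_grid = NULL,
                            n_lambda = 100, lambda_min_ratio = 1e-4,
                            monotone = TRUE, include_self = FALSE) {
  data <- as_expr_ts(data)
  if (is.null(lambda_grid)) {
    lambda_grid <- network_lambda_grid(data, l_max, n_lambda,
                                       lambda_min_ratio, monotone)
  }
  check_lambda_grid(lambda_grid)
  gn <- genes(data)
  entries <- purrr::map_dfr(gn, function(tg) {
    pr <- build_lagged_problem(data, tg, l_max)
    entry <- path_entries_target(pr, lambda_grid, penalty = NULL,
                                 monotone = monotone)
    tibble::tibble(source = gn, target = tg, entry_lambda = entry)
  })
  if (!include_self) {
    entries <- dplyr::filter(entries, .data$source != .data$target)
  }
  structure(
    list(entries = entries, lambdas = lambda_grid, l_max = l_max,
         method = if (monotone) "ordered_lasso" else "lasso_granger",
         include_self = include_self, gene_names = gn),
    class = "lagged_path"
  )
}

#' @export
print.lagged_path <- function(x, ...) {
  cat("<lagged_path> ", x$method, ", ", length(x$gene_names), " genes, ",
      "l_max = ", x$l_max, ", ", length(x$lambdas), " lambdas\n",
      "  ", sum(!is.na(x$entries$entry_lambda)), " of ",
      nrow(x$entries), " candidate edges enter the path\n", sep = "")
  invisible(x)
}

# ---- internals -------------------------------------------------------------

edge_active <- function(w, monotone) {
  if (monotone) {
    abs(w[, 1L]) > ACTIVE_TOL        # first lag dominates under the constraint
  } else {
    apply(abs(w) > ACTIVE_TOL, 1L, any)
  }
}

check_lambda_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L) {
    stop("`lambda_grid` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(grid <= 0) || any(diff(grid) >= 0)) {
    stop("`lambda_grid` must be positive and strictly decreasing",
         call. = FALSE)
  }
  invisible(grid)
}

# entry lambda per source gene for one target: largest grid value at which
# the source's block is active; NA when it never activates
path_entries_target <- function(problem, grid, penalty, monotone) {
  p <- length(problem$gene_names)
  entry <- rep(NA_real_, p)
  fit <- NULL
  for (lam in grid) {
    fit <- ordered_lasso(problem$x, problem$y, lam, problem$l_max,
                         penalty = penalty, monotone = monotone, init = fit)
    act <- edge_active(fit$w, monotone)
    newly <- act & is.na(entry)
    entry[newly] <- lam
  }
  entry
}
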