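#' Pairwise Granger causality
#'
#' For every ordered cross-gene pair (x -> y), compares two autoregressions
#' of the target: a restricted model on the target's own `l_max` lags and a
#' full model that adds the candidate driver's `l_max` lags (both with an
#' intercept). The explanatory gain is assessed with an F test,
#' `F = ((RSS_r - RSS_f)/l_max) / (RSS_f/df_f)`, and p-values are adjusted
#' across pairs with Benjamini-Hochberg. With multiple replicate series the
#' lag windows are built per series and the residual sums of squares pooled,
#' with the residual degrees of freedom adjusted accordingly.
#'
#' Short series are the method's known failure mode: the full model must
#' retain positive residual degrees of freedom, otherwise an error is
#' raised.
#'
#' @inheritParams build_lagged_problem
#' @return A `granger_result`: tibble with columns `source`, `target`,
#'   `statistic`, `p_value`, `p_adjusted`, plus `l_max` and residual df in
#'   attributes.
#' @seealso [granger_network()] to threshold the adjusted p-values.
#' @export
pairwise_granger <- function(data, l_max) {
  data <- as_expr_ts(data)
  gn <- genes(data)
  l_max <- as.integer(l_max)
  mats <- ets_matrices(data)
  n_rows <- sum(vapply(mats, function(m) max(0L, ncol(m) - l_max), 0L))
  df_full <- n_rows - 2L * l_max - 1L
  if (df_full <= 0) {
    stop("series too short for pairwise Granger at l_max = ", l_max,
         ": the full model has ", df_full,
         " residual degrees of freedom", call. = FALSE)
  }
  pairs <- expand.grid(source = gn, target = gn,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  res <- purrr::pmap_dfr(pairs, function(source, target) {
    rows <- lapply(mats, function(m) {
      tt <- ncol(m)
      idx <- (l_max + 1L):tt
      own <- vapply(seq_len(l_max), function(k) m[target, idx - k],
                    numeric(length(idx)))
      drv <- vapply(seq_len(l_max), function(k) m[source, idx - k],
                    numeric(length(idx)))
      list(y = m[target, idx],
           own = matrix(own, ncol = l_max),
           drv = matrix(drv, ncol = l_max))
    })
    y <- unlist(lapply(rows, `[[`, "y"), use.names = FALSE)
    own <- do.call(rbind, lapply(rows, `[[`, "own"))
    drv <- do.call(rbind, lapply(rows, `[[`, "drv"))
    rss_r <- ols_rss(cbind(1, own), y)
    rss_f <- ols_rss(cbind(1, own, drv), y)
    f_stat <- ((rss_r - rss_f) / l_max) / (rss_f / df_full)
    if (!is.finite(f_stat) || f_stat < 0) f_stat <- max(0, f_stat, na.rm = TRUE)
    p <- if (rss_f <= .Machine$double.eps * max(1, rss_r)) {
      0 # perfect full-model fit: infinite evidence for the driver
    } else {
      stats::pf(f_stat, l_max, df_full, lower.tail = FALSE)
    }
    tibble::tibble(source = source, target = target,
                   statistic = f_stat, p_value = p)
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- dplyr::arrange(res, match(.data$target, gn),
                        match(.data$source, gn))
  structure(res, l_max = l_max, df_full = df_full,
            gene_names = gn,
            class = c("granger_result", class(res)))
}

#' Threshold a Granger result into a network
#'
#' @param result A `granger_result` from [pairwise_granger()].
#' @param alpha FDR level applied to the Benjamini-Hochberg adjusted
#'   p-values.
#' @return Tibble of edges `source`, `target` with adjusted p below
#'   `alpha`.
#' @export
granger_network <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "granger_result"))
  dplyr::select(dplyr::filter(tibble::as_tibble(result),
                              .data$p_adjusted <= alpha),
                "source", "target")
}

#' Lasso-Granger network inference
#'
#' The de novo pipeline with the monotone lag constraint removed: an
#' ordinary lasso over all lagged predictors, predicting an edge when any
#' lag coefficient of the source is non-zero (all lags must be checked —
#' without the constraint the first lag carries no special status). At
#' `l_max = 1` the constraint is vacuous and Lasso-Granger coincides with
#' the time-lagged Ordered Lasso.
#'
#' @inheritParams infer_network_denovo
#' @return Tibble of predicted edges, as [infer_network_denovo()].
#' @export
lasso_granger <- function(data, l_max, lambda, include_self = FALSE) {
  infer_network_denovo(data, l_max, lambda, include_self = include_self,
                       monotone = FALSE)
}

#' @rdname lasso_granger
#' @inheritParams edge_entry_path
#' @return `lasso_granger_path()`: a `lagged_path` of entry values.
#' @export
lasso_granger_path <- function(data, l_max, lambda_grid = NULL,
                               n_lambda = 100, lambda_min_ratio = 1e-4,
                               include_self = FALSE) {
  edge_entry_path(data, l_max, lambda_grid = lambda_grid,
                  n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                  monotone = FALSE, include_self = include_self)
}

# residual sum of squares of an OLS fit (QR; rank-deficiency tolerated)
ols_rss <- function(x, y) {
  fit <- stats::lm.fit(x, y)
  sum(fit$residuals^2)
}
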