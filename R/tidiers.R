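#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ordered-lasso fit
#'
#' @param x An `ordered_lasso_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (predictor, lag): columns `predictor`,
#'   `lag`, `estimate`, `active`.
#' @method tidy ordered_lasso_fit
#' @export
tidy.ordered_lasso_fit <- function(x, ...) {
  out <- tibble::tibble(
    predictor = rep(rownames(x$w), each = ncol(x$w)),
    lag = rep(seq_len(ncol(x$w)), nrow(x$w)),
    estimate = as.numeric(t(x$w))
  )
  out$active <- abs(out$estimate) > ACTIVE_TOL
  out
}

#' @rdname tidy.ordered_lasso_fit
#' @method glance ordered_lasso_fit
#' @export
glance.ordered_lasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    l_max = x$l_max,
    monotone = x$monotone,
    n_active = sum(rowSums(abs(x$w) > ACTIVE_TOL) > 0),
    objective = x$objective,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Tidy a penalty path
#'
#' @param x A `lagged_path`.
#' @param ... Unused.
#' @return The entry tibble (`source`, `target`, `entry_lambda`), sorted by
#'   decreasing entry value.
#' @method tidy lagged_path
#' @export
tidy.lagged_path <- function(x, ...) {
  dplyr::arrange(x$entries, dplyr::desc(.data$entry_lambda))
}

#' @rdname tidy.lagged_path
#' @method glance lagged_path
#' @export
glance.lagged_path <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_genes = length(x$gene_names),
    l_max = x$l_max,
    n_lambda = length(x$lambdas),
    lambda_max = max(x$lambdas),
    lambda_min = min(x$lambdas),
    n_candidates = nrow(x$entries),
    n_entered = sum(!is.na(x$entries$entry_lambda))
  )
}

#' Tidy a Granger-causality result
#'
#' @param x A `granger_result`.
#' @param ... Unused.
#' @return The underlying tibble of per-pair statistics.
#' @method tidy granger_result
#' @export
tidy.granger_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.granger_result
#' @method glance granger_result
#' @export
glance.granger_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    l_max = attr(x, "l_max"),
    df_full = attr(x, "df_full"),
    n_significant_05 = sum(x$p_adjusted <= 0.05)
  )
}

#' Tidy an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The step-curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_true = x$n_true, n_false = x$n_false)
}

#' Tidy a semi-supervised fit
#'
#' @param x A `semisup_fit`.
#' @param ... Unused.
#' @return Tibble of per (source, target, lag) coefficients with prior
#'   membership and the novel/anomalous call.
#' @method tidy semisup_fit
#' @export
tidy.semisup_fit <- function(x, ...) {
  prior_key <- paste(x$prior$source, x$prior$target)
  novel_key <- paste(x$novel_edges$source, x$novel_edges$target)
  anom_key <- paste(x$anomalous_edges$source, x$anomalous_edges$target)
  purrr::imap_dfr(x$fits, function(fit, tg) {
    co <- tidy(fit)
    key <- paste(co$predictor, tg)
    tibble::tibble(
      source = co$predictor, target = tg, lag = co$lag,
      estimate = co$estimate,
      in_prior = key %in% prior_key,
      call = dplyr::case_when(
        key %in% novel_key ~ "novel",
        key %in% anom_key ~ "anomalous",
        TRUE ~ "none"
      )
    )
  })
}

#' @rdname tidy.semisup_fit
#' @method glance semisup_fit
#' @export
glance.semisup_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_names),
    l_max = x$l_max,
    lambda_edge = x$lambda_edge,
    lambda_non_edge = x$lambda_non_edge,
    n_prior = nrow(x$prior),
    n_novel = nrow(x$novel_edges),
    n_anomalous = nrow(x$anomalous_edges)
  )
}
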