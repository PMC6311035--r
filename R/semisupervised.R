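#' Semi-supervised network inference with a prior network
#'
#' Fits, for every target gene, the time-lagged Ordered Lasso with two
#' penalty levels: `lambda_edge` for predictors that are sources of a prior
#' edge onto the target, and `lambda_non_edge` for all other predictors.
#' With `lambda_edge < lambda_non_edge` the prior edges are penalised less,
#' letting them absorb most of the explainable variance, while non-prior
#' pairs must earn their way into the model. A *novel* edge is a non-prior
#' pair with any non-zero lagged coefficient; an *anomalous* edge is a prior
#' pair whose coefficients are all zero (only meaningful when
#' `lambda_edge > 0`). With equal penalties the fit reduces exactly to the
#' de novo model.
#'
#' @inheritParams infer_network_denovo
#' @param prior Prior network: data frame with columns `source`, `target`
#'   (self-pairs allowed); every gene must exist in `data`.
#' @param lambda_edge,lambda_non_edge Non-negative penalty levels for prior
#'   edges and non-edges.
#' @return A `semisup_fit`: per-target coefficient matrices, `novel_edges`
#'   and `anomalous_edges` tibbles, and the penalties used.
#' @export
fit_semisupervised <- function(data, prior, l_max,
                               lambda_edge, lambda_non_edge,
                               include_self = FALSE) {
  data <- as_expr_ts(data)
  gn <- genes(data)
  prior <- check_prior(prior, gn)
  stopifnot(lambda_edge >= 0, lambda_non_edge >= 0)
  if (lambda_edge > lambda_non_edge) {
    warning("lambda_edge > lambda_non_edge: prior edges are penalised more ",
            "heavily than non-edges")
  }
  fits <- purrr::map(gn, function(tg) {
    pr <- build_lagged_problem(data, tg, l_max)
    prior_src <- prior$source[prior$target == tg]
    # solver penalty = lambda * multiplier; carry both levels through
    # multipliers at lambda = 1
    mult <- ifelse(gn %in% prior_src, lambda_edge, lambda_non_edge)
    ordered_lasso(pr$x, pr$y, lambda = 1, l_max = l_max, penalty = mult)
  })
  names(fits) <- gn
  edges_all <- purrr::map_dfr(gn, function(tg) {
    act <- edge_active(fits[[tg]]$w, monotone = TRUE)
    tibble::tibble(source = gn, target = tg, active = act)
  })
  edges_all$in_prior <- paste(edges_all$source, edges_all$target) %in%
    paste(prior$source, prior$target)
  if (!include_self) {
    edges_all <- dplyr::filter(edges_all,
                               .data$source != .data$target | .data$in_prior)
  }
  novel <- dplyr::select(
    dplyr::filter(edges_all, .data$active & !.data$in_prior),
    "source", "target")
  anomalous <- dplyr::select(
    dplyr::filter(edges_all, !.data$active & .data$in_prior),
    "source", "target")
  structure(
    list(fits = fits, novel_edges = novel, anomalous_edges = anomalous,
         prior = prior, lambda_edge = lambda_edge,
         lambda_non_edge = lambda_non_edge, l_max = l_max,
         gene_names = gn),
    class = "semisup_fit"
  )
}

#' @export
print.semisup_fit <- function(x, ...) {
  cat("<semisup_fit> ", length(x$gene_names), " genes, l_max = ", x$l_max,
      ", lambda_edge = ", format(x$lambda_edge, digits = 4),
      ", lambda_non_edge = ", format(x$lambda_non_edge, digits = 4), "\n",
      "  novel edges: ", nrow(x$novel_edges),
      ", anomalous edges: ", nrow(x$anomalous_edges), "\n", sep = "")
  invisible(x)
}

#' Entry path of prior non-edges as the non-edge penalty decreases
#'
#' Holds `lambda_edge` fixed (0 by default, leaving prior edges
#' unpenalised) and sweeps `lambda_non_edge` down a decreasing grid,
#' recording for every prior non-edge the largest penalty at which it
#' becomes active — the same enter-at-that-value-or-larger merging used by
#' the de novo path, restricted to candidate novel edges. Ranking these
#' entry values against held-out true edges gives the novel-edge ROC.
#'
#' @inheritParams fit_semisupervised
#' @param lambda_grid Strictly decreasing positive grid for
#'   `lambda_non_edge`; computed (and verified to start with no active prior
#'   non-edge) when `NULL`.
#' @param n_lambda,lambda_min_ratio Grid parameters when `lambda_grid` is
#'   `NULL`.
#' @return A `lagged_path` whose entries cover only pairs outside the
#'   prior, with `prior` and `lambda_edge` fields attached.
#' @export
novel_edge_path <- function(data, prior, l_max, lambda_edge = 0,
                            lambda_grid = NULL, n_lambda = 100,
                            lambda_min_ratio = 1e-4,
                            include_self = FALSE) {
  data <- as_expr_ts(data)
  gn <- genes(data)
  prior <- check_prior(prior, gn)
  if (is.null(lambda_grid)) {
    top <- max(network_lambda_grid(data, l_max, n_lambda = 2,
                                   lambda_min_ratio = 0.5))
    # make sure no prior non-edge is active at the top of the grid
    for (i in 1:20) {
      fit <- fit_semisupervised(data, prior, l_max, lambda_edge, top,
                                include_self = include_self)
      if (nrow(fit$novel_edges) == 0) break
      top <- top * 2
    }
    lambda_grid <- exp(seq(log(top), log(top * lambda_min_ratio),
                           length.out = n_lambda))
  }
  check_lambda_grid(lambda_grid)
  prior_key <- paste(prior$source, prior$target)
  entries <- purrr::map_dfr(gn, function(tg) {
    pr <- build_lagged_problem(data, tg, l_max)
    prior_src <- prior$source[prior$target == tg]
    entry <- rep(NA_real_, length(gn))
    fit <- NULL
    for (lam in lambda_grid) {
      mult <- ifelse(gn %in% prior_src, lambda_edge / lam, 1)
      fit <- ordered_lasso(pr$x, pr$y, lambda = lam, l_max = l_max,
                           penalty = mult, init = fit)
      act <- edge_active(fit$w, monotone = TRUE)
      entry[act & is.na(entry)] <- lam
    }
    tibble::tibble(source = gn, target = tg, entry_lambda = entry)
  })
  entries <- dplyr::filter(entries,
                           !paste(.data$source, .data$target) %in% prior_key)
  if (!include_self) {
    entries <- dplyr::filter(entries, .data$source != .data$target)
  }
  structure(
    list(entries = entries, lambdas = lambda_grid, l_max = l_max,
         method = "semisupervised", include_self = include_self,
         gene_names = gn, prior = prior, lambda_edge = lambda_edge),
    class = "lagged_path"
  )
}

# ---- internals -------------------------------------------------------------

check_prior <- function(prior, gene_names) {
  prior <- tibble::as_tibble(prior)
  if (!all(c("source", "target") %in% names(prior))) {
    stop("prior network needs `source` and `target` columns", call. = FALSE)
  }
  prior <- dplyr::distinct(prior[c("source", "target")])
  prior$source <- as.character(prior$source)
  prior$target <- as.character(prior$target)
  unknown <- setdiff(unique(c(prior$source, prior$target)), gene_names)
  if (length(unknown)) {
    stop("prior network names genes absent from the dataset: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  prior
}
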