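#' ROC and AUC for ranked directed edges
#'
#' Scores a candidate set of directed gene pairs against a truth network.
#' Candidates are ranked by a score (larger = stronger): for a penalty path
#' the score is the entry penalty — an edge entering at a larger penalty is
#' predicted earlier, and thresholding at any penalty yields the merged,
#' nested predicted sets — and for a Granger result it is `1 - p`.
#' Candidates that never enter share a single bottom rank. The AUC is the
#' Mann-Whitney probability that a randomly chosen true edge outranks a
#' randomly chosen non-edge, with ties counted half.
#'
#' @param x Ranked edges: a `lagged_path`, a `granger_result`, or a data
#'   frame with columns `source`, `target`, `score`.
#' @param truth Truth network: data frame with columns `source`, `target`;
#'   must be a non-empty proper subset of the candidate pairs.
#' @param ... Passed between methods.
#' @return A `roc_result`: `auc`, the step-curve tibble
#'   (`threshold`, `fpr`, `tpr`), candidate counts, and the candidate-set
#'   convention.
#' @export
roc_edges <- function(x, truth, ...) UseMethod("roc_edges")

#' @rdname roc_edges
#' @export
roc_edges.lagged_path <- function(x, truth, ...) {
  scored <- x$entries
  scored$score <- scored$entry_lambda
  roc_scored(scored, truth, include_self = x$include_self)
}

#' @rdname roc_edges
#' @export
roc_edges.granger_result <- function(x, truth, ...) {
  scored <- tibble::as_tibble(x)
  scored$score <- 1 - scored$p_value
  roc_scored(scored, truth, include_self = FALSE)
}

#' @rdname roc_edges
#' @export
roc_edges.data.frame <- function(x, truth, ...) {
  stopifnot(all(c("source", "target", "score") %in% names(x)))
  roc_scored(tibble::as_tibble(x), truth, include_self = NA)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4), " (",
      x$n_true, " true edges, ", x$n_false, " non-edges)\n", sep = "")
  invisible(x)
}

#' Precision, recall and F1 of a predicted network
#'
#' Compares predicted and truth edge sets over the same gene universe.
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 is their
#' harmonic mean. Degenerate cases are returned, not raised: with no
#' predicted edges precision is reported as 1 and flagged; with an empty
#' truth recall is flagged likewise; F1 is 0 when precision and recall are
#' both 0.
#'
#' @param predicted,truth Data frames with columns `source`, `target`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @examples
#' precision_recall_f1(
#'   tibble::tibble(source = c("a", "b", "c", "d"),
#'                  target = c("b", "c", "d", "a")),
#'   tibble::tibble(source = c("a", "b", "c", "x", "y", "z"),
#'                  target = c("b", "c", "d", "y", "z", "x")))
#' @export
precision_recall_f1 <- function(predicted, truth) {
  pk <- paste(predicted$source, predicted$target)
  tk <- paste(truth$source, truth$target)
  pk <- unique(pk)
  tk <- unique(tk)
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  degenerate <- length(pk) == 0 || length(tk) == 0
  precision <- if (length(pk) == 0) 1 else tp / (tp + fp)
  recall <- if (length(tk) == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate)
}

# ---- internals -------------------------------------------------------------

# AUC + step curve from a scored candidate tibble; NA scores share the
# bottom rank. Ties get half credit via midranks.
roc_scored <- function(scored, truth, include_self) {
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("source", "target") %in% names(truth)))
  ckey <- paste(scored$source, scored$target)
  if (anyDuplicated(ckey)) {
    stop("duplicate candidate pairs in the ranking", call. = FALSE)
  }
  tkey <- unique(paste(truth$source, truth$target))
  if (!all(tkey %in% ckey)) {
    stop("truth contains pairs outside the candidate set: ",
         paste(utils::head(setdiff(tkey, ckey), 5), collapse = ", "),
         call. = FALSE)
  }
  is_true <- ckey %in% tkey
  n_true <- sum(is_true)
  n_false <- sum(!is_true)
  if (n_true == 0 || n_false == 0) {
    stop("AUC undefined: truth must be a non-empty proper subset of the ",
         "candidate pairs (", n_true, " true, ", n_false, " non-edges)",
         call. = FALSE)
  }
  score <- scored$score
  score[is.na(score)] <- -Inf
  rk <- rank(score, ties.method = "average")
  auc <- (sum(rk[is_true]) - n_true * (n_true + 1) / 2) / (n_true * n_false)

  thresholds <- sort(unique(score), decreasing = TRUE)
  curve <- purrr::map_dfr(thresholds, function(th) {
    pred <- score >= th
    tibble::tibble(threshold = th,
                   fpr = sum(pred & !is_true) / n_false,
                   tpr = sum(pred & is_true) / n_true)
  })
  curve <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, fpr = 0, tpr = 0), curve)
  structure(
    list(auc = auc, curve = curve, n_true = n_true, n_false = n_false,
         include_self = include_self),
    class = "roc_result"
  )
}
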