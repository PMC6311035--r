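#' Time-course expression data in long (tidy) form
#'
#' The canonical input across lagnet is a long tibble with one row per
#' (series, time point, gene) observation and columns `series`, `time`,
#' `gene`, `expression`. Sampling must be uniform within a series; the
#' interval `dt` is stored as an attribute and inferred from the `time`
#' column when not supplied. Gene order (the order used for design-matrix
#' blocks and edge indices) is the order of first appearance, kept in the
#' `gene_names` attribute.
#'
#' @param data A data frame with columns `series`, `time`, `gene`,
#'   `expression` (extra columns are dropped). `series` may be omitted when
#'   there is a single series.
#' @param dt Sampling interval; inferred from `time` when `NULL`.
#' @param gene_names Optional explicit gene ordering.
#' @return A tibble of class `expr_ts` with attributes `dt` and
#'   `gene_names` (and, for simulated data, `truth`).
#' @export
expr_ts <- function(data, dt = NULL, gene_names = NULL) {
  data <- tibble::as_tibble(data)
  if (!"series" %in% names(data)) data$series <- 1L
  req <- c("series", "time", "gene", "expression")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[req]
  data$gene <- as.character(data$gene)
  data$series <- as.character(data$series)
  if (!all(is.finite(data$expression))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (is.null(gene_names)) gene_names <- unique(data$gene)
  if (!setequal(gene_names, unique(data$gene))) {
    stop("`gene_names` must match the genes present in `data`", call. = FALSE)
  }
  # every series must contain every gene at every one of its time points
  counts <- dplyr::count(data, .data$series, .data$time)
  if (any(counts$n != length(gene_names))) {
    stop("each (series, time) must have exactly one value per gene",
         call. = FALSE)
  }
  dts <- unlist(lapply(split(unique(data[c("series", "time")])$time,
                             unique(data[c("series", "time")])$series),
                       function(tt) diff(sort(tt))))
  if (is.null(dt)) {
    if (!length(dts)) stop("cannot infer `dt` from a single time point",
                           call. = FALSE)
    dt <- stats::median(dts)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (length(dts) && any(abs(dts - dt) > 1e-6 * dt)) {
    stop("sampling must be uniform with interval `dt` within each series",
         call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$series, .data$time,
                         match(.data$gene, gene_names))
  structure(data,
            dt = dt,
            gene_names = gene_names,
            class = c("expr_ts", class(tibble::tibble())))
}

#' @rdname expr_ts
#' @param x Object to convert: a long data frame, or a list of
#'   genes-by-time matrices (one per series, shared rownames).
#' @param ... Passed on to methods.
#' @export
as_expr_ts <- function(x, ...) UseMethod("as_expr_ts")

#' @export
as_expr_ts.expr_ts <- function(x, ...) x

#' @export
as_expr_ts.data.frame <- function(x, dt = NULL, ...) expr_ts(x, dt = dt)

#' @rdname expr_ts
#' @export
as_expr_ts.list <- function(x, dt, gene_names = NULL, ...) {
  stopifnot(length(x) >= 1L)
  if (is.null(gene_names)) gene_names <- rownames(x[[1]])
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(nrow(x[[1]])))
  long <- purrr::imap_dfr(x, function(m, s) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == length(gene_names))
    tibble::tibble(
      series = as.character(s),
      time = rep((seq_len(ncol(m)) - 1L) * dt, each = nrow(m)),
      gene = rep(gene_names, ncol(m)),
      expression = as.numeric(m)
    )
  })
  expr_ts(long, dt = dt, gene_names = gene_names)
}

#' @export
print.expr_ts <- function(x, ...) {
  cat("<expr_ts> ", length(attr(x, "gene_names")), " genes, ",
      length(unique(x$series)), " series, dt = ",
      format(attr(x, "dt"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Gene names of an expression dataset
#' @param data An `expr_ts`.
#' @return Character vector in block order.
#' @export
genes <- function(data) attr(as_expr_ts(data), "gene_names")

#' Ground-truth network attached to a simulated dataset
#' @param data An `expr_ts` produced by a simulator.
#' @return A tibble with columns `source`, `target`, or `NULL`.
#' @export
truth_network <- function(data) attr(data, "truth")

# internal: list of genes x time matrices, one per series, in gene order
ets_matrices <- function(data) {
  data <- as_expr_ts(data)
  gn <- attr(data, "gene_names")
  lapply(split(data, data$series), function(d) {
    d <- dplyr::arrange(d, .data$time, match(.data$gene, gn))
    tt <- sort(unique(d$time))
    m <- matrix(d$expression, nrow = length(gn), ncol = length(tt),
                dimnames = list(gn, NULL))
    m
  })
}
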