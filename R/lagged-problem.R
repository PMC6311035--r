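#' Build the per-target lagged regression problem
#'
#' Assembles the design matrix for one target gene: the response is the
#' target's expression at each usable time point and the predictors are the
#' lagged expression values of every gene (the target itself included) at
#' lags `1..l_max` sampling intervals. Each gene contributes `l_max`
#' consecutive columns ordered by increasing lag. Rows from different
#' replicate series are stacked; no row ever mixes observations from two
#' series.
#'
#' @param data An [expr_ts] dataset (or coercible data frame).
#' @param target Gene name (or index in `genes(data)`).
#' @param l_max Maximum lag, in sampling intervals; every series must have at
#'   least `l_max + 1` time points.
#' @return A `lagged_problem`: list with design matrix `x`
#'   (`p * l_max` columns, names `gene.lagk`), response `y`, `target`,
#'   `gene_names`, `l_max`, `dt`, and `series_rows` (rows contributed per
#'   series).
#' @export
build_lagged_problem <- function(data, target, l_max) {
  data <- as_expr_ts(data)
  gn <- attr(data, "gene_names")
  if (is.numeric(target)) target <- gn[target]
  if (!target %in% gn) stop("unknown target gene: ", target, call. = FALSE)
  l_max <- as.integer(l_max)
  stopifnot(l_max >= 1L)
  mats <- ets_matrices(data)
  short <- names(mats)[vapply(mats, ncol, 0L) < l_max + 1L]
  if (length(short)) {
    stop("l_max = ", l_max, " needs at least ", l_max + 1,
         " time points, but series ", paste(short, collapse = ", "),
         " is too short", call. = FALSE)
  }
  p <- length(gn)
  blocks <- lapply(mats, function(m) {
    tt <- ncol(m)
    rows <- (l_max + 1L):tt
    x <- matrix(0, length(rows), p * l_max)
    for (j in seq_len(p)) {
      for (k in seq_len(l_max)) {
        x[, (j - 1L) * l_max + k] <- m[j, rows - k]
      }
    }
    list(x = x, y = m[target, rows])
  })
  x <- do.call(rbind, lapply(blocks, `[[`, "x"))
  y <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  colnames(x) <- paste0(rep(gn, each = l_max), ".lag",
                        rep(seq_len(l_max), p))
  structure(
    list(x = x, y = y, target = target, gene_names = gn, l_max = l_max,
         dt = attr(data, "dt"),
         series_rows = vapply(blocks, function(b) length(b$y), 0L)),
    class = "lagged_problem"
  )
}

#' @export
print.lagged_problem <- function(x, ...) {
  cat("<lagged_problem> target ", x$target, ": ", nrow(x$x), " rows, ",
      length(x$gene_names), " genes x ", x$l_max, " lags\n", sep = "")
  invisible(x)
}
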