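#' Read time-course expression matrices
#'
#' Reads one delimited file per replicate series: genes as rows, the first
#' column holding gene identifiers and the remaining columns one time point
#' each (header row = time indices, which are ignored beyond ordering —
#' sampling is taken to be uniform at `dt`). All series must share the same
#' gene set; gene order is taken from the first file.
#'
#' @param paths Character vector of TSV/CSV paths, one per series.
#' @param dt Sampling interval shared by all series.
#' @param delim Field delimiter (default tab).
#' @return An [expr_ts].
#' @export
read_expression <- function(paths, dt, delim = "\t") {
  stopifnot(length(paths) >= 1L, dt > 0)
  mats <- lapply(paths, function(pth) {
    df <- readr::read_delim(pth, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
  })
  gn <- rownames(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    if (!setequal(rownames(mats[[i]]), gn)) {
      stop("series file ", paths[i], " has a different gene set",
           call. = FALSE)
    }
    mats[[i]] <- mats[[i]][gn, , drop = FALSE]
  }
  names(mats) <- as.character(seq_along(mats))
  as_expr_ts(mats, dt = dt, gene_names = gn)
}

#' Write time-course expression matrices
#'
#' Inverse of [read_expression()]: one TSV per series, genes as rows, first
#' column `gene`, remaining columns `t0, t1, ...`.
#'
#' @param data An [expr_ts].
#' @param paths Output paths, one per series.
#' @param delim Field delimiter.
#' @return `paths`, invisibly.
#' @export
write_expression <- function(data, paths, delim = "\t") {
  mats <- ets_matrices(as_expr_ts(data))
  stopifnot(length(paths) == length(mats))
  purrr::walk2(mats, paths, function(m, pth) {
    df <- tibble::as_tibble(m, .name_repair = ~ paste0("t", seq_along(.x) - 1))
    df <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)), df)
    readr::write_delim(df, pth, delim = delim)
  })
  invisible(paths)
}

#' Read / write directed edge lists
#'
#' Edge lists are headerless tab-separated files: column 1 = source gene,
#' column 2 = target gene, optional column 3 = entry penalty.
#'
#' @param path File path.
#' @return `read_edge_list()`: tibble with columns `source`, `target` and,
#'   when present in the file, `entry_lambda`.
#' @export
read_edge_list <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(tibble::tibble(source = character(), target = character()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("source", "target", "entry_lambda")[
                            seq_len(max(utils::count.fields(path, sep = "\t")))])
  out <- tibble::as_tibble(df)
  if ("entry_lambda" %in% names(out)) {
    out$entry_lambda <- as.numeric(out$entry_lambda)
  }
  out
}

#' @rdname read_edge_list
#' @param edges Data frame with columns `source`, `target`, optionally
#'   `entry_lambda`.
#' @export
write_edge_list <- function(edges, path) {
  keep <- intersect(c("source", "target", "entry_lambda"), names(edges))
  df <- as.data.frame(edges)[, keep, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
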