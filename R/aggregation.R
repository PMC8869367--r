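#' Competition ranks of a stability metric
#'
#' Ranks genes by a stability metric, ascending (lower metric = more stable =
#' better rank). Exact ties share the minimum rank and the following rank is
#' skipped accordingly ("1, 1, 3"), matching how per-algorithm positions are
#' conventionally printed. Ranking operates on unrounded values.
#'
#' @param metric Named numeric vector of non-negative, finite stability
#'   values.
#' @return Named integer vector of ranks.
#' @export
rank_genes <- function(metric) {
  if (length(metric) == 0L) abort_rgstab("empty metric map", "EMPTY")
  if (any(!is.finite(metric))) abort_rgstab("metrics must be finite", "BAD_METRIC")
  stats::setNames(as.integer(rank(metric, ties.method = "min")), names(metric))
}

#' Comprehensive ranking as the geometric mean of per-algorithm ranks
#'
#' Combines the rankings of several stability algorithms into one
#' comprehensive order: each gene's score is the geometric mean of its ranks
#' across algorithms, and genes are sorted by that score ascending. Ties in
#' the geometric mean are broken by the arithmetic mean rank, then by input
#' gene order. The geometric mean is conventionally displayed rounded to two
#' decimals; the full-precision value is kept in the result.
#'
#' @param tables A list of `rg_stability` objects (see [genorm()] and
#'   friends), all covering the same gene set. A named list names the
#'   per-algorithm rank columns.
#' @return An object of class `rg_ranking`: a tibble with `final_rank`,
#'   `gene_id`, `geomean` and one `rank_<algorithm>` column per input table,
#'   with attribute `algorithm_order`.
#' @export
aggregate_rankings <- function(tables) {
  if (length(tables) == 0L) abort_rgstab("need >= 1 stability table", "EMPTY")
  if (inherits(tables, "rg_stability")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "rg_stability")))
  algs <- names(tables) %||% vapply(tables, `[[`, "", "algorithm")
  if (is.null(names(tables))) algs <- make.unique(algs, sep = "_")

  genes <- tables[[1L]]$table$gene_id
  for (tb in tables[-1L]) {
    if (!setequal(tb$table$gene_id, genes)) {
      diff <- c(setdiff(genes, tb$table$gene_id),
                setdiff(tb$table$gene_id, genes))
      abort_rgstab(paste0("gene sets differ between stability tables: ",
                          paste(diff, collapse = ", ")), "GENE_MISMATCH")
    }
  }
  ranks <- vapply(tables, function(tb) {
    stats::setNames(tb$table$rank, tb$table$gene_id)[genes]
  }, numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes),
                  dimnames = list(genes, algs))
  aggregate_rank_matrix(ranks)
}

#' @rdname aggregate_rankings
#' @param ranks A numeric matrix of per-algorithm ranks (genes in rows,
#'   algorithms in columns, gene rownames required), for aggregating
#'   rankings obtained outside the package (e.g. printed result tables).
#' @export
aggregate_rank_matrix <- function(ranks) {
  if (is.data.frame(ranks)) {
    rn <- ranks[[1L]]
    ranks <- as.matrix(ranks[, -1L, drop = FALSE])
    rownames(ranks) <- rn
  }
  if (is.null(rownames(ranks))) abort_rgstab("rank matrix needs gene rownames", "BAD_INPUT")
  if (any(!is.finite(ranks)) || any(ranks < 1)) {
    abort_rgstab("ranks must be finite and >= 1", "BAD_INPUT")
  }
  geomean <- exp(rowMeans(log(ranks)))
  amean <- rowMeans(ranks)
  ord <- order(geomean, amean, seq_len(nrow(ranks)))
  tbl <- tibble::tibble(gene_id = rownames(ranks), geomean = unname(geomean))
  for (j in seq_len(ncol(ranks))) {
    tbl[[paste0("rank_", colnames(ranks)[j])]] <- as.integer(ranks[, j])
  }
  tbl <- tbl[ord, ]
  tbl <- tibble::add_column(tbl, final_rank = seq_len(nrow(tbl)), .before = 1L)
  structure(tbl, algorithm_order = colnames(ranks),
            class = c("rg_ranking", class(tibble::tibble())))
}

#' Render a comprehensive ranking in the conventional report layout
#'
#' @param x An `rg_ranking`.
#' @param tables Optional named list of the `rg_stability` objects that fed
#'   the ranking; when given, per-algorithm columns show "metric (rank)".
#' @param digits Decimals for the displayed geometric mean (default 2).
#' @return A tibble: Ranking order, gene, geomean, and one column per
#'   algorithm.
#' @export
render_ranking <- function(x, tables = NULL, digits = 2) {
  out <- tibble::tibble(
    ranking_order = x$final_rank,
    gene_id = x$gene_id,
    geomean = round(x$geomean, digits)
  )
  if (!is.null(tables)) {
    for (nm in names(tables)) {
      tb <- tables[[nm]]$table
      m <- stats::setNames(tb$metric, tb$gene_id)[x$gene_id]
      r <- stats::setNames(tb$rank, tb$gene_id)[x$gene_id]
      out[[nm]] <- sprintf("%.3f (%d)", m, r)
    }
  } else {
    for (nm in attr(x, "algorithm_order")) {
      out[[nm]] <- x[[paste0("rank_", nm)]]
    }
  }
  out
}
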