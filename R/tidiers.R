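#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a stability result
#'
#' @param x An `rg_stability` object.
#' @param ... Unused.
#' @return A tibble with `algorithm`, `gene_id`, `metric`, `rank`, sorted by
#'   rank.
#' @export
tidy.rg_stability <- function(x, ...) {
  dplyr::arrange(
    tibble::add_column(x$table, algorithm = x$algorithm, .before = 1L),
    .data$rank
  )
}

#' @rdname tidy.rg_stability
#' @export
glance.rg_stability <- function(x, ...) {
  best <- x$table$gene_id[which.min(x$table$metric)]
  tibble::tibble(algorithm = x$algorithm, n_genes = x$n_genes,
                 n_samples = x$n_samples, best_gene = best,
                 best_metric = min(x$table$metric))
}

#' Tidy a comprehensive ranking
#'
#' @param x An `rg_ranking`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.rg_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.rg_ranking
#' @export
glance.rg_ranking <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_algorithms = length(attr(x, "algorithm_order")),
                 best_gene = x$gene_id[x$final_rank == 1L],
                 best_geomean = x$geomean[x$final_rank == 1L])
}

#' Tidy a full pipeline run
#'
#' @param x An `rg_pipeline`.
#' @param ... Unused.
#' @return Per-scope comprehensive rankings bound into one tibble with a
#'   `scope` column.
#' @export
tidy.rg_pipeline <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) {
    tibble::add_column(tibble::as_tibble(x[[nm]]$ranking), scope = nm,
                       .before = 1L)
  })
}

#' Tidy a sample PCA
#'
#' @param x An `rg_pca`.
#' @param ... Unused.
#' @return The coordinates tibble.
#' @export
tidy.rg_pca <- function(x, ...) x$coordinates

#' @rdname tidy.rg_pca
#' @export
glance.rg_pca <- function(x, ...) {
  tibble::tibble(n_axes = length(x$var_explained),
                 pc1_var = x$var_explained[1L],
                 pc12_var = sum(x$var_explained[seq_len(min(2L, length(x$var_explained)))]))
}
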