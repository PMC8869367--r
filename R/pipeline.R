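#' Run the full stability pipeline over one or more analysis scopes
#'
#' For each requested scope (by default every condition alone plus the merged
#' `"ALL"` analysis) the panel is preprocessed ([preprocess_panel()]), the
#' four stability algorithms are run, and their rankings are combined into a
#' comprehensive geometric-mean ranking ([aggregate_rankings()]). The result
#' mirrors the conventional three-panel stability report (one ranking table
#' per condition and one for all samples merged).
#'
#' @param x A raw [ct_matrix()].
#' @param scopes A named list of condition-label vectors; default one scope
#'   per condition plus `ALL` = all conditions. Scopes with fewer than 2
#'   samples are rejected.
#' @param normfinder_mode Passed to [normfinder()]; the default `"single"`
#'   treats each scope's samples as one group (including the merged scope).
#' @param bestkeeper_dispersion Passed to [bestkeeper()].
#' @param spike_equalize Passed to [preprocess_panel()].
#' @return An object of class `rg_pipeline`: a named list per scope, each
#'   with elements `matrix` (the cleaned panel), `stability` (named list of
#'   the four `rg_stability` objects), `ranking` (`rg_ranking`) and `report`
#'   (the rendered table). The presence table of the raw panel is attached as
#'   attribute `presence`.
#' @export
run_stability_pipeline <- function(x,
                                   scopes = NULL,
                                   normfinder_mode = "single",
                                   bestkeeper_dispersion = "mad",
                                   spike_equalize = TRUE) {
  conds <- unique(unname(ct_conditions(x)))
  if (is.null(scopes)) {
    scopes <- c(stats::setNames(as.list(conds), conds),
                if (length(conds) > 1L) list(ALL = conds))
  }
  presence <- call_presence(x)
  out <- lapply(names(scopes), function(nm) {
    clean <- preprocess_panel(x, scope = scopes[[nm]],
                              spike_equalize = spike_equalize)
    tabs <- list(
      genorm = genorm(clean),
      normfinder = normfinder(clean, mode = normfinder_mode),
      bestkeeper = bestkeeper(clean, dispersion = bestkeeper_dispersion),
      delta_ct = delta_ct_stability(clean)
    )
    ranking <- aggregate_rankings(tabs)
    list(matrix = clean, stability = tabs, ranking = ranking,
         report = render_ranking(ranking, tables = tabs))
  })
  names(out) <- names(scopes)
  structure(out, presence = presence, class = "rg_pipeline")
}

#' @export
print.rg_pipeline <- function(x, ...) {
  for (nm in names(x)) {
    cat("== Scope ", nm, " ==\n", sep = "")
    print(x[[nm]]$report)
  }
  invisible(x)
}

#' Principal component analysis of samples
#'
#' PCA of the samples in Ct space with genes as variables: gene rows are
#' centred, no unit-variance scaling is applied, and the centred matrix is
#' decomposed by SVD. Axis signs are arbitrary (as for any SVD).
#'
#' @param x A [ct_matrix()] with complete values, at least 2 genes and 2
#'   samples.
#' @return An object of class `rg_pca`: `coordinates` (tibble `sample_id`,
#'   `condition`, `PC1`, `PC2`, ...) and `var_explained` (fractions summing
#'   to 1 over all axes).
#' @export
pca_samples <- function(x) {
  vals <- ct_values(x)
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    abort_rgstab("PCA needs >= 2 genes and >= 2 samples", "TOO_FEW")
  }
  if (anyNA(vals)) abort_rgstab("complete values required; floor first", "MISSING_VALUES")
  centered <- vals - rowMeans(vals)
  if (all(abs(centered) < 1e-12)) {
    abort_rgstab("constant matrix: no variation to decompose", "DEGENERATE")
  }
  sv <- svd(centered)
  scores <- sv$v %*% diag(sv$d, nrow = length(sv$d))
  keep <- sv$d > max(sv$d) * 1e-10
  scores <- scores[, keep, drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  coords <- tibble::as_tibble(scores)
  coords <- tibble::add_column(coords,
                               sample_id = colnames(vals),
                               condition = unname(ct_conditions(x)[colnames(vals)]),
                               .before = 1L)
  structure(
    list(coordinates = coords,
         var_explained = sv$d[keep]^2 / sum(sv$d^2)),
    class = "rg_pca"
  )
}

#' @export
print.rg_pca <- function(x, ...) {
  cat("Sample PCA (genes centred, unscaled)\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  print(x$coordinates)
  invisible(x)
}

#' Correlation of mean expression between two panels
#'
#' Compares per-gene mean Ct between two datasets over the genes detected in
#' both, reporting the squared Pearson correlation, and classifies every gene
#' as detected in both panels, only in the first, or only in the second
#' (detection = present, per [call_presence()], in at least one condition of
#' that panel).
#'
#' @param a,b Two [ct_matrix()] panels.
#' @return A list of class `rg_crosscor`: `r_squared`, `n_shared`, `classes`
#'   (tibble `gene_id`, `class`), `means` (tibble of shared-gene mean Ct in
#'   both panels).
#' @export
cross_dataset_correlation <- function(a, b) {
  detected <- function(m) {
    pres <- call_presence(m)
    unique(pres$gene_id[pres$present])
  }
  det_a <- detected(a)
  det_b <- detected(b)
  shared <- intersect(det_a, det_b)
  if (length(shared) < 3L) {
    abort_rgstab("fewer than 3 genes detected in both panels", "TOO_FEW_SHARED")
  }
  mean_ct <- function(m, genes) {
    rowMeans(ct_values(m)[genes, , drop = FALSE], na.rm = TRUE)
  }
  ma <- mean_ct(a, shared)
  mb <- mean_ct(b, shared)
  classes <- tibble::tibble(
    gene_id = union(det_a, det_b),
    class = dplyr::case_when(
      union(det_a, det_b) %in% shared ~ "both",
      union(det_a, det_b) %in% det_a ~ "only_a",
      TRUE ~ "only_b"
    )
  )
  structure(
    list(r_squared = unname(stats::cor(ma, mb)^2),
         n_shared = length(shared),
         classes = classes,
         means = tibble::tibble(gene_id = shared, mean_ct_a = unname(ma),
                                mean_ct_b = unname(mb))),
    class = "rg_crosscor"
  )
}

#' @export
print.rg_crosscor <- function(x, ...) {
  cat(sprintf("Cross-dataset correlation: R^2 = %.3f over %d shared genes\n",
              x$r_squared, x$n_shared))
  print(table(x$classes$class))
  invisible(x)
}
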