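#' Pairwise variation between two genes
#'
#' The standard deviation (n−1 denominator) over samples of the Ct difference
#' between two genes. With amplification efficiency fixed at 2 (one cycle =
#' one log2 unit), the classical log-ratio variation between two candidate
#' reference genes reduces to exactly this quantity. It is symmetric in its
#' arguments and zero for a gene against itself or against any constant
#' offset of itself.
#'
#' @param x A preprocessed [ct_matrix()] (complete values).
#' @param gene_a,gene_b Gene ids.
#' @return Pairwise variation in cycles.
#' @export
pairwise_variation <- function(x, gene_a, gene_b) {
  vals <- ct_values(x)
  if (!all(c(gene_a, gene_b) %in% rownames(vals))) {
    abort_rgstab("gene not in panel", "BAD_GENE")
  }
  if (ncol(vals) < 2L) abort_rgstab("need >= 2 samples", "TOO_FEW_SAMPLES")
  stats::sd(vals[gene_a, ] - vals[gene_b, ])
}

# full symmetric matrix of pairwise variations
pairwise_variation_matrix <- function(vals) {
  k <- nrow(vals)
  V <- matrix(0, k, k, dimnames = list(rownames(vals), rownames(vals)))
  if (k < 2L) return(V)
  for (a in seq_len(k - 1L)) {
    for (b in seq(a + 1L, k)) {
      v <- stats::sd(vals[a, ] - vals[b, ])
      V[a, b] <- v
      V[b, a] <- v
    }
  }
  V
}

new_stability <- function(algorithm, metric, extras = list(), n_samples) {
  tbl <- tibble::tibble(
    gene_id = names(metric),
    metric = unname(metric),
    rank = unname(rank_genes(metric))
  )
  structure(
    list(algorithm = algorithm, table = tbl, extras = extras,
         n_genes = nrow(tbl), n_samples = n_samples),
    class = "rg_stability"
  )
}

#' @export
print.rg_stability <- function(x, ...) {
  cat(sprintf("Reference-gene stability (%s): %d genes, %d samples\n",
              x$algorithm, x$n_genes, x$n_samples))
  print(dplyr::arrange(x$table, .data$rank))
  invisible(x)
}

#' Stepwise-exclusion expression-stability measure (geNorm)
#'
#' For each gene the stability measure M is the mean pairwise variation
#' ([pairwise_variation()]) against all other candidates. The least stable
#' gene (highest M) is removed and M is recomputed among the survivors,
#' iterating until two genes remain; those two cannot be separated and share
#' the final-round M by construction. Each gene's reported metric is its M at
#' the round of its removal. Lower M means more stable.
#'
#' Ties at the exclusion step are broken by removing the gene occurring later
#' in input order, making the procedure deterministic.
#'
#' @param x A preprocessed [ct_matrix()] with at least 3 genes and 2 samples.
#' @return An object of class `rg_stability` with `algorithm = "genorm"` and
#'   extras `exclusion_order` (first removed first), `final_pair`, and the
#'   full `pairwise_variation` matrix. Use [tidy()] for the per-gene table.
#' @export
genorm <- function(x) {
  vals <- ct_values(x)
  if (nrow(vals) < 3L) abort_rgstab("stepwise exclusion needs >= 3 genes", "TOO_FEW_GENES")
  if (ncol(vals) < 2L) abort_rgstab("need >= 2 samples", "TOO_FEW_SAMPLES")
  if (anyNA(vals)) abort_rgstab("complete values required; floor first", "MISSING_VALUES")

  V <- pairwise_variation_matrix(vals)
  remaining <- rownames(vals)
  metric <- stats::setNames(rep(NA_real_, nrow(vals)), rownames(vals))
  exclusion <- character()
  while (length(remaining) > 2L) {
    M <- rowSums(V[remaining, remaining, drop = FALSE]) / (length(remaining) - 1L)
    worst <- utils::tail(which(M == max(M)), 1L)  # later input position on ties
    metric[remaining[worst]] <- M[worst]
    exclusion <- c(exclusion, remaining[worst])
    remaining <- remaining[-worst]
  }
  final_m <- V[remaining[1L], remaining[2L]]
  metric[remaining] <- final_m
  new_stability("genorm", metric,
                extras = list(exclusion_order = exclusion,
                              final_pair = remaining,
                              pairwise_variation = V),
                n_samples = ncol(vals))
}

#' Mean pairwise-variation stability (comparative delta-Ct method)
#'
#' Each gene's metric is the mean, over all other candidates, of the standard
#' deviation of the per-sample Ct differences — i.e. the initial (first-round)
#' value of the stepwise measure of [genorm()], without any exclusion. Lower
#' means more stable.
#'
#' @param x A preprocessed [ct_matrix()] with at least 2 genes and 2 samples.
#' @return An `rg_stability` object with `algorithm = "delta_ct"`.
#' @export
delta_ct_stability <- function(x) {
  vals <- ct_values(x)
  if (nrow(vals) < 2L) abort_rgstab("need >= 2 genes", "TOO_FEW_GENES")
  if (ncol(vals) < 2L) abort_rgstab("need >= 2 samples", "TOO_FEW_SAMPLES")
  if (anyNA(vals)) abort_rgstab("complete values required; floor first", "MISSING_VALUES")
  V <- pairwise_variation_matrix(vals)
  metric <- rowSums(V) / (nrow(vals) - 1L)
  new_stability("delta_ct", metric,
                extras = list(pairwise_variation = V),
                n_samples = ncol(vals))
}

# bias-corrected intragroup variances from raw two-way residual variances:
# s2_i = sigma2_i (1 - 2/k) + sum(sigma2)/k^2
andersen_variances <- function(vals) {
  k <- nrow(vals)
  n <- ncol(vals)
  centered <- vals - rowMeans(vals)
  centered <- sweep(centered, 2L, colMeans(centered), "-")
  s2 <- rowSums(centered^2) / (n - 1L)
  total <- sum(s2) / (1 - 1 / k)
  sigma2 <- (s2 - total / k^2) / (1 - 2 / k)
  list(raw = s2, sigma2 = pmax(sigma2, 0), clamped = sigma2 < 0)
}

#' Model-based stability value (NormFinder)
#'
#' Decomposes log-scale expression (Ct values) into gene and sample effects
#' plus gene-specific error, and estimates each gene's error variance with a
#' bias correction that accounts for all candidates sharing the per-sample
#' normalization. In `"single"` mode the metric is the corrected error SD. In
#' `"by_condition"` mode (exactly two groups) the metric combines the
#' magnitude of the shrunken between-group expression difference with the
#' within-group error SD: mean over groups of |d| + sd/sqrt(n_group), the
#' usual form of the grouped stability value. Lower means more stable.
#'
#' @param x A preprocessed [ct_matrix()] with at least 3 genes (the bias
#'   correction is degenerate below that).
#' @param mode `"single"` (all samples one group; the default, also used for
#'   merged-condition analyses) or `"by_condition"`.
#' @return An `rg_stability` object with `algorithm = "normfinder"` and
#'   extras: `groups_used`, `intragroup_variance`, and (grouped mode)
#'   `intergroup_difference` (raw d) and `shrunken_difference`.
#' @export
normfinder <- function(x, mode = c("single", "by_condition")) {
  mode <- match.arg(mode)
  vals <- ct_values(x)
  k <- nrow(vals)
  if (k < 3L) abort_rgstab("bias correction needs >= 3 genes", "TOO_FEW_GENES")
  if (anyNA(vals)) abort_rgstab("complete values required; floor first", "MISSING_VALUES")

  if (mode == "single") {
    if (ncol(vals) < 3L) abort_rgstab("need >= 3 samples", "TOO_FEW_SAMPLES")
    av <- andersen_variances(vals)
    metric <- sqrt(av$sigma2)
    return(new_stability("normfinder", stats::setNames(metric, rownames(vals)),
                         extras = list(groups_used = "single",
                                       intragroup_variance = av$sigma2,
                                       raw_residual_variance = av$raw,
                                       clamped = av$clamped),
                         n_samples = ncol(vals)))
  }

  cond <- ct_conditions(x)
  groups <- unique(unname(cond))
  if (length(groups) != 2L) {
    abort_rgstab("by_condition mode supports exactly 2 groups", "BAD_GROUPS")
  }
  per_group <- lapply(groups, function(g) {
    sub <- vals[, names(cond)[cond == g], drop = FALSE]
    if (ncol(sub) < 2L) abort_rgstab("need >= 2 samples per group", "TOO_FEW_SAMPLES")
    z <- sweep(sub, 2L, colMeans(sub), "-")
    d <- rowMeans(z) - mean(z)
    av <- andersen_variances(sub)
    list(n = ncol(sub), d = d, sigma2 = av$sigma2)
  })
  names(per_group) <- groups

  d_mat <- vapply(per_group, `[[`, numeric(k), "d")
  # gene-by-group interaction contrast: remove each gene's across-group mean
  # so differences sum to zero over groups
  d_mat <- d_mat - rowMeans(d_mat)
  s2_mat <- vapply(per_group, `[[`, numeric(k), "sigma2")
  n_g <- vapply(per_group, `[[`, 0, "n")

  d_tilde <- d_mat
  for (j in seq_along(groups)) {
    gamma2 <- max(0, stats::var(d_mat[, j]) - mean(s2_mat[, j]) / n_g[j])
    shrink <- gamma2 / (gamma2 + s2_mat[, j] / n_g[j])
    shrink[!is.finite(shrink)] <- 0
    d_tilde[, j] <- d_mat[, j] * shrink
  }
  per_gene <- abs(d_tilde) + sqrt(sweep(s2_mat, 2L, n_g, "/"))
  metric <- rowMeans(per_gene)
  new_stability("normfinder", stats::setNames(metric, rownames(vals)),
                extras = list(groups_used = groups,
                              intragroup_variance = s2_mat,
                              intergroup_difference = d_mat,
                              shrunken_difference = d_tilde),
                n_samples = ncol(vals))
}

#' Descriptive-statistics stability (BestKeeper)
#'
#' Per gene: geometric mean, arithmetic mean, extrema, the dispersion
#' SD(±Ct) — by default the mean absolute deviation from the arithmetic mean,
#' the classical choice; `dispersion = "sd"` gives the n−1 standard deviation
#' instead — and the coefficient of variation CV% = 100·SD/AM. The per-sample
#' geometric mean of all candidates forms an index, and each gene's Pearson
#' correlation against that index is reported. Ranking uses SD(±Ct); lower
#' means more stable.
#'
#' @param x A preprocessed [ct_matrix()] with positive Ct values and at least
#'   2 samples.
#' @param dispersion `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @return An `rg_stability` object with `algorithm = "bestkeeper"` and a
#'   `descriptives` tibble, the per-sample `index`, and `index_correlation`
#'   in `extras`. The index correlation is `NA` when the index has zero
#'   variance.
#' @export
bestkeeper <- function(x, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  vals <- ct_values(x)
  if (ncol(vals) < 2L) abort_rgstab("need >= 2 samples", "TOO_FEW_SAMPLES")
  if (anyNA(vals)) abort_rgstab("complete values required; floor first", "MISSING_VALUES")
  if (any(vals <= 0)) abort_rgstab("geometric mean undefined for non-positive Ct", "NEGATIVE_CT")

  am <- rowMeans(vals)
  gm <- exp(rowMeans(log(vals)))
  sd_ct <- if (dispersion == "mad") {
    rowMeans(abs(vals - am))
  } else {
    apply(vals, 1L, stats::sd)
  }
  index <- exp(colMeans(log(vals)))
  r <- if (stats::sd(index) == 0) {
    rep(NA_real_, nrow(vals))
  } else {
    apply(vals, 1L, function(v) {
      if (stats::sd(v) == 0) NA_real_ else stats::cor(v, index)
    })
  }
  desc <- tibble::tibble(
    gene_id = rownames(vals),
    gm = unname(gm), am = unname(am),
    min = unname(apply(vals, 1L, min)), max = unname(apply(vals, 1L, max)),
    sd_ct = unname(sd_ct), cv_pct = unname(100 * sd_ct / am),
    index_r = unname(r)
  )
  new_stability("bestkeeper", stats::setNames(sd_ct, rownames(vals)),
                extras = list(descriptives = desc, index = index,
                              index_correlation = stats::setNames(r, rownames(vals)),
                              dispersion = dispersion),
                n_samples = ncol(vals))
}
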