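#' Floor censored readings to the detection limit
#'
#' Missing readings and readings above the detection threshold (Ct > 27 by
#' default) are stochastic at single-copy template amounts, so they are set to
#' the detection limit (28 by default) rather than carried as-is. All other
#' values are unchanged. The operation is idempotent and does not mutate its
#' input.
#'
#' @param x A [ct_matrix()].
#' @return A `ct_matrix` with no missing values and no value above the
#'   detection threshold other than the limit itself.
#' @export
floor_to_detection_limit <- function(x) {
  stopifnot(is_ct_matrix(x))
  thr <- attr(x, "detection_threshold")
  lim <- attr(x, "detection_limit")
  vals <- ct_values(x)
  vals[is.na(vals) | vals > thr] <- lim
  set_ct_values(x, vals)
}

#' Call per-gene presence by condition
#'
#' A gene is called absent in a condition when more than half of that
#' condition's samples read above the detection threshold or missing (for the
#' canonical 3-sample design: absent when 2 of 3 samples are censored).
#' Missing readings count as above-threshold. Presence is meant to be called
#' on raw (pre-equalization) values; the pipeline driver enforces that order.
#'
#' @param x A [ct_matrix()].
#' @return A tibble with one row per (gene, condition): `gene_id`,
#'   `condition`, `n_samples`, `n_above_threshold`, `present`.
#' @export
call_presence <- function(x) {
  stopifnot(is_ct_matrix(x))
  thr <- attr(x, "detection_threshold")
  vals <- ct_values(x)
  cond <- ct_conditions(x)
  tab <- table(cond)
  if (any(tab == 0L)) abort_rgstab("condition with 0 samples", "EMPTY_CONDITION")

  purrr::map_dfr(sort(unique(unname(cond))), function(cc) {
    cols <- names(cond)[cond == cc]
    sub <- vals[, cols, drop = FALSE]
    n_above <- rowSums(is.na(sub) | sub > thr)
    tibble::tibble(
      gene_id = rownames(vals),
      condition = cc,
      n_samples = length(cols),
      n_above_threshold = as.integer(n_above),
      present = n_above <= floor(length(cols) / 2)
    )
  })
}

#' Genes retained for an analysis scope
#'
#' @param presence A presence table from [call_presence()].
#' @param scope Character vector of condition labels; a gene is retained when
#'   present in every condition of the scope.
#' @return Character vector of gene ids.
#' @export
retained_genes <- function(presence, scope = unique(presence$condition)) {
  presence |>
    dplyr::filter(.data$condition %in% scope) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(keep = all(.data$present), .groups = "drop") |>
    dplyr::filter(.data$keep) |>
    dplyr::pull("gene_id")
}

#' Restrict a panel to detected candidates
#'
#' Keeps only the genes present (per [call_presence()]) in every condition of
#' `scope`, and only the samples belonging to those conditions. The spike-in
#' gene is never a candidate: it is dropped from the returned panel and its
#' per-sample Ct values are carried along in the `spike_ct` attribute so that
#' [spike_in_equalize()] can still use them.
#'
#' @param x A [ct_matrix()].
#' @param presence Presence table computed from `x`; defaults to
#'   [call_presence()] on `x`.
#' @param scope Condition labels defining the analysis; default all.
#' @return A `ct_matrix` of retained candidates with attributes `spike_ct`
#'   (named numeric, or `NULL`) and `dropped_genes`.
#' @export
filter_candidates <- function(x, presence = call_presence(x),
                              scope = unique(unname(ct_conditions(x)))) {
  stopifnot(is_ct_matrix(x))
  cond <- ct_conditions(x)
  if (!all(scope %in% cond)) {
    abort_rgstab("scope contains unknown condition labels", "BAD_SCOPE")
  }
  keep_samples <- names(cond)[cond %in% scope]
  keep_genes <- retained_genes(presence, scope)
  spike <- ct_spike_gene(x)
  keep_genes <- setdiff(keep_genes, spike)
  dropped <- setdiff(setdiff(ct_genes(x), spike), keep_genes)
  if (length(keep_genes) == 0L) {
    abort_rgstab("no candidate gene survives presence filtering", "EMPTY_PANEL")
  }
  vals <- ct_values(x)
  out <- set_ct_values(x, vals[keep_genes, keep_samples, drop = FALSE],
                       samples = keep_samples)
  attr(out, "spike_gene") <- NULL
  if (!is.null(spike)) {
    attr(out, "spike_ct") <- vals[spike, keep_samples]
  }
  attr(out, "dropped_genes") <- dropped
  out
}

# spike Ct values of a panel: either a spike row or the carried attribute
spike_ct_of <- function(x) {
  spike <- ct_spike_gene(x)
  if (!is.null(spike)) {
    v <- ct_values(x)[spike, ]
  } else {
    v <- attr(x, "spike_ct")
  }
  v
}

#' Equalize technical handling differences with the spike-in
#'
#' The exogenous spike-in is added in equal amount to every sample before RNA
#' extraction, so per-sample deviations of its Ct reflect technical recovery
#' and reverse-transcription differences. Each sample's Ct values are shifted
#' by (mean spike Ct − that sample's spike Ct), centring the spike-in at its
#' mean. Within-sample Ct differences are unchanged, so pairwise stability
#' measures are unaffected by this step. Values previously floored to the
#' detection limit are shifted like any other value.
#'
#' @param x A [ct_matrix()] with a spike-in row or a `spike_ct` attribute
#'   carried by [filter_candidates()].
#' @return The equalized `ct_matrix`.
#' @export
spike_in_equalize <- function(x) {
  stopifnot(is_ct_matrix(x))
  s <- spike_ct_of(x)
  if (is.null(s)) abort_rgstab("panel has no spike-in gene", "SPIKE_MISSING")
  if (anyNA(s)) {
    abort_rgstab(paste0("spike-in Ct missing in sample(s): ",
                        paste(names(s)[is.na(s)], collapse = ", ")),
                 "SPIKE_MISSING")
  }
  corr <- mean(s) - s
  vals <- ct_values(x)
  vals <- sweep(vals, 2L, corr, "+")
  out <- set_ct_values(x, vals)
  if (!is.null(attr(x, "spike_ct"))) attr(out, "spike_ct") <- s + corr
  attr(out, "dropped_genes") <- attr(x, "dropped_genes")
  out
}

#' Equalize RNA input by global-mean centring
#'
#' Subtle differences in the amount of starting RNA shift every gene of a
#' sample by a common Ct offset. Each sample is centred so that its mean Ct
#' over the retained candidates equals the grand mean over the whole panel
#' (the spike-in, if still present, is excluded from the means but shifted
#' with its sample). Within-sample Ct differences are preserved.
#'
#' @param x A [ct_matrix()] of retained candidates.
#' @return The equalized `ct_matrix`; after it, every sample's candidate mean
#'   Ct equals the grand mean.
#' @export
global_mean_equalize <- function(x) {
  stopifnot(is_ct_matrix(x))
  spike <- ct_spike_gene(x)
  vals <- ct_values(x)
  cand <- setdiff(rownames(vals), spike)
  if (length(cand) == 1L) {
    warning("global-mean equalization on a single gene forces it constant, destroying all signal")
  }
  if (anyNA(vals[cand, ])) {
    abort_rgstab("global-mean equalization requires complete values; floor first",
                 "MISSING_VALUES")
  }
  sample_means <- colMeans(vals[cand, , drop = FALSE])
  grand <- mean(vals[cand, , drop = FALSE])
  vals <- sweep(vals, 2L, grand - sample_means, "+")
  out <- set_ct_values(x, vals)
  attr(out, "dropped_genes") <- attr(x, "dropped_genes")
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: presence calling on raw values, detection-limit
#' flooring, candidate filtering for the requested scope, spike-in
#' equalization (when a spike-in is available), and global-mean equalization.
#' Presence is deliberately called before any equalization, since equalization
#' shifts values across the detection threshold.
#'
#' @param x A raw [ct_matrix()].
#' @param scope Condition labels defining the analysis; default all
#'   conditions.
#' @param spike_equalize Apply [spike_in_equalize()] when possible. Default
#'   `TRUE`.
#' @return A clean `ct_matrix` of candidates restricted to `scope`, with
#'   attributes `presence` (the presence table) and `dropped_genes`.
#' @export
preprocess_panel <- function(x, scope = unique(unname(ct_conditions(x))),
                             spike_equalize = TRUE) {
  presence <- call_presence(x)
  out <- floor_to_detection_limit(x)
  out <- filter_candidates(out, presence = presence, scope = scope)
  if (spike_equalize && !is.null(spike_ct_of(out))) {
    out <- spike_in_equalize(out)
  }
  out <- global_mean_equalize(out)
  attr(out, "spike_ct") <- NULL
  attr(out, "presence") <- presence
  out
}
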