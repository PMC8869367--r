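#' Specification of a synthetic Ct panel
#'
#' Describes the data-generating model used throughout the package's tests:
#' \deqn{Ct_{i,s} = baseline_i + input_s + tech_s + effect_i \cdot [s\ treated] + \epsilon_{i,s}}
#' with per-gene Gaussian noise \eqn{\epsilon_{i,s} \sim N(0, noise\_sd_i)} on
#' the Ct (log2) scale, a per-sample RNA-input offset \eqn{input_s \sim
#' N(0, sample\_offset\_sd)}, and a per-sample technical handling offset
#' \eqn{tech_s \sim N(0, spike\_offset\_sd)} that is shared with the
#' exogenous spike-in row (the component spike-in equalization removes).
#' Readings above `censor_above` are reported missing with probability 0.5
#' and otherwise set to the detection limit, exercising both censoring rules
#' of the preprocessing chain.
#'
#' @param n_genes Number of candidate genes (excluding the spike-in).
#' @param n_donors Donors; each contributes one sample per condition.
#' @param conditions Condition labels; all but the first are "treated".
#' @param gene_ids Gene identifiers; default `RG01`, `RG02`, ...
#' @param baseline Per-gene mean Ct in the untreated condition (cycles);
#'   `NULL` draws them uniformly on 12–26 at generation time.
#' @param noise_sd Per-gene technical+biological SD (cycles); recycled.
#' @param treatment_effect Per-gene Ct shift added in treated conditions
#'   (cycles; negative = up-regulation); recycled. 0 means stable under
#'   treatment.
#' @param sample_offset_sd SD of the per-sample RNA-input offset (cycles).
#' @param spike_offset_sd SD of the per-sample technical offset tracked by
#'   the spike-in (cycles).
#' @param spike_base Mean Ct of the spike-in row (cycles).
#' @param spike_gene Spike-in identifier.
#' @param censor_above Detection threshold (cycles), default 27.
#' @param detection_limit Detection limit (cycles), default 28.
#' @param seed Default seed used by [generate_panel()] when none is given.
#' @return A list of class `synthetic_spec`.
#' @seealso [default_panel_spec()] for the ready-made 15-gene panel.
#' @export
synthetic_spec <- function(n_genes = 15, n_donors = 3,
                           conditions = c("CTRL", "SF"),
                           gene_ids = sprintf("RG%02d", seq_len(n_genes)),
                           baseline = NULL,
                           noise_sd = 0.5,
                           treatment_effect = 0,
                           sample_offset_sd = 0.3,
                           spike_offset_sd = 0.5,
                           spike_base = 15,
                           spike_gene = "ath-miR-159a",
                           censor_above = 27,
                           detection_limit = 28,
                           seed = 1L) {
  stopifnot(n_genes >= 1, n_donors >= 1, length(conditions) >= 1,
            length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  noise_sd <- rep_len(noise_sd, n_genes)
  treatment_effect <- rep_len(treatment_effect, n_genes)
  if (any(noise_sd < 0)) abort_rgstab("noise_sd must be >= 0", "BAD_SPEC")
  if (!is.null(baseline)) {
    baseline <- rep_len(baseline, n_genes)
    if (any(baseline <= 0)) abort_rgstab("baseline Ct must be > 0", "BAD_SPEC")
  }
  if (!(censor_above < detection_limit)) {
    abort_rgstab("censor_above must be < detection_limit", "BAD_SPEC")
  }
  structure(
    list(n_genes = n_genes, n_donors = n_donors, conditions = conditions,
         gene_ids = gene_ids, baseline = baseline, noise_sd = noise_sd,
         treatment_effect = treatment_effect,
         sample_offset_sd = sample_offset_sd,
         spike_offset_sd = spike_offset_sd, spike_base = spike_base,
         spike_gene = spike_gene, censor_above = censor_above,
         detection_limit = detection_limit, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' The default 15-gene EV-miRNA-like panel
#'
#' A ready-made [synthetic_spec()] emulating a small-RNA qPCR array panel of
#' 15 candidate reference genes plus a spike-in, profiled in extracellular
#' vesicles from 3 donors under a control and a synovial-fluid-treated
#' condition. Gene names follow the miRNA panel conventional in this field.
#' The designed roles, recorded in the generated truth object, are:
#'
#' * `miR-24-3p` — the designated stable gene: noise SD 0.05 cycles, no
#'   treatment effect.
#' * `miR-34a-5p` — the designated unstable gene: noise SD 1.5 cycles.
#' * `miR-23a-3p` — quiet within each condition (SD 0.10) but shifted 1.6
#'   cycles by treatment, so it looks excellent within a condition and poor
#'   in a merged analysis.
#' * `miR-193b-5p` — a treatment-responsive target: Ct 1 cycle lower (2-fold
#'   up) under treatment, noise SD 0.15.
#' * `miR-22-5p`, `miR-29a-5p`, `miR-101-3p` — near the detection limit
#'   (baseline 27.5), so they fail presence calling and the 15-gene panel
#'   yields 12 candidates.
#' * eight ordinary genes with noise SDs 0.30–0.80 cycles.
#'
#' @return A `synthetic_spec`.
#' @export
default_panel_spec <- function() {
  genes <- c("miR-24-3p", "miR-34a-5p", "miR-23a-3p", "miR-193b-5p",
             "miR-22-5p", "miR-29a-5p", "miR-101-3p",
             "let-7a-5p", "miR-16-5p", "miR-26a-5p", "miR-103a-3p",
             "miR-221-3p", "miR-423-5p", "miR-425-5p", "miR-660-5p")
  baseline <- c(13.0, 18.0, 15.0, 22.0,
                27.5, 27.5, 27.5,
                20.0, 14.5, 17.0, 24.0, 19.0, 21.0, 16.0, 18.5)
  noise <- c(0.05, 1.50, 0.10, 0.15,
             0.30, 0.30, 0.30,
             0.80, 0.30, 0.40, 0.70, 0.50, 0.45, 0.35, 0.60)
  effect <- c(0, 0, 1.6, -1.0, rep(0, 11))
  synthetic_spec(n_genes = length(genes), gene_ids = genes,
                 baseline = baseline, noise_sd = noise,
                 treatment_effect = effect)
}

#' Generate a synthetic Ct panel with ground truth
#'
#' Draws one panel from a [synthetic_spec()]. The same seed always yields the
#' same panel. Sample ids are the condition's first letter plus the donor
#' number (`C1..C3`, `S1..S3` for the default conditions).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list with `matrix` (a [ct_matrix()] including the spike-in row)
#'   and `truth` (class `synthetic_truth`): the realized per-gene parameters,
#'   per-sample offsets, a per-gene stability score (noise SD plus half the
#'   absolute treatment effect), and the designated most/least stable genes
#'   overall and within conditions.
#' @export
generate_panel <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))

  prefixes <- toupper(substr(spec$conditions, 1L, 1L))
  if (anyDuplicated(prefixes)) prefixes <- spec$conditions
  samples <- as.vector(t(outer(prefixes, seq_len(spec$n_donors), paste0)))
  cond <- stats::setNames(rep(spec$conditions, each = spec$n_donors), samples)
  treated <- cond %in% spec$conditions[-1L]
  n_s <- length(samples)

  baseline <- spec$baseline %||% stats::runif(spec$n_genes, 12, 26)
  input_offset <- stats::rnorm(n_s, 0, spec$sample_offset_sd)
  tech_offset <- stats::rnorm(n_s, 0, spec$spike_offset_sd)
  eps <- matrix(stats::rnorm(spec$n_genes * n_s), spec$n_genes, n_s) * spec$noise_sd

  vals <- baseline +
    outer(rep(1, spec$n_genes), input_offset + tech_offset) +
    outer(spec$treatment_effect, as.numeric(treated)) + eps
  dimnames(vals) <- list(spec$gene_ids, samples)

  over <- which(vals > spec$censor_above)
  if (length(over) > 0L) {
    drop_as_missing <- stats::runif(length(over)) < 0.5
    vals[over[drop_as_missing]] <- NA_real_
    vals[over[!drop_as_missing]] <- spec$detection_limit
  }

  spike <- spec$spike_base + tech_offset
  vals <- rbind(vals, matrix(spike, 1L, n_s,
                             dimnames = list(spec$spike_gene, samples)))

  score <- spec$noise_sd + abs(spec$treatment_effect) / 2
  truth <- structure(
    list(
      genes = tibble::tibble(
        gene_id = spec$gene_ids, baseline = baseline,
        noise_sd = spec$noise_sd, treatment_effect = spec$treatment_effect,
        stability_score = score
      ),
      sample_offsets = tibble::tibble(
        sample_id = samples, condition = unname(cond),
        input_offset = input_offset, tech_offset = tech_offset
      ),
      most_stable_overall = spec$gene_ids[which.min(score)],
      least_stable_overall = spec$gene_ids[which.max(score)],
      most_stable_within_condition = spec$gene_ids[which.min(spec$noise_sd)],
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )

  list(
    matrix = ct_matrix(vals, condition = cond, spike_gene = spec$spike_gene,
                       detection_threshold = spec$censor_above,
                       detection_limit = spec$detection_limit),
    truth = truth
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic panel ground truth (seed ", x$seed, ")\n", sep = "")
  cat("  most stable overall:  ", x$most_stable_overall, "\n", sep = "")
  cat("  least stable overall: ", x$least_stable_overall, "\n", sep = "")
  print(x$genes)
  invisible(x)
}
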