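#' Relative expression of a target against a reference gene
#'
#' Comparative-Ct quantification with amplification efficiency 2: for each
#' sample s, the relative quantity versus a milestone sample m is
#' \deqn{RQ_s = 2^{-[(Ct_{target,s} - Ct_{ref,s}) - (Ct_{target,m} - Ct_{ref,m})]}}
#' so the milestone sample is exactly 1 and every other sample is a fold
#' change relative to it.
#'
#' @param x A [ct_matrix()] containing both genes (typically preprocessed,
#'   but any complete panel works).
#' @param target,reference Gene ids; must differ.
#' @param milestone Sample id set to RQ = 1.
#' @return A tibble of class `rq_table`: `sample_id`, `condition`,
#'   `delta_ct` (target − reference), `rq`; attributes `target`, `reference`,
#'   `milestone`.
#' @export
relative_expression <- function(x, target, reference, milestone) {
  vals <- ct_values(x)
  if (target == reference) abort_rgstab("target and reference must differ", "BAD_GENE")
  if (!all(c(target, reference) %in% rownames(vals))) {
    abort_rgstab("target or reference not in panel", "BAD_GENE")
  }
  if (!milestone %in% colnames(vals)) {
    abort_rgstab(paste0("milestone sample '", milestone, "' not in panel"), "BAD_SAMPLE")
  }
  if (anyNA(vals[c(target, reference), ])) {
    abort_rgstab("missing Ct for target or reference; floor first", "MISSING_VALUES")
  }
  dct <- vals[target, ] - vals[reference, ]
  rq <- 2^(-(dct - dct[milestone]))
  rq[milestone] <- 1  # exact by definition
  structure(
    tibble::tibble(sample_id = colnames(vals),
                   condition = unname(ct_conditions(x)[colnames(vals)]),
                   delta_ct = unname(dct), rq = unname(rq)),
    target = target, reference = reference, milestone = milestone,
    class = c("rq_table", class(tibble::tibble()))
  )
}

#' Per-donor treated/control fold change
#'
#' Ratio of relative quantities between paired treated and control samples of
#' the same donor. Because the milestone normalization cancels in the ratio,
#' this equals the direct within-donor comparative-Ct fold change
#' \eqn{2^{-\Delta\Delta Ct}}. Swapping the treated and control roles inverts
#' every ratio.
#'
#' @param table_treated,table_control `rq_table`s from [relative_expression()]
#'   sharing target and reference.
#' @param pairing A data frame with columns `donor`, `treated`, `control`
#'   giving the sample ids of each donor's pair.
#' @return A tibble: `donor`, `rq_treated`, `rq_control`, `ratio`.
#' @export
condition_ratio <- function(table_treated, table_control, pairing) {
  for (a in c("target", "reference")) {
    if (!identical(attr(table_treated, a), attr(table_control, a))) {
      abort_rgstab(paste0("tables disagree on ", a), "BAD_INPUT")
    }
  }
  pairing <- tibble::as_tibble(pairing)
  stopifnot(all(c("donor", "treated", "control") %in% names(pairing)))
  rq_t <- stats::setNames(table_treated$rq, table_treated$sample_id)
  rq_c <- stats::setNames(table_control$rq, table_control$sample_id)
  missing <- pairing$donor[!(pairing$treated %in% names(rq_t)) |
                             !(pairing$control %in% names(rq_c))]
  if (length(missing) > 0L) {
    abort_rgstab(paste0("unpaired donor(s): ", paste(missing, collapse = ", ")),
                 "UNPAIRED_DONOR")
  }
  tibble::tibble(
    donor = pairing$donor,
    rq_treated = unname(rq_t[pairing$treated]),
    rq_control = unname(rq_c[pairing$control]),
    ratio = unname(rq_t[pairing$treated] / rq_c[pairing$control])
  )
}

#' One-sample t-test with a compound fold-change criterion
#'
#' Tests whether fold changes differ from a hypothetical mean (1 = no
#' change) with a two-sided one-sample t-test, and—when the compound
#' criterion is on (the default)—calls the result significant only if the
#' mean fold change also reaches `fold_criterion` (default 2). This is the
#' usual "at least two-fold AND p ≤ 0.05" call for treated-versus-control
#' comparisons.
#'
#' @param values Positive fold changes (one per donor); at least 2, with
#'   non-zero spread.
#' @param mu Hypothetical mean, default 1.
#' @param alpha Significance level, default 0.05.
#' @param fold_criterion Minimum mean fold change, default 2.
#' @param compound Require the fold criterion as well as p ≤ alpha. Default
#'   `TRUE`.
#' @return A one-row tibble: `estimate` (mean), `statistic` (t), `df`,
#'   `p_value`, `significant`, `criterion`.
#' @export
one_sample_t_test <- function(values, mu = 1, alpha = 0.05,
                              fold_criterion = 2, compound = TRUE) {
  if (length(values) < 2L) abort_rgstab("need >= 2 values", "TOO_FEW_SAMPLES")
  if (stats::sd(values) == 0) {
    abort_rgstab("zero spread: t-test undefined", "DEGENERATE")
  }
  fit <- stats::t.test(values, mu = mu)
  p <- unname(fit$p.value)
  m <- unname(fit$estimate)
  sig <- if (compound) (m >= fold_criterion) && (p <= alpha) else p <= alpha
  criterion <- if (compound) {
    sprintf("mean >= %g and p <= %g", fold_criterion, alpha)
  } else {
    sprintf("p <= %g", alpha)
  }
  tibble::tibble(estimate = m, statistic = unname(fit$statistic),
                 df = unname(fit$parameter), p_value = p,
                 significant = sig, criterion = criterion)
}

#' Two-sided single-outlier Grubbs test
#'
#' Flags at most one outlier: the value farthest from the mean in units of
#' the (n−1) standard deviation. The critical value at level `alpha` is
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n-2+t^2}}}
#' with t the upper `alpha/(2n)` quantile of the t-distribution on n−2
#' degrees of freedom.
#'
#' @param values Numeric vector, n ≥ 3.
#' @param alpha Significance level, default 0.05.
#' @return A one-row tibble: `statistic` (G), `critical`, `outlier_index`,
#'   `outlier_value` (both `NA` when no outlier is flagged), `significant`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) abort_rgstab("Grubbs test needs >= 3 values", "TOO_FEW_SAMPLES")
  s <- stats::sd(values)
  if (s == 0) abort_rgstab("zero spread: Grubbs test undefined", "DEGENERATE")
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  out <- g > gcrit
  idx <- if (out) which.max(dev) else NA_integer_
  tibble::tibble(statistic = g, critical = gcrit,
                 outlier_index = idx,
                 outlier_value = if (out) values[idx] else NA_real_,
                 significant = out)
}
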