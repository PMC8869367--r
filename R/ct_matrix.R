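#' Construct a Ct panel
#'
#' A `ct_matrix` holds quantification-cycle (Ct) values for a panel of small
#' RNAs measured across samples, together with the per-sample condition labels,
#' an optional exogenous spike-in row, and the platform's detection threshold
#' and limit. It is a tibble with one row per gene (first column `gene_id`,
#' one numeric column per sample) so that it prints and pipes like any other
#' tidy table, plus attributes carrying the panel metadata.
#'
#' Ct is a log2-scale abundance measure: one cycle corresponds to a two-fold
#' difference in template, and higher Ct means less template. Values above the
#' detection threshold (default 27 cycles) are considered stochastic and are
#' floored to the detection limit (default 28, roughly single-copy territory
#' on array-format qPCR platforms) by [floor_to_detection_limit()].
#'
#' @param x A data frame whose first column holds gene identifiers and whose
#'   remaining columns hold numeric Ct values (one column per sample), or a
#'   numeric matrix with gene rownames and sample colnames.
#' @param condition Named character vector mapping every sample id to a
#'   condition label (e.g. `c(C1 = "CTRL", S1 = "SF")`). If `NULL`, sample ids
#'   of the form `C<i>`/`S<i>` are mapped to `"CTRL"`/`"SF"`; otherwise all
#'   samples are assigned the single condition `"ALL"`.
#' @param spike_gene Optional gene id of an exogenous spike-in (e.g.
#'   `"ath-miR-159a"`). If `NULL`, a single gene whose id starts with `"ath-"`
#'   is auto-detected.
#' @param detection_threshold Cycles above which a reading is treated as not
#'   reliably detected. Default 27.
#' @param detection_limit Cycles assigned to censored readings. Default 28.
#'
#' @return A `ct_matrix` (tibble subclass).
#' @examples
#' m <- ct_matrix(
#'   data.frame(gene_id = c("miR-16-5p", "miR-23a-3p"),
#'              C1 = c(20.1, 18.9), C2 = c(20.4, 19.2),
#'              S1 = c(21.0, 19.1), S2 = c(20.8, 18.8))
#' )
#' ct_conditions(m)
#' @export
ct_matrix <- function(x, condition = NULL, spike_gene = NULL,
                      detection_threshold = 27, detection_limit = 28) {
  if (is.matrix(x)) {
    if (is.null(colnames(x)) && !is.null(names(condition)) &&
        length(condition) == ncol(x)) {
      colnames(x) <- names(condition)
    }
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort_rgstab("matrix input requires gene rownames and sample colnames",
                   "BAD_INPUT")
    }
    x <- tibble::as_tibble(as.data.frame(x), rownames = "gene_id")
  }
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort_rgstab("`x` must be a data frame with a gene id column and at least one sample column",
                 "EMPTY")
  }
  df <- tibble::as_tibble(x)
  names(df)[1] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  for (j in seq(2L, ncol(df))) df[[j]] <- as.numeric(df[[j]])

  samples <- names(df)[-1]
  if (is.null(condition)) condition <- infer_conditions(samples)
  condition <- condition[samples]
  if (anyNA(condition) || is.null(names(condition))) {
    abort_rgstab("`condition` must name a label for every sample", "BAD_CONDITION")
  }
  if (is.null(spike_gene)) {
    auto <- grep("^ath-", df$gene_id, value = TRUE)
    if (length(auto) == 1L) spike_gene <- auto
  }

  out <- structure(
    df,
    condition = stats::setNames(as.character(condition), samples),
    spike_gene = spike_gene,
    detection_threshold = detection_threshold,
    detection_limit = detection_limit,
    class = c("ct_matrix", class(tibble::tibble()))
  )
  rep <- validate_matrix(out)
  if (nrow(rep$errors) > 0L) {
    abort_rgstab(paste0("invalid ct_matrix: ",
                        paste(rep$errors$message, collapse = "; ")),
                 rep$errors$code[1])
  }
  out
}

infer_conditions <- function(samples) {
  if (all(grepl("^[CcSs]", samples))) {
    stats::setNames(ifelse(grepl("^[Cc]", samples), "CTRL", "SF"), samples)
  } else {
    stats::setNames(rep("ALL", length(samples)), samples)
  }
}

#' @rdname ct_matrix
#' @export
is_ct_matrix <- function(x) inherits(x, "ct_matrix")

#' Accessors for `ct_matrix` metadata
#'
#' `ct_values()` returns the genes-by-samples numeric matrix, `ct_genes()` and
#' `ct_samples()` the identifier vectors, `ct_conditions()` the named
#' sample-to-condition map, and `ct_spike_gene()` the spike-in id (or `NULL`).
#'
#' @param x A [ct_matrix()].
#' @return See individual descriptions.
#' @export
ct_values <- function(x) {
  stopifnot(is_ct_matrix(x))
  v <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  rownames(v) <- x$gene_id
  storage.mode(v) <- "double"
  v
}

#' @rdname ct_values
#' @export
ct_genes <- function(x) x$gene_id

#' @rdname ct_values
#' @export
ct_samples <- function(x) names(x)[-1]

#' @rdname ct_values
#' @export
ct_conditions <- function(x) attr(x, "condition")

#' @rdname ct_values
#' @export
ct_spike_gene <- function(x) attr(x, "spike_gene")

# rebuild a ct_matrix from a values matrix, inheriting metadata from `template`
set_ct_values <- function(template, values, samples = colnames(values)) {
  cond <- ct_conditions(template)[samples]
  df <- tibble::as_tibble(as.data.frame(values), rownames = "gene_id")
  names(df) <- c("gene_id", samples)
  structure(
    df,
    condition = cond,
    spike_gene = intersect(attr(template, "spike_gene"), rownames(values)) %0% NULL,
    detection_threshold = attr(template, "detection_threshold"),
    detection_limit = attr(template, "detection_limit"),
    spike_ct = attr(template, "spike_ct"),
    class = c("ct_matrix", class(tibble::tibble()))
  )
}

`%0%` <- function(a, b) if (length(a) == 0L) b else a

abort_rgstab <- function(message, code) {
  rlang::abort(message, class = c(paste0("rgstab_error_", code), "rgstab_error"))
}

#' Validate a Ct panel
#'
#' Checks every structural invariant of a [ct_matrix()] and returns the
#' findings as data rather than raising: duplicate identifiers, non-positive
#' or non-finite Ct values, inconsistent detection threshold/limit, a spike-in
#' id that is not a member of the panel, and an empty grid. An empty `errors`
#' table means the panel satisfies all invariants.
#'
#' @param x A `ct_matrix` (or something shaped like one).
#' @return A list of class `ct_validation` with tibbles `errors` and
#'   `warnings` (columns `code`, `message`) and counts `n_genes`, `n_samples`,
#'   `n_missing`.
#' @export
validate_matrix <- function(x) {
  errors <- list()
  warnings <- list()
  add <- function(store, code, message) c(store, list(list(code = code, message = message)))

  genes <- x$gene_id
  samples <- names(x)[-1]
  if (length(genes) == 0L || length(samples) == 0L) {
    errors <- add(errors, "EMPTY", "matrix has no genes or no samples")
  }
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0L) {
    errors <- add(errors, "DUP_GENE",
                  paste0("duplicated gene id(s): ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0L) {
    errors <- add(errors, "DUP_SAMPLE",
                  paste0("duplicated sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  vals <- suppressWarnings(as.matrix(as.data.frame(x)[, -1, drop = FALSE]))
  storage.mode(vals) <- "double"
  bad <- !is.na(vals) & (!is.finite(vals) | vals <= 0)
  if (any(bad)) {
    errors <- add(errors, "NEGATIVE_CT",
                  paste0(sum(bad), " value(s) are non-positive or non-finite"))
  }
  thr <- attr(x, "detection_threshold")
  lim <- attr(x, "detection_limit")
  if (!is.null(thr) && !is.null(lim) && !(thr < lim)) {
    errors <- add(errors, "BAD_LIMITS",
                  sprintf("detection_threshold (%s) must be < detection_limit (%s)", thr, lim))
  }
  sg <- attr(x, "spike_gene")
  if (!is.null(sg) && !sg %in% genes) {
    errors <- add(errors, "BAD_SPIKE",
                  paste0("spike_gene '", sg, "' is not a gene of the panel"))
  }
  cond <- attr(x, "condition")
  if (!is.null(cond) && !setequal(names(cond), samples)) {
    errors <- add(errors, "BAD_CONDITION",
                  "condition labels do not cover exactly the sample ids")
  }

  as_tbl <- function(store) {
    if (length(store) == 0L) {
      tibble::tibble(code = character(), message = character())
    } else {
      tibble::tibble(code = vapply(store, `[[`, "", "code"),
                     message = vapply(store, `[[`, "", "message"))
    }
  }
  structure(
    list(errors = as_tbl(errors), warnings = as_tbl(warnings),
         n_genes = length(genes), n_samples = length(samples),
         n_missing = sum(is.na(vals))),
    class = "ct_validation"
  )
}

#' @export
print.ct_validation <- function(x, ...) {
  cat(sprintf("Ct panel validation: %d genes x %d samples, %d missing\n",
              x$n_genes, x$n_samples, x$n_missing))
  if (nrow(x$errors) == 0L) {
    cat("No errors.\n")
  } else {
    cat("Errors:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat("  [", x$errors$code[i], "] ", x$errors$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
print.ct_matrix <- function(x, ...) {
  cond <- ct_conditions(x)
  cat(sprintf("# Ct panel: %d genes x %d samples (%s)\n",
              nrow(x), length(cond),
              paste(sprintf("%s n=%d", names(table(cond)), table(cond)),
                    collapse = ", ")))
  if (!is.null(ct_spike_gene(x))) {
    cat("# spike-in: ", ct_spike_gene(x), "\n", sep = "")
  }
  cat(sprintf("# detection threshold %s, limit %s cycles\n",
              attr(x, "detection_threshold"), attr(x, "detection_limit")))
  NextMethod()
}
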