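#' Read a Ct panel from delimited text
#'
#' Reads the package's canonical dialect: genes as rows and samples as
#' columns, one header line of sample ids, and an optional second header line
#' starting with `condition` giving the per-sample condition labels. Lines
#' starting with `#` are ignored. Empty cells and the tokens `NA`, `ND` and
#' `Undetermined` (case-insensitive) denote missing readings, which are kept
#' missing — flooring to the detection limit is a separate, explicit step
#' ([floor_to_detection_limit()]).
#'
#' Files exported with samples as rows are read with
#' `orientation = "samples-as-rows"`; the result is identical to reading the
#' transposed file.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, default `","`.
#' @param orientation `"genes-as-rows"` (default) or `"samples-as-rows"`.
#' @param condition,spike_gene,detection_threshold,detection_limit Passed to
#'   [ct_matrix()]; an explicit `condition` overrides any condition header
#'   line in the file.
#' @return A [ct_matrix()].
#' @export
read_ct_matrix <- function(path, delimiter = ",",
                           orientation = c("genes-as-rows", "samples-as-rows"),
                           condition = NULL, spike_gene = NULL,
                           detection_threshold = 27, detection_limit = 28) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort_rgstab(paste0("file not found: ", path), "IO")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) abort_rgstab("file contains no data rows", "EMPTY")

  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(fields[[1]])
  col_ids <- header[-1]
  body <- fields[-1]

  cond_from_file <- NULL
  if (tolower(trimws(body[[1]][1])) == "condition") {
    labels <- trimws(body[[1]][-1])
    cond_from_file <- stats::setNames(labels, col_ids)
    body <- body[-1]
  }
  if (length(body) == 0L) abort_rgstab("file contains no data rows", "EMPTY")

  row_ids <- vapply(body, function(f) trimws(f[1]), "")
  cells <- lapply(body, function(f) {
    v <- trimws(f[-1])
    length(v) <- length(col_ids)  # pad short rows with NA tokens
    v
  })
  values <- matrix(NA_real_, nrow = length(row_ids), ncol = length(col_ids),
                   dimnames = list(row_ids, col_ids))
  missing_tokens <- c("", "na", "nd", "undetermined")
  for (i in seq_along(cells)) {
    v <- cells[[i]]
    is_missing <- is.na(v) | tolower(v) %in% missing_tokens
    num <- suppressWarnings(as.numeric(v))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      j <- which(bad)[1]
      abort_rgstab(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                           v[j], row_ids[i], col_ids[j]), "BAD_CELL")
    }
    num[is_missing] <- NA_real_
    values[i, ] <- num
  }

  if (orientation == "samples-as-rows") {
    values <- t(values)
    # a condition header line labels columns, which are genes here: not applicable
    cond_from_file <- NULL
  }

  genes <- rownames(values)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    abort_rgstab(paste0("duplicated gene id(s): ", paste(dup, collapse = ", ")),
                 "DUP_GENE")
  }
  cond <- condition %||% cond_from_file
  ct_matrix(values, condition = cond, spike_gene = spike_gene,
            detection_threshold = detection_threshold,
            detection_limit = detection_limit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Ct panel as delimited text
#'
#' Writes the canonical dialect read by [read_ct_matrix()]: a header line of
#' sample ids, a `condition` line with the per-sample labels, then one row per
#' gene. Missing values are written as `NA`. Values are formatted to 10
#' significant digits, so a write/read cycle preserves them well beyond the
#' precision qPCR instruments report, and a second write of the re-read panel
#' is byte-identical.
#'
#' @param x A valid [ct_matrix()].
#' @param path Output file path.
#' @param delimiter Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path, delimiter = ",") {
  rep <- validate_matrix(x)
  if (nrow(rep$errors) > 0L) {
    abort_rgstab(paste0("refusing to write invalid matrix: ",
                        paste(rep$errors$message, collapse = "; ")),
                 rep$errors$code[1])
  }
  vals <- ct_values(x)
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g"))
  lines <- c(
    paste(c("gene_id", colnames(vals)), collapse = delimiter),
    paste(c("condition", unname(ct_conditions(x)[colnames(vals)])),
          collapse = delimiter),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], fmt(vals[i, ])), collapse = delimiter)
    }, "")
  )
  tryCatch(suppressWarnings(writeLines(lines, path)),
           error = function(e) abort_rgstab(paste0("cannot write ", path), "IO"))
  invisible(path)
}

#' Write a result table as CSV with a provenance header
#'
#' All tabular results of the pipeline are plain CSV with a one-line comment
#' header recording the package version and the producing step, so a result
#' file is self-describing.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @param command Short label of the producing step.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(tbl, path, command = "result") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# rgstab %s %s",
                     as.character(utils::packageVersion("rgstab")), command), con)
  utils::write.csv(as.data.frame(tbl), con, row.names = FALSE)
  invisible(path)
}
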