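# Small panels built in code, shared across test files.

# deterministic 3-gene toy with hand-computable pairwise variations
toy_matrix <- function() {
  ct_matrix(data.frame(gene_id = c("G1", "G2", "G3"),
                       C1 = c(20, 20, 20),
                       C2 = c(21, 21, 22),
                       C3 = c(22, 22, 21)))
}

# random complete panel: k genes x n samples, Ct ~ N(20, 1), no spike
random_panel <- function(k, n, seed, conditions = NULL) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(k * n, mean = 20, sd = 1), k, n,
                 dimnames = list(sprintf("G%02d", seq_len(k)),
                                 sprintf("S%02d", seq_len(n))))
  cond <- conditions %||% stats::setNames(rep("ALL", n), colnames(vals))
  ct_matrix(vals, condition = cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a canonical CSV fixture and return its path (tempdir, cleaned by R)
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

metrics_of <- function(st) stats::setNames(st$table$metric, st$table$gene_id)
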