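test_that("pairwise variation is the n-1 SD of Ct differences", {
  m <- toy_matrix()
  expect_equal(pairwise_variation(m, "G1", "G1"), 0)
  expect_equal(pairwise_variation(m, "G1", "G3"), 1)  # SD of (0, -1, 1)
  expect_equal(pairwise_variation(m, "G1", "G3"),
               pairwise_variation(m, "G3", "G1"))
  shifted <- ct_matrix(rbind(A = c(20, 21, 22), B = c(23, 24, 25)),
                       condition = c(S1 = "ALL", S2 = "ALL", S3 = "ALL"))
  expect_equal(pairwise_variation(shifted, "A", "B"), 0)
})

test_that("stepwise exclusion reproduces the hand-computed toy and shares the final M", {
  g <- genorm(toy_matrix())
  expect_equal(metrics_of(g), c(G1 = 0, G2 = 0, G3 = 1))
  expect_equal(g$extras$exclusion_order, "G3")
  expect_setequal(g$extras$final_pair, c("G1", "G2"))
  expect_equal(unname(setNames(g$table$rank, g$table$gene_id)[c("G1", "G2", "G3")]),
               c(1L, 1L, 3L))
  expect_error(genorm(random_panel(2, 4, seed = 1)),
               class = "rgstab_error_TOO_FEW_GENES")
})

test_that("a duplicated gene survives to the final pair with M 0", {
  m <- random_panel(5, 6, seed = 3)
  vals <- rbind(ct_values(m), G_dup = ct_values(m)["G01", ] + 2)
  g <- genorm(ct_matrix(vals, condition = ct_conditions(m)))
  expect_setequal(g$extras$final_pair, c("G01", "G_dup"))
  expect_equal(metrics_of(g)[["G01"]], 0)
})

test_that("the final pair always shares one exact M value", {
  for (s in 1:20) {
    set.seed(s)
    g <- genorm(random_panel(sample(3:12, 1), sample(3:8, 1), seed = s))
    pair <- g$extras$final_pair
    mm <- metrics_of(g)
    expect_identical(mm[[pair[1]]], mm[[pair[2]]])
  }
})

test_that("mean pairwise variation equals first-round stepwise M everywhere", {
  expect_equal(metrics_of(delta_ct_stability(toy_matrix())),
               c(G1 = 0.5, G2 = 0.5, G3 = 1))
  for (s in 1:100) {
    m <- random_panel(12, 6, seed = 1000 + s)
    d <- metrics_of(delta_ct_stability(m))
    V <- genorm(m)$extras$pairwise_variation
    first_round <- rowSums(V) / (nrow(V) - 1)
    expect_lt(max(abs(d - first_round[names(d)])), 1e-12)
  }
})

test_that("model-based stability is zero on exactly additive data", {
  vals <- outer(c(14, 17, 20, 23), c(0, 0.5, -0.3, 0.2, 1), "+")
  dimnames(vals) <- list(paste0("G", 1:4), paste0("S", 1:5))
  nf <- normfinder(ct_matrix(vals, condition = setNames(rep("ALL", 5), colnames(vals))))
  expect_equal(unname(metrics_of(nf)), rep(0, 4), tolerance = 1e-12)
})

test_that("bias-corrected variances match an independent solve of the estimating equations", {
  # the relation s2_i = sigma2_i (1 - 2/k) + sum(sigma2)/k^2 is a linear
  # system A sigma2 = s2 with A = (1 - 2/k) I + J/k^2; solve it directly.
  brute_force <- function(vals) {
    k <- nrow(vals); n <- ncol(vals)
    r <- vals
    for (i in seq_len(k)) r[i, ] <- r[i, ] - mean(vals[i, ])
    for (j in seq_len(n)) r[, j] <- r[, j] - mean(r[, j])
    s2 <- apply(r, 1, function(x) sum(x^2) / (n - 1))
    A <- diag(1 - 2 / k, k) + matrix(1 / k^2, k, k)
    pmax(solve(A, s2), 0)
  }
  for (s in 1:50) {
    m <- random_panel(5, 8, seed = 2000 + s)
    nf <- normfinder(m)
    expect_lt(max(abs(nf$extras$intragroup_variance - brute_force(ct_values(m)))),
              1e-9)
  }
})

test_that("model-based ranking tracks the true noise ordering in simulation", {
  last_ok <- 0
  rho <- numeric(200)
  for (s in 1:200) {
    sp <- synthetic_spec(n_genes = 4, n_donors = 3, conditions = c("CTRL", "SF"),
                         baseline = c(16, 18, 20, 22),
                         noise_sd = c(0.05, 0.1, 0.3, 0.6), treatment_effect = 0)
    nf <- normfinder(preprocess_panel(generate_panel(sp, seed = s)$matrix))
    tb <- nf$table
    last_ok <- last_ok + (tb$rank[tb$gene_id == "RG04"] == 4L)
    rho[s] <- cor(tb$metric, c(0.05, 0.1, 0.3, 0.6), method = "spearman")
  }
  expect_gte(last_ok / 200, 0.85)   # noisiest gene identified as least stable
  expect_gte(mean(rho), 0.7)        # metric order tracks the truth on average
})

test_that("grouped mode decomposes into balanced group differences", {
  sp <- synthetic_spec(n_genes = 6, n_donors = 4, conditions = c("CTRL", "SF"),
                       baseline = seq(14, 24, 2), noise_sd = 0.3,
                       treatment_effect = c(0, 0, 1, 0, 0, 0))
  clean <- preprocess_panel(generate_panel(sp, seed = 9)$matrix)
  nf <- normfinder(clean, mode = "by_condition")
  d <- nf$extras$intergroup_difference
  expect_equal(unname(rowSums(d)), rep(0, nrow(d)), tolerance = 1e-9)
  expect_true(all(nf$extras$intragroup_variance >= 0))
  # the treatment-shifted gene carries the largest group difference
  expect_equal(rownames(d)[which.max(abs(d[, 1]))], "RG03")
  expect_no_error(normfinder(clean, mode = "single"))
})

test_that("descriptive statistics match hand computation and shift as expected", {
  m <- ct_matrix(rbind(A = c(20, 21, 22), B = c(18, 18, 18)),
                 condition = c(S1 = "ALL", S2 = "ALL", S3 = "ALL"))
  bk <- bestkeeper(m)
  desc <- bk$extras$descriptives
  a <- desc[desc$gene_id == "A", ]
  expect_equal(a$am, 21)
  expect_equal(a$sd_ct, 2 / 3, tolerance = 1e-12)
  expect_equal(a$gm, (20 * 21 * 22)^(1 / 3), tolerance = 1e-9)
  expect_equal(a$min, 20)
  expect_equal(a$max, 22)
  b <- desc[desc$gene_id == "B", ]
  expect_equal(b$sd_ct, 0)
  expect_equal(b$cv_pct, 0)
  expect_true(all(desc$gm <= desc$am + 1e-12))

  shifted <- ct_matrix(rbind(A = c(20, 21, 22) + 3, B = c(18, 18, 18)),
                       condition = c(S1 = "ALL", S2 = "ALL", S3 = "ALL"))
  bk2 <- bestkeeper(shifted)
  a2 <- bk2$extras$descriptives[bk2$extras$descriptives$gene_id == "A", ]
  expect_equal(a2$sd_ct, a$sd_ct)
  expect_equal(a2$am, a$am + 3)

  classical <- bestkeeper(m, dispersion = "sd")
  expect_equal(metrics_of(classical)[["A"]], 1)
})

test_that("sample-shift, gene-shift and permutation invariances hold", {
  m <- random_panel(8, 6, seed = 77)
  vals <- ct_values(m)
  cond <- ct_conditions(m)
  algs <- list(genorm = genorm, delta_ct = delta_ct_stability,
               normfinder = normfinder, bestkeeper = bestkeeper)
  base <- lapply(algs, function(f) metrics_of(f(m)))

  # per-sample shifts leave all but the descriptive dispersion unchanged
  shift_s <- sweep(vals, 2, seq(-0.5, 0.75, length.out = 6), "+")
  m_s <- ct_matrix(shift_s, condition = cond)
  for (a in c("genorm", "delta_ct", "normfinder")) {
    expect_equal(metrics_of(algs[[a]](m_s)), base[[a]], tolerance = 1e-9)
  }
  expect_gt(max(abs(metrics_of(bestkeeper(m_s)) - base$bestkeeper)), 1e-6)

  # a constant added to one gene changes no metric of any algorithm
  shift_g <- vals
  shift_g["G03", ] <- shift_g["G03", ] + 2.5
  m_g <- ct_matrix(shift_g, condition = cond)
  for (a in names(algs)) {
    expect_equal(metrics_of(algs[[a]](m_g)), base[[a]], tolerance = 1e-9)
  }

  # permuting samples permutes nothing in the metrics
  perm <- c(4, 1, 6, 2, 5, 3)
  m_p <- ct_matrix(vals[, perm], condition = cond[perm])
  for (a in names(algs)) {
    expect_equal(metrics_of(algs[[a]](m_p)), base[[a]], tolerance = 1e-9)
  }
})

test_that("all stability metrics are non-negative on random panels", {
  for (s in 1:10) {
    m <- random_panel(6, 5, seed = 300 + s)
    expect_true(all(metrics_of(genorm(m)) >= 0))
    expect_true(all(metrics_of(delta_ct_stability(m)) >= 0))
    expect_true(all(metrics_of(normfinder(m)) >= 0))
    expect_true(all(metrics_of(bestkeeper(m)) >= 0))
  }
})
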