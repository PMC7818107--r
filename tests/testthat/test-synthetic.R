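test_that("build_ld_block handles trivial and template cases", {
  expect_equal(build_ld_block(1, seed = 1), matrix(1, 1, 1))
  expect_equal(build_ld_block(4, mode = "template", template = diag(10),
                              seed = 1), diag(4))
  expect_error(build_ld_block(12, mode = "template", template = diag(5)),
               "smaller")
  b <- build_ld_block(8, seed = 2)
  expect_true(isSymmetric(b))
  expect_equal(diag(b), rep(1, 8))
  # template mode extracts a principal submatrix
  set.seed(3)
  tmpl <- cov2cor(crossprod(matrix(rnorm(400), 20, 20)))
  sub <- build_ld_block(5, mode = "template", template = tmpl, seed = 4)
  expect_true(isSymmetric(sub))
  expect_true(all(sub %in% tmpl))
})

test_that("random off-diagonal magnitudes follow the configured bin frequencies", {
  set.seed(41)
  vals <- c()
  while (length(vals) < 1e4) {
    b <- build_ld_block(40)
    vals <- c(vals, abs(b[upper.tri(b)]))
  }
  vals <- vals[1:1e4]
  freq <- c(mean(vals < 0.2), mean(vals >= 0.2 & vals < 0.5),
            mean(vals >= 0.5))
  expect_equal(freq, c(0.70, 0.25, 0.05), tolerance = 0.02)
  expect_true(all(vals < 0.8))
})

test_that("assemble_target plants exactly the configured effects", {
  # null scenario: SNP-by-phenotype block identically zero
  scn0 <- scenario(n_snps_total = 10, n_effect_snps = 0, seed = 5)
  tg0 <- assemble_target(scn0)
  expect_true(all(tg0$sigma[1:10, 11:13] == 0))
  expect_equal(nrow(tg0$effect_map), 0)

  # planted entries equal effect_r exactly, one per effect SNP
  scn <- scenario(n_snps_total = 10, n_effect_snps = 4, effect_r = 0.2,
                  pheno_corr = 0.5, seed = 6)
  tg <- assemble_target(scn)
  expect_true(isSymmetric(tg$sigma))
  expect_equal(diag(tg$sigma), rep(1, 13))
  planted <- tg$sigma[cbind(tg$effect_map$snp, 10 + tg$effect_map$phenotype)]
  expect_equal(planted, rep(0.2, 4))
  expect_equal(nrow(tg$effect_map), 4)
  # everything else in the cross block is zero
  cross <- tg$sigma[1:10, 11:13]
  expect_equal(sum(cross != 0), 4)
  # phenotype block has the common correlation
  ph <- tg$sigma[11:13, 11:13]
  expect_equal(ph[upper.tri(ph)], rep(0.5, 3))

  # determinism under the scenario seed
  tg2 <- assemble_target(scn)
  expect_identical(tg$sigma, tg2$sigma)
  expect_identical(tg$effect_map, tg2$effect_map)

  # infeasible allocation errors
  scn_bad <- scenario(n_snps_total = 10, n_effect_snps = 6, n_genes = 2,
                      seed = 7)
  expect_error(assemble_target(scn_bad), "exceeds SNPs available")
})

test_that("effects spread across genes and multi-gene splits work", {
  scn <- scenario(n_snps_total = 9, n_effect_snps = 6, n_genes = 3,
                  spread_across_genes = TRUE, seed = 8)
  tg <- assemble_target(scn)
  expect_equal(tg$gene_of, rep(c("gene1", "gene2", "gene3"), each = 3))
  expect_gt(length(unique(tg$gene_of[tg$effect_map$snp])), 1)
})

test_that("nearest_pd is a fixed point on valid inputs and matches the oracle", {
  expect_equal(nearest_pd(diag(5)), diag(5))
  set.seed(9)
  valid <- cov2cor(crossprod(matrix(rnorm(64), 8, 8)) + diag(8))
  expect_lt(max(abs(nearest_pd(valid) - valid)), 1e-8)

  bad <- matrix(c(1, 0.9, 0.9,
                  0.9, 1, -0.9,
                  0.9, -0.9, 1), 3, 3)
  rep1 <- nearest_pd(bad, tol = 1e-10)
  expect_gte(min(eigen(rep1, symmetric = TRUE)$values), -1e-8)
  expect_equal(diag(rep1), rep(1, 3))
  # independent oracle: Higham algorithm from the Matrix package
  skip_if_not_installed("Matrix")
  oracle <- as.matrix(Matrix::nearPD(bad, corr = TRUE,
                                     eig.tol = 1e-12,
                                     conv.tol = 1e-12)$mat)
  expect_equal(rep1, oracle, tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(nearest_pd(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("repaired targets keep their eigenvalue floor", {
  for (seed in c(10, 11)) {
    scn <- scenario(n_snps_total = 15, n_effect_snps = 5, effect_r = 0.2,
                    seed = seed)
    tg <- assemble_target(scn)
    rep <- nearest_pd(tg$sigma, floor = 0.05)
    expect_gte(min(eigen(rep, symmetric = TRUE)$values), 0.05 - 1e-8)
    expect_equal(diag(rep), rep(1, 18))
  }
})

test_that("sampled data reproduce the target correlations at large n", {
  scn <- scenario(n_snps_total = 10, n_effect_snps = 3, effect_r = 0.2,
                  pheno_corr = 0.5, seed = 12)
  tg <- assemble_target(scn)
  sigma <- nearest_pd(tg$sigma, floor = 0.05)
  ds <- suppressWarnings(sample_dataset(tg, 1e5, seed = 13))
  emp <- cor(ds$values)
  expect_lt(max(abs(emp - sigma)), 0.02)
})

test_that("sample_dataset is deterministic, standardized, and validates n", {
  scn <- scenario(n_snps_total = 6, n_effect_snps = 2, seed = 14)
  tg <- assemble_target(scn)
  d1 <- suppressWarnings(sample_dataset(tg, 50, seed = 15))
  d2 <- suppressWarnings(sample_dataset(tg, 50, seed = 15))
  expect_identical(d1$values, d2$values)
  expect_lt(max(abs(colMeans(d1$values))), 1e-10)
  expect_lt(max(abs(apply(d1$values, 2, var) - 1)), 1e-10)
  expect_equal(unname(d1$block_of),
               c(rep("gene1", 6), rep("phenotypes", 3)))
  expect_error(sample_dataset(tg, 2), "at least 3")
})

test_that("discretized SNPs take dosage values with roughly HW frequencies", {
  scn <- scenario(n_snps_total = 4, n_effect_snps = 0, seed = 16)
  tg <- assemble_target(scn)
  # inspect dosages before standardization via the quantile construction
  set.seed(17)
  ds <- sample_dataset(tg, 2e4, seed = 17, discretize = TRUE, maf = 0.3)
  # standardized columns of a 0/1/2 variable take at most 3 distinct values
  expect_true(all(apply(ds$values[, 1:4], 2,
                        function(x) length(unique(x))) <= 3))
  # recover dosage frequencies from the standardized encoding
  z <- ds$values[, 1]
  lev <- sort(unique(z))
  counts <- table(z)[as.character(lev)]
  freqs <- as.numeric(counts) / length(z)
  expect_equal(freqs, c(0.49, 0.42, 0.09), tolerance = 0.02)
})
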