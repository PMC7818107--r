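test_that("single-indicator components reduce the path to a Pearson correlation", {
  set.seed(2)
  X <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("s1", "p1")))
  ds <- standardize(gsca_dataset(X, c(s1 = "g1", p1 = "phenotypes")))
  m <- gsca_model(list(g1 = "s1", pathway = "p1"),
                  cbind("g1", "pathway"))
  f <- fit_gsca(ds, m, seed = 1)
  expect_equal(f$paths$estimate, cor(ds$values[, 1], ds$values[, 2]),
               tolerance = 1e-8)
})

test_that("single gene-to-pathway |b| equals the first canonical correlation", {
  for (seed in 1:6) {
    ds <- make_dataset(n = 60, gene_sizes = c(g1 = 3), n_pheno = 2,
                       seed = seed, rho = 0.25)
    f <- fit_gsca(ds, pathway_model(ds), seed = seed, tol = 1e-10)
    snps <- ds$values[, ds$block_of != "phenotypes"]
    phen <- ds$values[, ds$block_of == "phenotypes"]
    expect_equal(abs(f$paths$estimate), cancor_oracle(snps, phen),
                 tolerance = 1e-6)
  }
})

test_that("fitted components have unit variance and a non-increasing criterion", {
  ds <- make_dataset(n = 80, gene_sizes = c(g1 = 4, g2 = 3), n_pheno = 3,
                     seed = 3)
  f <- fit_gsca(ds, pathway_model(ds), seed = 3)
  gam <- component_scores(f, ds)
  expect_lt(max(abs(apply(gam, 2, var) - 1)), 1e-8)
  expect_true(all(diff(f$criterion_trace) <= 1e-10))
})

test_that("the fit criterion matches direct recomputation from the data", {
  ds <- make_dataset(n = 50, gene_sizes = c(g1 = 3, g2 = 2), n_pheno = 2,
                     seed = 4)
  m <- pathway_model(ds)
  f <- fit_gsca(ds, m, seed = 4)
  expect_equal(f$criterion, gsca_criterion(ds, m, f$weights, f$paths),
               tolerance = 1e-10)
})

test_that("criterion is 0 for an exact structural fit and (N-1) for b = 0", {
  ds <- make_dataset(n = 40, gene_sizes = c(g1 = 2), n_pheno = 2, seed = 5)
  m <- pathway_model(ds)
  f <- fit_gsca(ds, m, seed = 5)
  # phenotype block duplicating the gene block with b = 1 -> exact fit
  ds_same <- ds
  v <- ds$values
  v[, 3] <- v[, 1]; v[, 4] <- v[, 2]
  ds_same$values <- v
  crit0 <- gsca_criterion(ds_same, m, list(g1 = f$weights$g1,
                                           pathway = f$weights$g1),
                          data.frame(source = "g1", sink = "pathway",
                                     estimate = 1))
  expect_equal(crit0, 0, tolerance = 1e-10)
  # b = 0 leaves the unit-variance sink unexplained: criterion (N-1)*1
  critb0 <- gsca_criterion(ds, m, f$weights,
                           data.frame(source = "g1", sink = "pathway",
                                      estimate = 0))
  expect_equal(critb0, (ds$n - 1), tolerance = 1e-8)
})

test_that("scale and sign invariances hold", {
  set.seed(6)
  n <- 70
  raw <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, c("s1", "s2", "s3", "p1", "p2")))
  blocks <- setNames(c("g1", "g1", "g1", "phenotypes", "phenotypes"),
                     colnames(raw))
  ds <- standardize(gsca_dataset(raw, blocks))
  f <- fit_gsca(ds, pathway_model(ds), seed = 1)

  # multiplying a raw indicator by a positive constant changes nothing
  raw2 <- raw
  raw2[, "s2"] <- raw2[, "s2"] * 7.3
  ds2 <- standardize(gsca_dataset(raw2, blocks))
  f2 <- fit_gsca(ds2, pathway_model(ds2), seed = 1)
  expect_equal(abs(f2$paths$estimate), abs(f$paths$estimate),
               tolerance = 1e-8)

  # flipping one component's weights flips b but not |b| or the criterion
  wflip <- f$weights
  wflip$g1 <- -wflip$g1
  pflip <- f$paths
  pflip$estimate <- -pflip$estimate
  expect_equal(gsca_criterion(ds, pathway_model(ds), wflip, pflip),
               f$criterion, tolerance = 1e-10)

  # reported weights follow the non-negative-sum convention
  expect_true(all(vapply(f$weights, sum, numeric(1)) >= 0))
})

test_that("ALS matches a general-purpose optimizer on small models", {
  # criterion parameterized over unnormalized weights, components rescaled
  for (seed in 1:4) {
    ds <- make_dataset(n = 50, gene_sizes = c(g1 = 2), n_pheno = 2,
                       seed = seed + 10, rho = 0.2)
    m <- pathway_model(ds)
    f <- fit_gsca(ds, m, seed = seed, tol = 1e-10)
    X <- ds$values[, 1:2]
    Y <- ds$values[, 3:4]
    obj <- function(par) {
      wx <- par[1:2]; wy <- par[3:4]
      gx <- drop(X %*% wx); gy <- drop(Y %*% wy)
      sx <- sd(gx); sy <- sd(gy)
      if (sx < 1e-8 || sy < 1e-8) return(1e6)
      gx <- gx / sx; gy <- gy / sy
      b <- sum(gx * gy) / sum(gx^2)
      sum((gy - b * gx)^2)
    }
    opt <- optim(c(1, 1, 1, 1), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    expect_equal(f$criterion, opt$value, tolerance = 1e-4)
    expect_lte(f$criterion, opt$value + 1e-6)
  }
})

test_that("exactly collinear indicators are rejected with guidance", {
  set.seed(8)
  X <- matrix(rnorm(120), 40, 3)
  X <- cbind(X[, 1], X, rnorm(40))
  colnames(X) <- c("s0", "s1", "s2", "s3", "p1")
  blocks <- setNames(c(rep("g1", 4), "phenotypes"), colnames(X))
  ds <- standardize(gsca_dataset(X, blocks))
  expect_error(fit_gsca(ds, pathway_model(ds)), "filter_snps")
})

test_that("permutation p-values respect the add-one lower bound and alpha split", {
  ds <- make_dataset(n = 50, gene_sizes = c(g1 = 2, g2 = 2), n_pheno = 2,
                     seed = 9)
  m <- pathway_model(ds)
  f <- fit_gsca(ds, m, seed = 9, n_starts = 2)
  pt <- permutation_test(ds, m, f, n_perm = 49, family_alpha = 0.05, seed = 1)
  expect_true(all(pt$table$p_value >= 1 / 50))
  expect_true(all(pt$table$p_value <= 1))
  expect_equal(pt$alpha_per_path, 0.05 / 2)
  # determinism under a fixed seed
  pt2 <- permutation_test(ds, m, f, n_perm = 49, family_alpha = 0.05, seed = 1)
  expect_identical(pt$table$p_value, pt2$table$p_value)
})

test_that("permutation p-values are approximately uniform under the null", {
  # independent blocks: fraction of p < 0.05 within binomial error of 0.05
  set.seed(10)
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(50 * 5), 50, 5,
                dimnames = list(NULL, c("s1", "s2", "s3", "p1", "p2")))
    ds <- standardize(gsca_dataset(
      X, setNames(c("g1", "g1", "g1", "phenotypes", "phenotypes"),
                  colnames(X))))
    m <- pathway_model(ds)
    f <- fit_gsca(ds, m, n_starts = 1)
    pt <- permutation_test(ds, m, f, n_perm = 99, seed = NULL)
    if (pt$table$p_value < 0.05) hits <- hits + 1L
  }
  # 3 * binomial SE around 0.05
  expect_lt(hits / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
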