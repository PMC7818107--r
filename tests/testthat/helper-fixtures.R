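# Shared fixtures and independent oracles, all built in code.

# A small standardized dataset with named gene blocks and phenotypes.
make_dataset <- function(n = 60, gene_sizes = c(g1 = 3), n_pheno = 2,
                         seed = 1, rho = 0.3) {
  set.seed(seed)
  k <- sum(gene_sizes) + n_pheno
  sigma <- diag(k) * (1 - rho) + rho
  X <- matrix(rnorm(n * k), n, k) %*% chol(sigma)
  snp_names <- unlist(lapply(names(gene_sizes), function(g)
    paste0(g, "_s", seq_len(gene_sizes[[g]]))))
  colnames(X) <- c(snp_names, paste0("p", seq_len(n_pheno)))
  block_of <- setNames(
    c(rep(names(gene_sizes), gene_sizes), rep("phenotypes", n_pheno)),
    colnames(X))
  standardize(gsca_dataset(X, block_of))
}

# Write a toy genotype/phenotype CSV + gene map; returns both paths.
make_toy_csv <- function(dir, values, genes, phenotypes) {
  csv <- file.path(dir, "toy.csv")
  write.csv(values, csv, row.names = FALSE)
  map <- file.path(dir, "map.yaml")
  yaml::write_yaml(list(genes = genes, phenotypes = phenotypes), map)
  list(csv = csv, map = map)
}

# First canonical correlation between two blocks (oracle for single-path |b|).
cancor_oracle <- function(X, Y) stats::cancor(X, Y)$cor[1]

# Brute-force Benjamini-Hochberg step-up.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Closed-form simple OLS slope/t/p oracle for one pair.
ols_oracle <- function(x, y) {
  n <- length(x)
  fit <- lm(y ~ x)
  s <- summary(fit)$coefficients["x", ]
  list(slope = unname(s["Estimate"]), t = unname(s["t value"]),
       p = unname(s["Pr(>|t|)"]))
}

# Greedy keep-first LD pruning by brute force over all pairs.
prune_bruteforce <- function(X, ld_max, metric = "r2") {
  nm <- colnames(X)
  keep <- character(0)
  for (s in nm) {
    ok <- TRUE
    for (k in keep) {
      r <- cor(X[, s], X[, k])
      v <- if (metric == "r2") r^2 else abs(r)
      if (v >= ld_max) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, s)
  }
  keep
}
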