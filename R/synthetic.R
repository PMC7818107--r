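#' Define a simulation scenario
#'
#' A scenario is one combination of the factors varied in the power study:
#' total number of SNPs, number of SNPs carrying an effect, number of genes,
#' sample size, phenotype intercorrelation, and effect size (the correlation
#' between an effect SNP and its phenotype). Effect sizes of 0.1, 0.15 and
#' 0.2 are the canonical grid values; any correlation in (-1, 1) is
#' accepted.
#'
#' @param n_snps_total total SNPs across all genes.
#' @param n_effect_snps SNPs with a planted phenotype correlation (0 gives a
#'   null scenario).
#' @param n_genes number of gene blocks; SNPs are split as evenly as
#'   possible across genes.
#' @param n_individuals sample size per simulated dataset.
#' @param pheno_corr common correlation among the three phenotypes, in
#'   `[0, 1)`.
#' @param effect_r planted SNP-phenotype correlation.
#' @param ld_mode `"random"` (draw an LD-like correlation pattern) or
#'   `"template"` (sample a principal submatrix of `template_corr`).
#' @param template_corr SNP-SNP correlation matrix to sample from when
#'   `ld_mode = "template"`.
#' @param effect_allocation `"one_phenotype_each"` (each effect SNP is
#'   correlated with one uniformly chosen phenotype, the default) or
#'   `"all_phenotypes"`.
#' @param spread_across_genes if `FALSE` (default) all effect SNPs lie in
#'   the first gene (effects clustered within a gene); if `TRUE` they are
#'   drawn from all genes.
#' @param seed scenario-level integer seed.
#' @return An object of class `gsca_scenario`.
#' @export
scenario <- function(n_snps_total = 20, n_effect_snps = 0, n_genes = 1,
                     n_individuals = 100, pheno_corr = 0.5, effect_r = 0.2,
                     ld_mode = c("random", "template"), template_corr = NULL,
                     effect_allocation = c("one_phenotype_each",
                                           "all_phenotypes"),
                     spread_across_genes = FALSE, seed = 1L) {
  ld_mode <- match.arg(ld_mode)
  effect_allocation <- match.arg(effect_allocation)
  stopifnot(n_snps_total >= 1, n_effect_snps >= 0,
            n_effect_snps <= n_snps_total,
            n_genes >= 1, n_genes <= n_snps_total,
            pheno_corr >= 0, pheno_corr < 1,
            effect_r > -1, effect_r < 1)
  if (ld_mode == "template" && is.null(template_corr))
    stop("template_corr is required when ld_mode = 'template'")
  structure(
    list(n_snps_total = as.integer(n_snps_total),
         n_effect_snps = as.integer(n_effect_snps),
         n_genes = as.integer(n_genes),
         n_individuals = as.integer(n_individuals),
         pheno_corr = pheno_corr, effect_r = effect_r,
         ld_mode = ld_mode, template_corr = template_corr,
         effect_allocation = effect_allocation,
         spread_across_genes = isTRUE(spread_across_genes),
         seed = as.integer(seed)),
    class = "gsca_scenario")
}

#' Draw one LD-like SNP correlation block
#'
#' `"random"` mode draws off-diagonal magnitudes from a binned frequency
#' distribution (with random signs) chosen to give a sparse-LD look: by
#' default 70% of pairs in `[0, 0.2)`, 25% in `[0.2, 0.5)` and 5% in
#' `[0.5, 0.8)`, uniform within bin. `"template"` mode samples a principal
#' submatrix of a supplied correlation matrix at random SNP indices, so the
#' block inherits the empirical LD of a real genotype panel.
#'
#' @param n_snps block size.
#' @param mode `"random"` or `"template"`.
#' @param template correlation matrix (required for `"template"` mode, at
#'   least `n_snps` columns).
#' @param mag_breaks bin edges of the magnitude distribution (random mode).
#' @param mag_probs bin probabilities, one fewer than `mag_breaks`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Symmetric unit-diagonal `n_snps` x `n_snps` matrix (not
#'   necessarily positive definite; see [nearest_pd()]).
#' @export
build_ld_block <- function(n_snps, mode = c("random", "template"),
                           template = NULL,
                           mag_breaks = c(0, 0.2, 0.5, 0.8),
                           mag_probs = c(0.70, 0.25, 0.05),
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_snps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "template") {
    if (is.null(template)) stop("template required for mode = 'template'")
    if (nrow(template) < n_snps)
      stop("template (", nrow(template), " SNPs) smaller than n_snps = ",
           n_snps)
    ix <- sort(sample.int(nrow(template), n_snps))
    return(unname(as.matrix(template)[ix, ix, drop = FALSE]))
  }
  stopifnot(length(mag_probs) == length(mag_breaks) - 1,
            abs(sum(mag_probs) - 1) < 1e-8)
  m <- diag(n_snps)
  if (n_snps > 1) {
    n_off <- n_snps * (n_snps - 1) / 2
    bin <- sample.int(length(mag_probs), n_off, replace = TRUE,
                      prob = mag_probs)
    mag <- stats::runif(n_off, mag_breaks[bin], mag_breaks[bin + 1])
    val <- mag * sample(c(-1, 1), n_off, replace = TRUE)
    m[upper.tri(m)] <- val
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  m
}

#' Assemble the target correlation matrix of a scenario
#'
#' Builds the joint SNP + phenotype correlation target: one LD block per
#' gene on the diagonal (genes mutually uncorrelated), a 3-phenotype block
#' with common off-diagonal `pheno_corr`, and a SNP-by-phenotype block that
#' is zero except for the planted effects — `n_effect_snps` SNPs drawn
#' uniformly without replacement (from the first gene unless
#' `spread_across_genes`) each given correlation `effect_r` with its
#' allocated phenotype(s). Data are simulated from this correlation
#' structure directly, with no further model structure.
#'
#' @param scn a `gsca_scenario`.
#' @param seed seed; defaults to the scenario seed. Pass `NULL` to use the
#'   current RNG stream (as the replicate engine does).
#' @return An object of class `gsca_target`: `sigma` (the
#'   `(n_snps_total + 3)`-square matrix, before positive-definiteness
#'   repair), `effect_map` (data.frame of snp/phenotype index pairs),
#'   `gene_of` (gene label per SNP), `snp_names`, `pheno_names`.
#' @export
assemble_target <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "gsca_scenario"))
  if (!is.null(seed)) set.seed(seed)
  J <- scn$n_snps_total
  sizes <- rep(J %/% scn$n_genes, scn$n_genes)
  extra <- J %% scn$n_genes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  gene_of <- rep(paste0("gene", seq_len(scn$n_genes)), times = sizes)

  K <- J + 3L
  sigma <- diag(K)
  at <- 0L
  for (g in seq_len(scn$n_genes)) {
    ix <- at + seq_len(sizes[g])
    sigma[ix, ix] <- build_ld_block(sizes[g], scn$ld_mode,
                                    template = scn$template_corr)
    at <- at + sizes[g]
  }
  ph <- J + 1:3
  sigma[ph, ph] <- matrix(scn$pheno_corr, 3, 3)
  diag(sigma)[ph] <- 1

  effect_map <- data.frame(snp = integer(0), phenotype = integer(0))
  if (scn$n_effect_snps > 0) {
    pool <- if (scn$spread_across_genes) seq_len(J)
            else which(gene_of == "gene1")
    if (scn$n_effect_snps > length(pool))
      stop("n_effect_snps (", scn$n_effect_snps,
           ") exceeds SNPs available in the causal gene (", length(pool), ")")
    snps <- sort(sample(pool, scn$n_effect_snps))
    if (scn$effect_allocation == "one_phenotype_each") {
      phen <- sample.int(3, scn$n_effect_snps, replace = TRUE)
      effect_map <- data.frame(snp = snps, phenotype = phen)
    } else {
      effect_map <- data.frame(snp = rep(snps, each = 3),
                               phenotype = rep(1:3, length(snps)))
    }
    for (r in seq_len(nrow(effect_map))) {
      i <- effect_map$snp[r]; j <- J + effect_map$phenotype[r]
      sigma[i, j] <- sigma[j, i] <- scn$effect_r
    }
  }

  structure(
    list(sigma = sigma, effect_map = effect_map, gene_of = gene_of,
         snp_names = paste0("snp", seq_len(J)),
         pheno_names = paste0("pheno", 1:3)),
    class = "gsca_target")
}

#' Nearest correlation matrix by alternating projections
#'
#' Repairs a symmetric unit-diagonal matrix that is not positive
#' semi-definite (assembled targets need not be) by alternating projections:
#' eigenvalue clipping onto the PSD cone followed by unit-diagonal
#' restoration, iterated until the smallest eigenvalue of the unit-diagonal
#' iterate is above `-tol`. An input that is already a valid correlation
#' matrix is returned unchanged.
#'
#' @param sigma symmetric matrix.
#' @param tol eigenvalue tolerance; default 1e-8.
#' @param max_iter projection cap; default 1000.
#' @param floor eigenvalue clipping level. The default (`tol`) projects onto
#'   the PSD cone, leaving already-valid inputs unchanged. A positive floor
#'   (e.g. 0.05, as used when repairing simulation targets) returns the
#'   nearest correlation matrix whose smallest eigenvalue is at least
#'   `floor - tol`, keeping sampled targets well-conditioned instead of
#'   sitting on the PSD boundary.
#' @return Symmetric unit-diagonal matrix with smallest eigenvalue
#'   `>= floor - tol`.
#' @export
nearest_pd <- function(sigma, tol = 1e-8, max_iter = 1000, floor = tol) {
  if (!isSymmetric(sigma, tol = 1e-8))
    stop("input must be symmetric")
  s <- (sigma + t(sigma)) / 2
  for (it in seq_len(max_iter)) {
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) >= floor - tol && max(abs(diag(s) - 1)) <= tol)
      return(s)
    s <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    diag(s) <- 1
    s <- (s + t(s)) / 2
  }
  stop("nearest_pd did not converge in ", max_iter, " iterations")
}

#' Sample a dataset from a correlation target
#'
#' Draws `n` multivariate-normal rows with the (repaired) target
#' correlation, labels columns with the scenario's gene split, and
#' standardizes every column. SNP columns may optionally be discretized to
#' 0/1/2 additive dosages by Hardy-Weinberg quantile thresholds from `maf`
#' before standardization; the default keeps them continuous, matching a
#' simulation defined directly on correlations.
#'
#' An assembled target whose smallest eigenvalue is below `eig_floor` is
#' first repaired with `nearest_pd(..., floor = eig_floor)`: sampling from a
#' target on (or numerically past) the PSD boundary would make the
#' phenotypes near-exact linear combinations of the SNPs, a degeneracy of
#' the matrix rather than a property of the planted effects. A warning is
#' issued if the repair moves any planted effect entry by more than 0.02.
#'
#' @param target a `gsca_target`.
#' @param n number of individuals; must be at least 3.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param discretize discretize SNPs to genotype dosages? Default `FALSE`.
#' @param maf per-SNP minor allele frequencies, required when
#'   `discretize = TRUE` (recycled if length 1).
#' @param eig_floor minimum eigenvalue enforced on the sampling target;
#'   default 0.05.
#' @param warn_drift warn when the repair moves a planted effect entry by
#'   more than 0.02. The replicate engines pass `FALSE` and report the
#'   maximum drift once per scenario instead; the drift is always available
#'   as attribute `planted_drift` of the result.
#' @return A standardized `gsca_dataset`.
#' @export
sample_dataset <- function(target, n, seed = NULL, discretize = FALSE,
                           maf = NULL, eig_floor = 0.05, warn_drift = TRUE) {
  stopifnot(inherits(target, "gsca_target"))
  if (n < 3) stop("n must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  sigma <- target$sigma
  drift <- 0
  e <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < eig_floor - 1e-8) {
    sigma <- nearest_pd(sigma, floor = eig_floor)
    if (nrow(target$effect_map)) {
      J <- length(target$snp_names)
      planted <- cbind(target$effect_map$snp, J + target$effect_map$phenotype)
      drift <- max(abs(sigma[planted] - target$sigma[planted]))
      if (warn_drift && drift > 0.02)
        warning("PD repair moved a planted effect entry by ",
                format(drift, digits = 3))
    }
  }
  R <- tryCatch(chol(sigma),
                error = function(e) chol(sigma + 1e-8 * diag(nrow(sigma))))
  K <- nrow(sigma)
  Z <- matrix(stats::rnorm(n * K), n, K) %*% R
  colnames(Z) <- c(target$snp_names, target$pheno_names)

  J <- length(target$snp_names)
  if (discretize) {
    if (is.null(maf)) stop("maf required when discretize = TRUE")
    maf <- rep_len(maf, J)
    if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
    for (j in seq_len(J)) {
      q0 <- stats::qnorm((1 - maf[j])^2)
      q1 <- stats::qnorm((1 - maf[j])^2 + 2 * maf[j] * (1 - maf[j]))
      Z[, j] <- as.numeric(Z[, j] > q0) + as.numeric(Z[, j] > q1)
    }
  }

  block_of <- stats::setNames(
    c(target$gene_of, rep("phenotypes", 3)), colnames(Z))
  out <- standardize(gsca_dataset(Z, block_of))
  attr(out, "planted_drift") <- drift
  out
}
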