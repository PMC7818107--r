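# Monte-Carlo engine: replicate scenarios, apply the component-based fit
# and the regression comparator, estimate power / false-positive rates.

.rep_seeds <- function(scn, n_replicates) {
  # one deterministic stream per replicate, derived from the scenario seed
  set.seed(scn$seed)
  sample.int(2147483646L, n_replicates)
}

.power_row <- function(scn, method, n_positive, n_replicates, alpha_used) {
  data.frame(
    n_snps_total = scn$n_snps_total,
    n_effect_snps = scn$n_effect_snps,
    n_genes = scn$n_genes,
    effect_r = scn$effect_r,
    power = n_positive / n_replicates,
    n_replicates = n_replicates,
    n_individuals = scn$n_individuals,
    pheno_corr = scn$pheno_corr,
    ld_mode = scn$ld_mode,
    method = method,
    alpha_used = alpha_used,
    n_positive = n_positive,
    seed = scn$seed,
    stringsAsFactors = FALSE)
}

#' Estimate power of the component-based analysis for one scenario
#'
#' For each replicate: draw a fresh correlation target (LD pattern and
#' effect allocation are re-drawn per replicate), sample a dataset, fit the
#' genes-to-pathway model, and permutation-test the paths at the per-path
#' alpha (`family_alpha` divided by the number of paths). A replicate is
#' positive when a causal gene's path is significant — under a null
#' scenario, when any path is — so the returned proportion is the power, or
#' the false-positive rate when `n_effect_snps = 0`.
#'
#' Both the observed fit and the permutation refits use a single
#' equal-weight start, keeping the observed and permuted statistics
#' exchangeable under the null.
#'
#' @param scn a `gsca_scenario`.
#' @param n_replicates Monte-Carlo replicates; default 100.
#' @param n_perm permutations per replicate; default 200.
#' @param family_alpha family-wise alpha; default 0.05.
#' @param n_starts ALS starts per fit; default 1 (see Details).
#' @return One-row data.frame (a power row): the flattened scenario plus
#'   `method = "gsca"`, `n_positive`, `power` and `alpha_used`.
#' @export
run_scenario_gsca <- function(scn, n_replicates = 100, n_perm = 200,
                              family_alpha = 0.05, n_starts = 1) {
  stopifnot(inherits(scn, "gsca_scenario"), n_replicates >= 1)
  seeds <- .rep_seeds(scn, n_replicates)
  n_positive <- 0L
  alpha_pp <- NA_real_
  max_drift <- 0
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      set.seed(seeds[r])
      target <- assemble_target(scn, seed = NULL)
      ds <- sample_dataset(target, scn$n_individuals, seed = NULL,
                           warn_drift = FALSE)
      max_drift <- max(max_drift, attr(ds, "planted_drift"))
      model <- pathway_model(ds)
      fit <- fit_gsca(ds, model, n_starts = n_starts)
      pt <- permutation_test(ds, model, fit, n_perm = n_perm,
                             family_alpha = family_alpha, seed = NULL)
      causal <- if (nrow(target$effect_map) == 0) {
        unique(pt$table$source)                       # null: any path counts
      } else {
        unique(target$gene_of[target$effect_map$snp]) # genes with an effect
      }
      list(pos = any(pt$table$significant[pt$table$source %in% causal]),
           alpha = pt$alpha_per_path)
    }, error = function(e) {
      stop("replicate ", r, " of scenario (J=", scn$n_snps_total,
           ", effects=", scn$n_effect_snps, ", r=", scn$effect_r,
           ", N=", scn$n_individuals, ") failed: ", conditionMessage(e))
    })
    alpha_pp <- res$alpha
    if (res$pos) n_positive <- n_positive + 1L
  }
  if (max_drift > 0.02)
    message(sprintf(
      "PD repair moved planted effect entries by up to %.3f in this scenario",
      max_drift))
  .power_row(scn, "gsca", n_positive, n_replicates, alpha_pp)
}

#' Estimate power of the per-SNP regression comparator for one scenario
#'
#' For each replicate: draw a dataset as in [run_scenario_gsca()], run every
#' SNP-by-phenotype simple regression, adjust p-values jointly across all
#' tests, and score the replicate positive if any adjusted p-value falls
#' below `family_alpha`.
#'
#' @param scn a `gsca_scenario`.
#' @param n_replicates Monte-Carlo replicates; default 1000 (the comparator
#'   is much cheaper than the permutation-tested fit).
#' @param family_alpha family-wise / FDR level; default 0.05.
#' @param method multiple-testing correction; default `"bh"`.
#' @return One-row power data.frame with `method = "univariate"`.
#' @export
run_scenario_univariate <- function(scn, n_replicates = 1000,
                                    family_alpha = 0.05, method = "bh") {
  stopifnot(inherits(scn, "gsca_scenario"), n_replicates >= 1)
  seeds <- .rep_seeds(scn, n_replicates)
  n_positive <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    target <- assemble_target(scn, seed = NULL)
    ds <- sample_dataset(target, scn$n_individuals, seed = NULL,
                         warn_drift = FALSE)
    if (any_significant(regress_all(ds), family_alpha, method))
      n_positive <- n_positive + 1L
  }
  .power_row(scn, "univariate", n_positive, n_replicates, family_alpha)
}

#' The default simulation grid
#'
#' Enumerates the 54 factor combinations used by the power study: total
#' SNPs {20, 40} x effect size {0.1, 0.15, 0.2} x phenotype correlation
#' {0, 0.25, 0.5} x effect SNPs {0, 5, 10}, at N = 100 individuals in one
#' gene.
#'
#' @param n_individuals sample size; default 100.
#' @param base_seed scenario seeds are `base_seed + 1 ... base_seed + 54`.
#' @return List of `gsca_scenario` objects.
#' @export
scenario_grid <- function(n_individuals = 100, base_seed = 1000L) {
  g <- expand.grid(n_snps_total = c(20L, 40L),
                   effect_r = c(0.1, 0.15, 0.2),
                   pheno_corr = c(0, 0.25, 0.5),
                   n_effect_snps = c(0L, 5L, 10L))
  lapply(seq_len(nrow(g)), function(i)
    scenario(n_snps_total = g$n_snps_total[i],
             n_effect_snps = g$n_effect_snps[i],
             n_individuals = n_individuals,
             pheno_corr = g$pheno_corr[i],
             effect_r = g$effect_r[i],
             seed = base_seed + i))
}

#' Run a scenario grid for one or both methods
#'
#' Deterministic given the scenario seeds; with a `checkpoint` CSV the run
#' is resumable — completed scenario-method rows are read back and skipped.
#'
#' @param scenarios list of `gsca_scenario` objects (distinct parameter
#'   combinations).
#' @param methods subset of `c("gsca", "univariate")`.
#' @param n_replicates_gsca,n_replicates_univariate replicates per method.
#' @param n_perm permutations inside each replicate's fit.
#' @param family_alpha family-wise alpha.
#' @param checkpoint optional CSV path; rows are appended as scenarios
#'   finish and reused on rerun.
#' @return data.frame of power rows, one per scenario-method pair.
#' @export
run_grid <- function(scenarios, methods = c("gsca", "univariate"),
                     n_replicates_gsca = 100, n_replicates_univariate = 1000,
                     n_perm = 200, family_alpha = 0.05, checkpoint = NULL) {
  stopifnot(length(scenarios) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  key <- function(scn, method) paste(
    scn$n_snps_total, scn$n_effect_snps, scn$n_genes, scn$n_individuals,
    scn$pheno_corr, scn$effect_r, scn$ld_mode, scn$seed, method, sep = "|")
  ids <- vapply(scenarios, key, character(1), method = "")
  if (anyDuplicated(ids))
    stop("duplicate scenarios in grid (identical parameters and seed)")

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint))
    done <- read_results(checkpoint)
  done_keys <- if (is.null(done) || !nrow(done)) character(0) else
    paste(done$n_snps_total, done$n_effect_snps, done$n_genes,
          done$n_individuals, done$pheno_corr, done$effect_r, done$ld_mode,
          done$seed, done$method, sep = "|")

  rows <- if (!is.null(done)) split(done, seq_len(nrow(done))) else list()
  for (scn in scenarios) {
    for (m in methods) {
      if (key(scn, m) %in% done_keys) next
      row <- if (m == "gsca")
        run_scenario_gsca(scn, n_replicates_gsca, n_perm, family_alpha)
      else
        run_scenario_univariate(scn, n_replicates_univariate, family_alpha)
      rows[[length(rows) + 1]] <- row
      if (!is.null(checkpoint))
        write_results(do.call(rbind, rows), checkpoint)
      message(sprintf(
        "[%s] J=%d effects=%d r=%.2f rho=%.2f N=%d -> power %.3f",
        m, scn$n_snps_total, scn$n_effect_snps, scn$effect_r,
        scn$pheno_corr, scn$n_individuals, row$power))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.power_cols <- c("n_snps_total", "n_effect_snps", "n_genes", "effect_r",
                 "power", "n_replicates", "n_individuals", "pheno_corr",
                 "ld_mode", "method", "alpha_used", "n_positive", "seed")

#' Write power rows as CSV
#'
#' Columns follow the result-file schema of the study output (total SNPs,
#' effect SNPs, genes, effect size, power estimate, replicates, subjects,
#' phenotype correlation) plus `method` and `alpha_used`; stable order. An
#' empty input writes a header-only file.
#'
#' @param rows data.frame of power rows (possibly zero rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (is.null(rows) || !nrow(rows)) {
    rows <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.power_cols))), .power_cols)
  }
  utils::write.csv(rows[, .power_cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read power rows written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame with the power-row columns.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ld_mode = "character",
                                 method = "character"))
}
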