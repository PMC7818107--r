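#' Per-SNP, per-phenotype linear regression
#'
#' The conventional comparator to the component-based analysis: a simple
#' linear regression of every phenotype on every SNP dosage (additive
#' coding, quantitative-trait model, no covariates), with a two-sided t test
#' on the slope (N - 2 degrees of freedom).
#'
#' @param dataset a `gsca_dataset`; SNP blocks are every block except
#'   `"phenotypes"`.
#' @return An `assoc_table` data.frame with one row per SNP-phenotype pair:
#'   `snp`, `phenotype`, `slope`, `statistic`, `p_value`.
#' @export
regress_all <- function(dataset) {
  stopifnot(inherits(dataset, "gsca_dataset"))
  if (dataset$n < 3) stop("need at least 3 individuals")
  snp_cols <- dataset$indicator_names[dataset$block_of != "phenotypes"]
  ph_cols <- dataset$indicator_names[dataset$block_of == "phenotypes"]
  if (!length(snp_cols) || !length(ph_cols))
    stop("dataset must contain both SNP and phenotype columns")
  G <- dataset$values[, snp_cols, drop = FALSE]
  Y <- dataset$values[, ph_cols, drop = FALSE]
  sg <- apply(G, 2, stats::sd)
  if (any(sg <= 0))
    stop("zero-variance SNP(s): ",
         paste(snp_cols[sg <= 0], collapse = ", "),
         "; filter them upstream")
  sy <- apply(Y, 2, stats::sd)

  # closed-form simple OLS per pair, via the correlation matrix
  n <- dataset$n
  r <- stats::cor(G, Y)
  slope <- r * rep(sy, each = length(snp_cols)) / sg
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)

  out <- data.frame(
    snp = rep(snp_cols, times = length(ph_cols)),
    phenotype = rep(ph_cols, each = length(snp_cols)),
    slope = as.numeric(slope),
    statistic = as.numeric(tt),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] offering the standard corrections
#' plus Sidak (`1 - (1 - p)^m`), which `p.adjust` does not provide.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param method one of `"bh"` (Benjamini-Hochberg, the default), `"by"`
#'   (Benjamini-Yekutieli), `"bonferroni"`, `"holm"`, `"sidak"`.
#' @return Adjusted p-values in `[0, 1]`, same length and order as the
#'   input.
#' @export
adjust_pvalues <- function(pvalues,
                           method = c("bh", "by", "bonferroni", "holm",
                                      "sidak")) {
  method <- match.arg(method)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  switch(method,
    bh = stats::p.adjust(pvalues, "BH"),
    by = stats::p.adjust(pvalues, "BY"),
    bonferroni = stats::p.adjust(pvalues, "bonferroni"),
    holm = stats::p.adjust(pvalues, "holm"),
    sidak = pmin(1, 1 - (1 - pvalues)^length(pvalues)))
}

#' Trial-level decision: any significant association?
#'
#' Adjusts p-values jointly across all SNP-by-phenotype tests in the table
#' and returns `TRUE` if any adjusted p-value falls below the family alpha —
#' the decision rule used to score a simulated trial of the regression
#' comparator as positive.
#'
#' @param table an `assoc_table` from [regress_all()].
#' @param family_alpha family-wise / FDR level; default 0.05.
#' @param method correction method passed to [adjust_pvalues()]; default
#'   `"bh"`.
#' @return Logical flag.
#' @export
any_significant <- function(table, family_alpha = 0.05, method = "bh") {
  if (!nrow(table)) stop("empty association table")
  adj <- adjust_pvalues(table$p_value, method)
  any(adj < family_alpha)
}

#' Write an association table as CSV
#'
#' @param table an `assoc_table`.
#' @param path output path.
#' @param method adjustment method for the `p_adjusted` column; default
#'   `"bh"`.
#' @return `path`, invisibly.
#' @export
write_assoc_table <- function(table, path, method = "bh") {
  out <- table
  out$p_adjusted <- adjust_pvalues(table$p_value, method)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
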