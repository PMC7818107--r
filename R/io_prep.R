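#' Construct a gene/phenotype dataset
#'
#' A `gsca_dataset` is the common container of the package: a numeric matrix
#' of individuals by indicators (SNP additive dosages and quantitative
#' phenotypes) together with the block each indicator belongs to (a gene
#' name, or `"phenotypes"` for the outcome block).
#'
#' @param values numeric matrix, one row per individual, one column per
#'   indicator; column names are the indicator names.
#' @param block_of named character vector mapping every column of `values`
#'   to its block label.
#' @param standardized logical; has each column already been centred and
#'   scaled to unit variance?
#' @return An object of class `gsca_dataset` with elements `values`,
#'   `indicator_names`, `block_of`, `n` and `standardized`.
#' @export
gsca_dataset <- function(values, block_of, standardized = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must have column names (indicator names)")
  storage.mode(values) <- "double"
  nm <- colnames(values)
  missing_blocks <- setdiff(nm, names(block_of))
  if (length(missing_blocks))
    stop("no block assigned to indicator(s): ",
         paste(missing_blocks, collapse = ", "))
  if (anyNA(values))
    stop("'values' contains missing entries; use load_dataset() for listwise deletion")
  structure(
    list(values = values,
         indicator_names = nm,
         block_of = block_of[nm],
         n = nrow(values),
         standardized = isTRUE(standardized)),
    class = "gsca_dataset")
}

#' @export
print.gsca_dataset <- function(x, ...) {
  blocks <- table(x$block_of)
  cat("gsca_dataset:", x$n, "individuals,",
      length(x$indicator_names), "indicators\n")
  cat("  blocks:",
      paste(sprintf("%s (%d)", names(blocks), blocks), collapse = ", "), "\n")
  cat("  standardized:", x$standardized, "\n")
  invisible(x)
}

#' Read a gene-to-SNP mapping configuration
#'
#' The mapping file (YAML or JSON) has a `genes` section assigning SNP column
#' names to genes and a `phenotypes` list of phenotype column names:
#' \preformatted{
#' genes:
#'   CNTNAP2: [rs1, rs2]
#'   FOXP2:   [rs3]
#' phenotypes: [ELS, RLS, NWR]
#' }
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or a list already in
#'   that shape.
#' @return list with elements `genes` (named list of character vectors) and
#'   `phenotypes` (character vector).
#' @export
load_gene_map <- function(path) {
  map <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(map$genes) || is.null(map$phenotypes))
    stop("gene map must contain 'genes' and 'phenotypes' entries")
  map$genes <- lapply(map$genes, as.character)
  map$phenotypes <- as.character(map$phenotypes)
  map
}

#' Load a genotype + phenotype table
#'
#' Reads a CSV with one row per individual and columns for SNP dosages and
#' phenotypes, assigns each column to its block from the gene map, and
#' applies listwise deletion: any row with a missing value in a mapped column
#' is dropped and the number of dropped rows is reported.
#'
#' @param csv path to the CSV file (header row, one individual per row).
#' @param gene_map a gene map as returned by [load_gene_map()], or a path to
#'   one.
#' @param id_cols columns to ignore (identifiers); default `"id"` if present.
#' @return A `gsca_dataset` (unstandardized) with attribute `n_dropped`, the
#'   number of rows removed by listwise deletion.
#' @export
load_dataset <- function(csv, gene_map, id_cols = "id") {
  map <- load_gene_map(gene_map)
  df <- utils::read.csv(csv, check.names = FALSE)
  df <- df[, !(names(df) %in% id_cols), drop = FALSE]

  block_of <- c(
    unlist(lapply(names(map$genes), function(g) {
      stats::setNames(rep(g, length(map$genes[[g]])), map$genes[[g]])
    })),
    stats::setNames(rep("phenotypes", length(map$phenotypes)), map$phenotypes))

  absent <- setdiff(names(block_of), names(df))
  if (length(absent))
    stop("mapped column(s) absent from CSV: ", paste(absent, collapse = ", "))
  unmapped <- setdiff(names(df), names(block_of))
  if (length(unmapped))
    stop("unmapped column(s) in CSV: ", paste(unmapped, collapse = ", "))

  df <- df[, names(block_of), drop = FALSE]
  all_na <- vapply(df, function(x) all(is.na(x)), logical(1))
  if (any(all_na))
    stop("column(s) entirely missing: ",
         paste(names(df)[all_na], collapse = ", "))

  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("load_dataset: dropped ", n_dropped,
            " row(s) with missing values (listwise deletion)")
  values <- as.matrix(df[keep, , drop = FALSE])
  ds <- gsca_dataset(values, block_of)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Standardize every indicator column
#'
#' Centres each column to mean zero and scales it to unit sample variance
#' (denominator N-1). Components in the structural model are
#' variance-normalized weighted sums, so all model fitting operates on
#' standardized data.
#'
#' @param dataset a `gsca_dataset`.
#' @return The dataset with standardized columns and `standardized = TRUE`.
#' @export
standardize <- function(dataset) {
  stopifnot(inherits(dataset, "gsca_dataset"))
  v <- dataset$values
  sds <- apply(v, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  v <- scale(v, center = TRUE, scale = sds)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  dataset$values <- v
  dataset$standardized <- TRUE
  dataset
}

#' Filter SNPs by minor allele frequency and pairwise LD
#'
#' Applies the two candidate-SNP filters used before model fitting: SNPs with
#' minor allele frequency at or below `maf_min` are removed, then remaining
#' SNPs are greedily pruned for linkage disequilibrium — scanning in column
#' order and keeping the first member of any pair whose pairwise LD reaches
#' `ld_max`. Perfectly correlated SNP pairs are always pruned (the structural
#' fit has no mechanism to deal with exact collinearity). Phenotype columns
#' are never touched.
#'
#' @param dataset a `gsca_dataset`.
#' @param maf optional named vector of minor allele frequencies per SNP; when
#'   `NULL` they are computed from the dosages as `mean(dosage)/2`, folded
#'   onto `[0, 0.5]`.
#' @param maf_min MAF threshold; SNPs with MAF `<= maf_min` are dropped.
#'   Default 0.03.
#' @param ld_max LD pruning threshold in `(0, 1]`; default 0.8.
#' @param ld_metric `"r2"` (squared Pearson correlation, the default) or
#'   `"abs"` (absolute correlation).
#' @return The filtered `gsca_dataset`, with attributes `snps_removed_maf`
#'   and `snps_removed_ld` listing the removed SNP names.
#' @export
filter_snps <- function(dataset, maf = NULL, maf_min = 0.03, ld_max = 0.8,
                        ld_metric = c("r2", "abs")) {
  stopifnot(inherits(dataset, "gsca_dataset"))
  ld_metric <- match.arg(ld_metric)
  stopifnot(ld_max > 0, ld_max <= 1)
  snp_cols <- dataset$indicator_names[dataset$block_of != "phenotypes"]

  if (is.null(maf)) {
    maf <- colMeans(dataset$values[, snp_cols, drop = FALSE]) / 2
    maf <- pmin(maf, 1 - maf)
  } else {
    absent <- setdiff(snp_cols, names(maf))
    if (length(absent))
      stop("no MAF supplied for SNP(s): ", paste(absent, collapse = ", "))
    maf <- maf[snp_cols]
    if (any(maf < 0 | maf > 0.5))
      stop("MAF values must lie in [0, 0.5]")
  }

  drop_maf <- snp_cols[maf[snp_cols] <= maf_min]
  kept <- setdiff(snp_cols, drop_maf)
  if (!length(kept))
    stop("all SNPs removed by the MAF filter")

  # greedy keep-first pruning in input column order
  r <- stats::cor(dataset$values[, kept, drop = FALSE])
  ld <- if (ld_metric == "r2") r^2 else abs(r)
  survivors <- character(0)
  drop_ld <- character(0)
  for (s in kept) {
    high <- length(survivors) && any(ld[s, survivors] >= ld_max)
    if (high) drop_ld <- c(drop_ld, s) else survivors <- c(survivors, s)
  }
  if (!length(survivors))
    stop("all SNPs removed by LD pruning")

  keep_cols <- dataset$indicator_names[
    dataset$indicator_names %in% c(survivors,
      dataset$indicator_names[dataset$block_of == "phenotypes"])]
  dataset$values <- dataset$values[, keep_cols, drop = FALSE]
  dataset$indicator_names <- keep_cols
  dataset$block_of <- dataset$block_of[keep_cols]
  attr(dataset, "snps_removed_maf") <- drop_maf
  attr(dataset, "snps_removed_ld") <- drop_ld
  dataset
}

#' Write the canonical dataset CSV and a JSON run log
#'
#' @param dataset a `gsca_dataset`.
#' @param csv_path output CSV path (one row per individual, indicator
#'   columns in order).
#' @param log_path optional path for a JSON run log recording the block map,
#'   rows dropped at load and SNPs pruned by the filters (taken from the
#'   dataset's attributes when present).
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(dataset, csv_path, log_path = NULL) {
  stopifnot(inherits(dataset, "gsca_dataset"))
  utils::write.csv(as.data.frame(dataset$values), csv_path,
                   row.names = FALSE)
  if (!is.null(log_path)) {
    log <- list(
      n = dataset$n,
      standardized = dataset$standardized,
      blocks = as.list(dataset$block_of),
      n_dropped = attr(dataset, "n_dropped") %||% 0L,
      snps_removed_maf = as.character(attr(dataset, "snps_removed_maf")),
      snps_removed_ld = as.character(attr(dataset, "snps_removed_ld")))
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csv_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
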