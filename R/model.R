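#' Specify a structural component model
#'
#' A model maps disjoint sets of indicators onto latent components (each
#' component is a unit-variance weighted sum of its indicators) and declares
#' directed structural paths between components. In the candidate-gene
#' setting the latents are one component per gene plus one clinical-pathway
#' component over the phenotypes, with one path from every gene to the
#' pathway.
#'
#' @param indicator_sets named list; one entry per latent giving the names
#'   (or column indices) of its indicators. Sets must be disjoint.
#' @param paths two-column matrix or data.frame of `(source, sink)` latent
#'   names.
#' @return An object of class `gsca_model` with elements `latent_names`,
#'   `indicator_sets`, `paths`, `n_latents` and `n_genes` (latents that are
#'   path sources).
#' @export
gsca_model <- function(indicator_sets, paths) {
  stopifnot(is.list(indicator_sets), length(names(indicator_sets)) ==
              length(indicator_sets))
  paths <- as.matrix(paths)
  if (ncol(paths) != 2) stop("'paths' must have two columns (source, sink)")
  colnames(paths) <- c("source", "sink")
  latents <- names(indicator_sets)

  all_ind <- unlist(indicator_sets, use.names = FALSE)
  if (anyDuplicated(all_ind))
    stop("indicator sets must be disjoint; duplicated: ",
         paste(unique(all_ind[duplicated(all_ind)]), collapse = ", "))
  bad <- setdiff(c(paths), latents)
  if (length(bad))
    stop("path references undeclared latent(s): ", paste(bad, collapse = ", "))
  if (any(paths[, 1] == paths[, 2]))
    stop("a path must connect two distinct latents")

  sources <- unique(paths[, "source"])
  sinks <- unique(paths[, "sink"])
  if (length(intersect(sources, sinks)))
    stop("latents acting as both source and sink are not supported")
  orphan <- setdiff(latents, c(sources, sinks))
  if (length(orphan))
    stop("latent(s) not on any path: ", paste(orphan, collapse = ", "))

  structure(
    list(latent_names = latents,
         indicator_sets = indicator_sets,
         paths = paths,
         n_latents = length(latents),
         n_genes = length(sources)),
    class = "gsca_model")
}

#' Build the genes-to-pathway model for a dataset
#'
#' Constructs the standard candidate-gene model from the dataset's block
#' labels: one latent per gene block, a `pathway` latent over the
#' `"phenotypes"` block, and one structural path from each gene to the
#' pathway.
#'
#' @param dataset a `gsca_dataset`.
#' @return A `gsca_model`.
#' @export
pathway_model <- function(dataset) {
  stopifnot(inherits(dataset, "gsca_dataset"))
  blocks <- dataset$block_of
  genes <- unique(blocks[blocks != "phenotypes"])
  if (!length(genes)) stop("dataset has no gene blocks")
  if (!any(blocks == "phenotypes")) stop("dataset has no 'phenotypes' block")
  sets <- c(
    lapply(genes, function(g) names(blocks)[blocks == g]),
    list(names(blocks)[blocks == "phenotypes"]))
  names(sets) <- c(genes, "pathway")
  gsca_model(sets, cbind(source = genes, sink = rep("pathway", length(genes))))
}

#' @export
print.gsca_model <- function(x, ...) {
  sizes <- vapply(x$indicator_sets, length, integer(1))
  cat("gsca_model:", x$n_latents, "latents,", nrow(x$paths), "paths\n")
  cat("  ", paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "),
      "\n", sep = "")
  for (i in seq_len(nrow(x$paths)))
    cat("  ", x$paths[i, 1], "->", x$paths[i, 2], "\n")
  invisible(x)
}
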