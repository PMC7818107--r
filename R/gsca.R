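# Resolve a model's indicator sets to integer column indices of the data.
.model_indices <- function(model, indicator_names) {
  lapply(model$indicator_sets, function(s) {
    if (is.numeric(s)) return(as.integer(s))
    i <- match(s, indicator_names)
    if (anyNA(i))
      stop("indicator(s) not in dataset: ",
           paste(s[is.na(i)], collapse = ", "))
    i
  })
}

# Alternating least squares on the indicator covariance matrix C.
#
# Each cycle performs exact conditional minimizations of the structural
# criterion q = sum over sinks of E||gamma_sink - sum_b gamma_source||^2
# (in variance units, components held at unit variance):
#   (a) path coefficients: OLS of each sink component on its sources;
#   (b) each latent's weights: the closed-form maximizer of w'c subject to
#       w' C_ll w = 1, which is the constrained least-squares solution.
# Every step is an exact minimization given the other parameters, so q is
# non-increasing across cycles.
.gsca_als <- function(C, idx, paths, w_init, tol = 1e-5, max_iter = 200) {
  latents <- names(idx)
  sinks <- unique(paths[, "sink"])
  sources <- unique(paths[, "source"])
  src_of <- lapply(sinks, function(s) paths[paths[, "sink"] == s, "source"])
  names(src_of) <- sinks

  # pre-extract every needed sub-block of C (hot path: permutation refits)
  CB <- lapply(latents, function(a) {
    out <- lapply(latents, function(d) C[idx[[a]], idx[[d]], drop = FALSE])
    names(out) <- latents
    out
  })
  names(CB) <- latents

  normalize <- function(w, Cll) {
    v <- sqrt(drop(crossprod(w, Cll %*% w)))
    if (!is.finite(v) || v < 1e-12)
      stop("degenerate component (zero variance); check for collinear indicators")
    w / v
  }
  w <- lapply(latents, function(l) normalize(w_init[[l]], CB[[l]][[l]]))
  names(w) <- latents
  b <- lapply(sinks, function(s) numeric(length(src_of[[s]])))
  names(b) <- sinks
  ccov <- function(a, d) drop(crossprod(w[[a]], CB[[a]][[d]] %*% w[[d]]))
  sink_mM <- function(s) {
    srcs <- src_of[[s]]
    k <- length(srcs)
    m <- numeric(k)
    M <- diag(k)
    for (a in seq_len(k)) {
      m[a] <- ccov(s, srcs[a])
      for (d in seq_len(a))
        M[a, d] <- M[d, a] <- ccov(srcs[a], srcs[d])
    }
    list(m = m, M = M)
  }

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # (a) path update: OLS of each sink component on its source components
    for (s in sinks) {
      mm <- sink_mM(s)
      b[[s]] <- tryCatch(solve(mm$M, mm$m), error = function(e) {
        sv <- svd(mm$M)
        pos <- sv$d > 1e-10 * max(sv$d)
        drop(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], mm$m)) / sv$d[pos]))
      })
    }
    # (b) weight updates, sink then sources, each the exact constrained solve
    for (s in sinks) {
      srcs <- src_of[[s]]
      cc <- numeric(length(idx[[s]]))
      for (a in seq_along(srcs))
        cc <- cc + b[[s]][a] * drop(CB[[s]][[srcs[a]]] %*% w[[srcs[a]]])
      if (sqrt(sum(cc^2)) > 1e-12)
        w[[s]] <- normalize(solve(CB[[s]][[s]], cc), CB[[s]][[s]])
    }
    for (l in sources) {
      cc <- numeric(length(idx[[l]]))
      for (s in sinks) {
        a <- match(l, src_of[[s]])
        if (is.na(a)) next
        r <- drop(CB[[l]][[s]] %*% w[[s]])
        for (d in seq_along(src_of[[s]])) {
          if (d == a) next
          l2 <- src_of[[s]][d]
          r <- r - b[[s]][d] * drop(CB[[l]][[l2]] %*% w[[l2]])
        }
        cc <- cc + b[[s]][a] * r
      }
      if (sqrt(sum(cc^2)) > 1e-12)
        w[[l]] <- normalize(solve(CB[[l]][[l]], cc), CB[[l]][[l]])
    }
    q <- 0
    for (s in sinks) {
      mm <- sink_mM(s)
      q <- q + 1 - 2 * sum(b[[s]] * mm$m) +
        drop(crossprod(b[[s]], mm$M %*% b[[s]]))
    }
    trace <- c(trace, q)
    if (it > 1) {
      # denominator floored so near-zero criteria do not grind at max_iter
      rel <- (trace[it - 1] - trace[it]) / max(trace[it - 1], 1e-4)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
  }
  list(w = w, b = b, q = trace[length(trace)], trace = trace,
       converged = converged, n_iter = length(trace))
}

# Fit on a covariance matrix with multiple starts; returns the best run.
.fit_C <- function(C, idx, paths, tol, max_iter, n_starts) {
  best <- NULL
  for (s in seq_len(n_starts)) {
    w0 <- lapply(idx, function(i) {
      if (s == 1) rep(1, length(i)) else stats::rnorm(length(i))
    })
    names(w0) <- names(idx)
    run <- .gsca_als(C, idx, paths, w0, tol, max_iter)
    if (is.null(best) || run$q < best$q) best <- run
  }
  best
}

#' Fit a structural component model by alternating least squares
#'
#' Estimates, for each latent, the weights of its unit-variance component
#' (a weighted sum of its standardized indicators) and the structural path
#' coefficients linking source components (genes) to sink components (the
#' clinical pathway). The criterion minimized is the total squared
#' structural residual: the sum over sink components of the squared norm of
#' `gamma_sink - sum_sources b * gamma_source`, subject to every component
#' having unit sample variance. Estimation alternates exact conditional
#' least-squares solves for the paths and for each latent's weights, so the
#' criterion is non-increasing across iterations.
#'
#' @param dataset a standardized `gsca_dataset` (see [standardize()]).
#' @param model a `gsca_model`.
#' @param tol relative criterion change declaring convergence; default 1e-5.
#' @param max_iter maximum ALS cycles; default 200.
#' @param n_starts number of starts: the first uses equal weights, the rest
#'   draw standard-normal weights. The best run by final criterion is
#'   returned. Default 5.
#' @param seed optional integer seed for the random starts.
#' @return An object of class `gsca_fit`: `weights` (named list per latent),
#'   `paths` (data.frame of source, sink, estimate), `criterion` (final
#'   squared-residual value), `criterion_trace` (one value per ALS cycle of
#'   the best run), `converged`, `n_iter`, `n`, and the fitting `settings`.
#'   Weight signs follow the convention that each component's weight sum is
#'   non-negative; only `|estimate|` is stable under sign flips.
#' @export
fit_gsca <- function(dataset, model, tol = 1e-5, max_iter = 200,
                     n_starts = 5, seed = NULL) {
  stopifnot(inherits(dataset, "gsca_dataset"), inherits(model, "gsca_model"))
  if (!dataset$standardized)
    stop("dataset must be standardized; call standardize() first")
  if (!is.null(seed)) set.seed(seed)
  X <- dataset$values
  idx <- .model_indices(model, dataset$indicator_names)
  if (any(vapply(idx, length, integer(1)) == 0))
    stop("model has an empty indicator set")

  C <- crossprod(X) / (dataset$n - 1)
  for (l in names(idx)) {
    Cll <- C[idx[[l]], idx[[l]], drop = FALSE]
    ev <- eigen(Cll, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev))
      stop("exactly collinear indicators within block '", l,
           "'; remove them with filter_snps()")
  }

  best <- .fit_C(C, idx, model$paths, tol, max_iter, n_starts)
  if (!best$converged)
    warning("ALS did not converge in ", max_iter,
            " iterations; returning best iterate")

  # sign convention: each component's weight sum non-negative
  w <- best$w; b <- best$b
  for (l in names(w)) {
    if (sum(w[[l]]) < 0) {
      w[[l]] <- -w[[l]]
      for (s in names(b)) {
        srcs <- model$paths[model$paths[, "sink"] == s, "source"]
        if (l == s) b[[s]] <- -b[[s]]
        else if (l %in% srcs) b[[s]][match(l, srcs)] <- -b[[s]][match(l, srcs)]
      }
    }
  }
  for (l in names(w)) names(w[[l]]) <- dataset$indicator_names[idx[[l]]]

  paths_df <- do.call(rbind, lapply(names(b), function(s) {
    srcs <- model$paths[model$paths[, "sink"] == s, "source"]
    data.frame(source = srcs, sink = s, estimate = as.numeric(b[[s]]),
               stringsAsFactors = FALSE)
  }))
  rownames(paths_df) <- NULL

  structure(
    list(weights = w, paths = paths_df,
         criterion = best$q * (dataset$n - 1),
         criterion_trace = best$trace * (dataset$n - 1),
         converged = best$converged, n_iter = best$n_iter, n = dataset$n,
         settings = list(tol = tol, max_iter = max_iter, n_starts = n_starts),
         model = model),
    class = "gsca_fit")
}

#' @export
print.gsca_fit <- function(x, ...) {
  cat("gsca_fit: criterion", format(x$criterion, digits = 6),
      if (x$converged) "(converged" else "(NOT converged",
      "in", x$n_iter, "iterations)\n")
  print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Component scores of a fitted model
#'
#' @param fit a `gsca_fit`.
#' @param dataset the standardized dataset the model was fitted to.
#' @return numeric matrix, one unit-variance component score column per
#'   latent.
#' @export
component_scores <- function(fit, dataset) {
  stopifnot(inherits(fit, "gsca_fit"), inherits(dataset, "gsca_dataset"))
  idx <- .model_indices(fit$model, dataset$indicator_names)
  out <- vapply(names(idx), function(l)
    drop(dataset$values[, idx[[l]], drop = FALSE] %*% fit$weights[[l]]),
    numeric(dataset$n))
  colnames(out) <- names(idx)
  out
}

#' Structural criterion for given weights and paths
#'
#' Computes the total squared structural residual directly from the data:
#' for every sink component, the squared norm of its score vector minus the
#' path-weighted sum of its source score vectors, summed over sinks. Zero
#' if and only if every structural relation holds exactly.
#'
#' @param dataset a standardized `gsca_dataset`.
#' @param model a `gsca_model`.
#' @param weights named list of weight vectors (one per latent), normalized
#'   to unit component variance.
#' @param paths data.frame with columns `source`, `sink`, `estimate`.
#' @return Non-negative scalar.
#' @export
gsca_criterion <- function(dataset, model, weights, paths) {
  stopifnot(inherits(dataset, "gsca_dataset"), inherits(model, "gsca_model"))
  idx <- .model_indices(model, dataset$indicator_names)
  for (l in names(idx))
    if (length(weights[[l]]) != length(idx[[l]]))
      stop("weight vector for '", l, "' has length ", length(weights[[l]]),
           ", expected ", length(idx[[l]]))
  gam <- lapply(names(idx), function(l)
    drop(dataset$values[, idx[[l]], drop = FALSE] %*% weights[[l]]))
  names(gam) <- names(idx)
  crit <- 0
  for (s in unique(paths$sink)) {
    rows <- paths[paths$sink == s, , drop = FALSE]
    pred <- numeric(dataset$n)
    for (r in seq_len(nrow(rows)))
      pred <- pred + rows$estimate[r] * gam[[rows$source[r]]]
    crit <- crit + sum((gam[[s]] - pred)^2)
  }
  crit
}

#' Permutation test for structural path coefficients
#'
#' Tests each gene-to-pathway path by permutation: the rows of the phenotype
#' block are jointly permuted against the genotype blocks (preserving the
#' within-block correlation structure on both sides), the model is refitted,
#' and the absolute refitted path coefficient is compared with the observed
#' one. P-values use the add-one estimator
#' `p = (1 + #(|b*| >= |b_hat|)) / (1 + n_perm)`, a two-sided test on `|b|`.
#' The per-path significance level divides the family alpha by the number of
#' structural paths (the multiplicity relevant to this method — no
#' correction for the number of SNPs is required).
#'
#' @param dataset the standardized `gsca_dataset` used for `fit`.
#' @param model the `gsca_model` used for `fit`.
#' @param fit the observed `gsca_fit`.
#' @param n_perm number of permutations; default 1000.
#' @param family_alpha family-wise alpha to divide across paths; default
#'   0.05.
#' @param seed optional integer seed.
#' @return An object of class `gsca_perm`: `table` (data.frame of source,
#'   sink, estimate, p_value, significant), `n_perm`, `alpha_per_path`,
#'   `family_alpha`. Permutation refits reuse the fit's settings so the
#'   observed and permuted statistics are exchangeable under the null.
#' @export
permutation_test <- function(dataset, model, fit, n_perm = 1000,
                             family_alpha = 0.05, seed = NULL) {
  stopifnot(inherits(dataset, "gsca_dataset"), inherits(fit, "gsca_fit"),
            n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- dataset$values
  n <- dataset$n
  idx <- .model_indices(model, dataset$indicator_names)
  ph <- which(dataset$block_of == "phenotypes")
  gt <- setdiff(seq_len(ncol(X)), ph)
  if (!length(ph)) stop("dataset has no 'phenotypes' block to permute")

  C <- crossprod(X) / (n - 1)
  obs <- abs(fit$paths$estimate)
  exceed <- numeric(length(obs))
  st <- fit$settings

  fails <- 0L
  done <- 0L
  while (done < n_perm) {
    perm <- sample.int(n)
    Cp <- C
    cross <- crossprod(X[, gt, drop = FALSE], X[perm, ph, drop = FALSE]) / (n - 1)
    Cp[gt, ph] <- cross
    Cp[ph, gt] <- t(cross)
    run <- tryCatch(
      .fit_C(Cp, idx, model$paths, st$tol, st$max_iter, st$n_starts),
      error = function(e) NULL)
    if (is.null(run)) {
      fails <- fails + 1L
      if (fails > 25L)
        stop("permutation refits failed repeatedly; last model is degenerate")
      next
    }
    bstar <- abs(unlist(lapply(names(run$b), function(s) {
      srcs <- model$paths[model$paths[, "sink"] == s, "source"]
      stats::setNames(run$b[[s]], paste(srcs, s))
    }), use.names = FALSE))
    exceed <- exceed + as.numeric(bstar >= obs)
    done <- done + 1L
  }

  p <- (1 + exceed) / (1 + n_perm)
  alpha_pp <- family_alpha / nrow(fit$paths)
  tab <- cbind(fit$paths,
               data.frame(p_value = p, significant = p < alpha_pp))
  structure(
    list(table = tab, n_perm = n_perm, alpha_per_path = alpha_pp,
         family_alpha = family_alpha),
    class = "gsca_perm")
}

#' @export
print.gsca_perm <- function(x, ...) {
  cat("Permutation test:", x$n_perm, "permutations, per-path alpha",
      format(x$alpha_per_path, digits = 4),
      sprintf("(= %g / %d paths)\n", x$family_alpha, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
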