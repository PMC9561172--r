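#' @noRd
as_count_matrix <- function(x, depth) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric samples x taxa matrix")
  if (any(x < 0)) stop("negative values in abundance/count matrix")
  if (all(abs(rowSums(x) - 1) < 1e-6)) {
    # relative abundances: rescale to pseudo-counts at the stated depth
    x <- round(x * depth)
  }
  x
}

#' SparCC-style basis correlations for compositional data
#'
#' Estimates correlations between taxa on the (unobserved) basis scale from
#' compositional counts or relative abundances. Per iteration, component
#' fractions are resampled from a Dirichlet posterior with pseudocount 1,
#' the variation matrix `t_ij = Var(log x_i / x_j)` is formed, and the basis
#' variances are solved from the linear system implied by assuming sparse
#' correlations; `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clamped
#' to `[-1, 1]`. Up to `exclude_iterations` rounds then remove the currently
#' strongest `|rho| > exclusion_threshold` pair from the system and
#' re-solve, which protects the sparsity assumption from a few strong
#' correlations. The reported matrix is the element-wise median over
#' iterations.
#'
#' Taxon pairs whose basis variance turns non-positive after exclusions (a
#' degenerate system) are set to 0 and flagged with a warning rather than
#' reported silently.
#'
#' @param x samples x taxa matrix of counts, or of relative abundances
#'   (rows summing to 1), which are rescaled to pseudo-counts at `depth`.
#' @param iterations number of Dirichlet resampling iterations (default
#'   100).
#' @param exclude_iterations maximum strong-pair exclusion rounds (default
#'   20).
#' @param exclusion_threshold `|rho|` above which a pair can be excluded
#'   (default 0.1).
#' @param seed integer seed; fully determines the estimate.
#' @param depth pseudo-count depth used when `x` holds relative abundances.
#' @return symmetric correlation matrix with unit diagonal and an
#'   `n_nonpositive_basis` attribute.
#' @export
sparcc_correlations <- function(x, iterations = 100L, exclude_iterations = 20L,
                                exclusion_threshold = 0.1, seed = 1L, depth = 10000) {
  counts <- as_count_matrix(x, depth)
  if (ncol(counts) < 4L)
    stop("need at least 4 taxa: the basis-variance system is not identifiable below that")
  if (nrow(counts) < 10L) stop("need at least 10 samples")
  res <- .sparcc_fit_cpp(counts, as.integer(iterations), as.integer(exclude_iterations),
                         exclusion_threshold, as.numeric(child_seed(seed, "sparcc")))
  rho <- res$rho
  dimnames(rho) <- list(colnames(x), colnames(x))
  if (res$n_nonpositive_basis > 0)
    warning(sprintf("%d taxon pair(s) hit a non-positive basis variance and were set to 0",
                    res$n_nonpositive_basis))
  attr(rho, "n_nonpositive_basis") <- res$n_nonpositive_basis
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Null replicates are built by independently permuting each taxon's values
#' across samples — destroying all inter-taxon association while preserving
#' every marginal — and re-running the correlation estimator with identical
#' settings. Two-sided add-one p-values:
#' `p_ij = (1 + #{|rho_null| >= |rho_obs|}) / (n_boot + 1)`, so the smallest
#' attainable p is `1 / (n_boot + 1)`.
#'
#' @param x the data matrix `rho_obs` was estimated from.
#' @param rho_obs observed correlation matrix from [sparcc_correlations()].
#' @param n_boot number of permutation replicates (default 1000).
#' @param seed integer seed.
#' @inheritParams sparcc_correlations
#' @return matrix of p-values (diagonal `NA`).
#' @export
edge_pvalues <- function(x, rho_obs, n_boot = 1000L, seed = 1L, iterations = 100L,
                         exclude_iterations = 20L, exclusion_threshold = 0.1,
                         depth = 10000) {
  counts <- as_count_matrix(x, depth)
  if (!all(dim(rho_obs) == ncol(counts))) stop("rho_obs does not match x")
  exceed <- .sparcc_perm_exceed_cpp(counts, abs(rho_obs), as.integer(n_boot),
                                    as.integer(iterations), as.integer(exclude_iterations),
                                    exclusion_threshold,
                                    as.numeric(child_seed(seed, "sparcc_perm")))
  p <- (1 + exceed) / (n_boot + 1)
  dimnames(p) <- dimnames(rho_obs)
  diag(p) <- NA_real_
  p
}
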