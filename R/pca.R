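#' PLINK-style variance standardization of a dosage matrix
#'
#' Missing dosages are mean-imputed per site. Each site is centered by its
#' mean dosage and scaled by `sqrt(2 p (1 - p))` with `p` = mean dosage / 2
#' (the variance of a binomial(2, p) allele count). Monomorphic sites
#' (`p` of 0 or 1, or constant dosages) are dropped.
#'
#' @param matrix a [dosage_matrix()]
#' @return numeric matrix, retained sites x samples, with attribute
#'   `kept_sites` (indices of the retained sites)
#' @export
standardize_dosage <- function(matrix) {
  d <- matrix$dosage
  storage.mode(d) <- "double"
  mu <- rowMeans(d, na.rm = TRUE)
  imp <- which(is.na(d), arr.ind = TRUE)
  if (nrow(imp)) d[imp] <- mu[imp[, 1]]
  p <- mu / 2
  keep <- p > 0 & p < 1 & apply(d, 1, function(r) any(r != r[1]))
  if (!any(keep)) stop("all sites monomorphic: nothing to standardize")
  d <- d[keep, , drop = FALSE]
  p <- p[keep]
  x <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  attr(x, "kept_sites") <- which(keep)
  x
}

#' Principal component analysis of a genotype matrix
#'
#' Eigendecomposition of the sample-by-sample covariance of the
#' variance-standardized dosage matrix (divided by the number of sites).
#' Sample coordinates are eigenvectors scaled by the square root of their
#' eigenvalue; each component reports its eigenvalue and its fraction of the
#' total variance (eigenvalue / trace). Each eigenvector's
#' largest-magnitude entry is made positive so output signs are
#' deterministic.
#'
#' @param matrix a [dosage_matrix()] with at least 2 samples
#' @param n_components number of components to return (clipped, with a
#'   warning, to samples - 1)
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `eigenvalues` (all components), `var_frac` (fractions summing to 1),
#'   `n_sites` (sites used after dropping monomorphic ones)
#' @export
pca_genotypes <- function(matrix, n_components = 2L) {
  ns <- length(matrix$samples)
  if (ns < 2) stop("PCA needs at least 2 samples")
  if (n_components > ns - 1L) {
    warning("n_components clipped to samples - 1")
    n_components <- ns - 1L
  }
  x <- standardize_dosage(matrix)
  g <- crossprod(x) / nrow(x)
  ee <- eigen(g, symmetric = TRUE)
  vals <- ee$values
  if (any(vals < -1e-9)) stop("covariance eigenvalues unexpectedly negative")
  vals[vals < 0] <- 0
  vecs <- ee$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  k <- seq_len(n_components)
  scores <- vecs[, k, drop = FALSE] %*% diag(sqrt(vals[k]), n_components)
  dimnames(scores) <- list(matrix$samples, paste0("PC", k))
  structure(list(scores = scores, eigenvalues = vals,
                 var_frac = vals / sum(vals), n_sites = nrow(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA over %d sites, %d samples\n", x$n_sites, nrow(x$scores)))
  k <- seq_len(ncol(x$scores))
  cat(sprintf("  %s: %.2f%% of variance\n", colnames(x$scores),
              100 * x$var_frac[k]), sep = "")
  invisible(x)
}
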