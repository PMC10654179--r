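#' Squared Pearson correlation between two dosage vectors
#'
#' Missing entries are pairwise-deleted. If either vector is constant after
#' deletion the correlation is undefined and 0 is returned (such a pair
#' carries no linkage signal).
#'
#' @param x,y numeric dosage vectors of equal length (NA = missing)
#' @return squared Pearson correlation in `[0, 1]`
#' @export
pairwise_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 complete pairs: r^2 undefined")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

# r^2 matrix between rows of m (sites x samples), pairwise deletion,
# undefined values treated as 0 (no linkage evidence)
.r2_matrix <- function(m) {
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' LD-prune configuration
#'
#' Defaults reproduce the PLINK-style `--indep-pairwise 50 10 0.5` thinning:
#' sliding windows of 50 SNPs advanced in 10-SNP increments, removing one of
#' any pair with squared correlation above 0.5.
#'
#' @param window window size in SNPs
#' @param step window increment in SNPs
#' @param r2_max maximum tolerated pairwise r-squared
#' @return a list of class `prune_config`
#' @export
prune_config <- function(window = 50L, step = 10L, r2_max = 0.5) {
  if (step <= 0 || window <= 0 || step > window)
    stop("need 0 < step <= window")
  if (r2_max < 0 || r2_max > 1) stop("r2_max must be in [0, 1]")
  structure(list(window = as.integer(window), step = as.integer(step),
                 r2_max = r2_max), class = "prune_config")
}

# prune one scaffold; m = dosage rows in genomic order; returns kept row indices
.prune_scaffold <- function(m, cfg) {
  kept <- seq_len(nrow(m))
  repeat {
    removed_any <- FALSE
    start <- 1L
    repeat {
      stop_at <- min(start + cfg$window - 1L, length(kept))
      win <- kept[start:stop_at]
      if (length(win) >= 2L) {
        r2 <- .r2_matrix(m[win, , drop = FALSE])
        repeat {
          off <- which(upper.tri(r2) & r2 > cfg$r2_max, arr.ind = TRUE)
          if (!nrow(off)) break
          # first offending pair in (earlier, later) order; drop the later SNP
          off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
          victim <- off[1, 2]
          kept <- setdiff(kept, win[victim])
          win <- win[-victim]
          r2 <- r2[-victim, -victim, drop = FALSE]
          removed_any <- TRUE
        }
      }
      if (start + cfg$window - 1L >= length(kept)) break
      start <- start + cfg$step
    }
    if (!removed_any) break
  }
  kept
}

#' Thin SNPs by windowed pairwise r-squared
#'
#' Per scaffold, a window of `cfg$window` currently-kept SNPs is scanned;
#' while any pair inside the window has r-squared above `cfg$r2_max`, the
#' later-positioned SNP of the first offending pair is removed. The window
#' then advances by `cfg$step` kept SNPs. Sweeps repeat until a full pass
#' removes nothing, so no pair of kept SNPs that ever shares a window
#' exceeds the threshold, and the operation is idempotent. Sites on
#' different scaffolds are never compared.
#'
#' @param matrix a [dosage_matrix()] with sites sorted by (scaffold, position)
#' @param cfg a [prune_config()]
#' @return integer vector of kept site indices (ascending genomic order)
#' @export
ld_prune <- function(matrix, cfg = prune_config()) {
  stopifnot(inherits(matrix, "dosage_matrix"), inherits(cfg, "prune_config"))
  ord <- order(matrix$chrom, matrix$pos)
  if (any(ord != seq_along(ord)))
    stop("sites must be sorted by (scaffold, position)")
  kept <- integer(0)
  for (sc in unique(matrix$chrom)) {
    rows <- which(matrix$chrom == sc)
    kept_sc <- .prune_scaffold(matrix$dosage[rows, , drop = FALSE], cfg)
    kept <- c(kept, rows[kept_sc])
  }
  sort(kept)
}

#' Apply an LD-prune result to a dosage matrix
#'
#' @param matrix a [dosage_matrix()]
#' @param kept integer indices from [ld_prune()]
#' @return the thinned `dosage_matrix`
#' @export
subset_dosage <- function(matrix, kept) {
  dosage_matrix(matrix$dosage[kept, , drop = FALSE], matrix$chrom[kept],
                matrix$pos[kept], matrix$samples)
}
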