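#' Per-site alt-allele frequencies for the four D-statistic roles
#'
#' Frequencies are computed per role as (sum of dosages) / (2 x called
#' samples), pooling all populations assigned to the role. Sites where any
#' role has no called genotype are skipped.
#'
#' @param matrix a [dosage_matrix()]
#' @param pops a `pop_map` with roles assigned (see [assign_roles()])
#' @return data.frame with columns `chrom`, `pos`, `p1`, `p2`, `p3`, `p4`
#'   (alt-allele frequency of P1, P2, P3 and the outgroup), in genomic order
#' @export
pop_freqs <- function(matrix, pops) {
  roles <- c("P1", "P2", "P3", "outgroup")
  fr <- lapply(roles, function(r) {
    ids <- role_samples(pops, r)
    ids <- intersect(ids, matrix$samples)
    if (!length(ids)) stop("no samples in matrix for role ", r)
    d <- matrix$dosage[, match(ids, matrix$samples), drop = FALSE]
    called <- rowSums(!is.na(d))
    ifelse(called > 0, rowSums(d, na.rm = TRUE) / (2 * called), NA_real_)
  })
  names(fr) <- c("p1", "p2", "p3", "p4")
  out <- data.frame(chrom = matrix$chrom, pos = matrix$pos,
                    p1 = fr$p1, p2 = fr$p2, p3 = fr$p3, p4 = fr$p4,
                    stringsAsFactors = FALSE)
  out[stats::complete.cases(out[, c("p1", "p2", "p3", "p4")]), , drop = FALSE]
}

#' Frequency-weighted ABBA/BABA pattern sums
#'
#' Per-site weights of the two discordant patterns and the concordant one,
#' summed over sites: `ABBA = sum (1-p1) p2 p3 (1-p4)`,
#' `BABA = sum p1 (1-p2) p3 (1-p4)`,
#' `concordant = sum p1 p2 (1-p3) (1-p4)` (the pattern grouping P1 with P2;
#' reported under the label AABB). The `(1 - p4)` factor downweights sites
#' where the outgroup carries the alt allele, so no explicit ancestral
#' repolarization is performed.
#'
#' @param p1,p2,p3,p4 per-site alt-allele frequencies (equal-length vectors)
#' @return list with elements `abba`, `baba`, `concordant` (the sums) and
#'   `abba_w`, `baba_w` (per-site weight vectors, for jackknifing)
#' @export
pattern_weights <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  abba_w <- (1 - p1) * p2 * p3 * (1 - p4)
  baba_w <- p1 * (1 - p2) * p3 * (1 - p4)
  conc_w <- p1 * p2 * (1 - p3) * (1 - p4)
  list(abba = sum(abba_w), baba = sum(baba_w), concordant = sum(conc_w),
       abba_w = abba_w, baba_w = baba_w)
}

#' Patterson's D statistic from pattern sums
#'
#' @param abba,baba frequency-weighted pattern sums
#' @return D = (ABBA - BABA) / (ABBA + BABA), in `[-1, 1]`
#' @export
d_statistic <- function(abba, baba) {
  if (abba + baba <= 0)
    stop("D undefined: ABBA + BABA must be positive")
  (abba - baba) / (abba + baba)
}

#' Two-sided normal p-value from a Z score
#' @param z a Z score
#' @return `2 (1 - Phi(|z|))`
#' @export
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Block-jackknife standard error for the D statistic
#'
#' Sites (in genome order) are cut into `num_blocks` contiguous blocks of
#' near-equal size (`floor(n / num_blocks)`, remainder spread over the first
#' blocks). The SE uses the delete-m_j weighted jackknife over the
#' delete-one-block D estimates, which reduces to the ordinary delete-one
#' block jackknife when all blocks are equal. Z = D / SE and
#' p = 2 (1 - Phi(|Z|)).
#'
#' @param abba_w,baba_w per-site ABBA and BABA weights in genome order
#' @param num_blocks number of jackknife blocks (default 20)
#' @return list: `D`, `se`, `z`, `p`, `num_blocks`, `block_sizes`
#' @export
block_jackknife <- function(abba_w, baba_w, num_blocks = 20L) {
  n <- length(abba_w)
  stopifnot(length(baba_w) == n)
  if (num_blocks < 2) stop("need at least 2 jackknife blocks")
  if (n < num_blocks) stop("fewer usable sites than jackknife blocks")
  base <- n %/% num_blocks
  sizes <- rep(base, num_blocks)
  extra <- n - base * num_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(num_blocks), times = sizes)

  a_tot <- sum(abba_w); b_tot <- sum(baba_w)
  d_hat <- d_statistic(a_tot, b_tot)
  a_blk <- tapply(abba_w, block, sum)
  b_blk <- tapply(baba_w, block, sum)
  denom <- (a_tot - a_blk) + (b_tot - b_blk)
  if (any(denom <= 0)) stop("a delete-one-block D estimate is undefined")
  d_minus <- ((a_tot - a_blk) - (b_tot - b_blk)) / denom

  # weighted delete-m_j jackknife (Busing et al. 1999)
  g <- num_blocks
  h <- n / sizes
  theta_tilde <- g * d_hat - sum((1 - sizes / n) * d_minus)
  pseudo <- h * d_hat - (h - 1) * d_minus
  var_j <- sum((pseudo - theta_tilde)^2 / (h - 1)) / g
  se <- sqrt(var_j)
  z <- d_hat / se
  list(D = d_hat, se = se, z = z, p = z_to_p(z),
       num_blocks = as.integer(g), block_sizes = as.integer(sizes))
}

#' ABBA/BABA D statistic with block-jackknife significance
#'
#' Runs the whole frequency-weighted ABBA/BABA analysis on a dosage matrix:
#' per-role allele frequencies, pattern sums, D, and the block-jackknife
#' Z and two-sided p. Roles are taken as given (D is signed; positive D
#' means an excess of P2-P3 allele sharing).
#'
#' @param matrix a [dosage_matrix()]
#' @param pops a `pop_map` with roles assigned (see [assign_roles()])
#' @param num_blocks number of jackknife blocks (default 20)
#' @return list of class `dstat_result`: `abba`, `baba`, `aabb`
#'   (concordant), `D`, `se`, `z`, `p`, `n_sites`, `num_blocks`,
#'   `block_sizes`
#' @export
d_stat <- function(matrix, pops, num_blocks = 20L) {
  fr <- pop_freqs(matrix, pops)
  w <- pattern_weights(fr$p1, fr$p2, fr$p3, fr$p4)
  jk <- block_jackknife(w$abba_w, w$baba_w, num_blocks)
  structure(list(abba = w$abba, baba = w$baba, aabb = w$concordant,
                 D = jk$D, se = jk$se, z = jk$z, p = jk$p,
                 n_sites = nrow(fr), num_blocks = jk$num_blocks,
                 block_sizes = jk$block_sizes),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("ABBA/BABA D statistic over %d sites (%d jackknife blocks)\n",
              x$n_sites, x$num_blocks))
  cat(sprintf("  ABBA = %.2f, BABA = %.2f, AABB = %.2f\n",
              x$abba, x$baba, x$aabb))
  cat(sprintf("  D = %.4f, Z = %.4f, p = %.4f\n", x$D, x$z, x$p))
  invisible(x)
}

#' One-row data.frame view of a D-statistic result
#' @param x a `dstat_result`
#' @return data.frame with columns ABBA, BABA, AABB, D, SE, Z, p, n_sites,
#'   n_blocks
#' @export
dstat_row <- function(x) {
  data.frame(ABBA = x$abba, BABA = x$baba, AABB = x$aabb, D = x$D,
             SE = x$se, Z = x$z, p = x$p, n_sites = x$n_sites,
             n_blocks = x$num_blocks)
}
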