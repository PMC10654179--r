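# Test fixtures are built in code: small variant tables assembled directly,
# plus a hand-written plain-text VCF emitter that is independent of the
# package's own writer (so reader tests do not lean on write_vcf).

toy_sites <- function(n, chrom = rep("s1", n), ref = rep("A", n),
                      alt = rep("G", n)) {
  pos <- stats::ave(seq_len(n), chrom, FUN = seq_along) * 10L
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# variant_table from a dosage matrix (biallelic sites), full depth
table_from_dosage <- function(dos, chrom = rep("s1", nrow(dos)),
                              depth = 30L) {
  n <- nrow(dos); m <- ncol(dos)
  samples <- colnames(dos)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(m))
  a1 <- ifelse(dos == 2L, 1L, 0L)
  a2 <- ifelse(dos >= 1L, 1L, 0L)
  a1[is.na(dos)] <- NA_integer_
  a2[is.na(dos)] <- NA_integer_
  variant_table(toy_sites(n, chrom), a1, a2,
                matrix(as.integer(depth), n, m), samples)
}

random_dosage <- function(n_sites, n_samples, p_missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  if (p_missing > 0)
    d[stats::runif(length(d)) < p_missing] <- NA_integer_
  colnames(d) <- sprintf("S%d", seq_len(n_samples))
  d
}

# plain-text VCF written by hand; `records` are pre-formatted data lines
write_plain_vcf <- function(records, samples, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
    '##INFO=<ID=FC,Number=1,Type=String,Description="class">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# independent r^2: explicit moment formula, same conventions as pairwise_r2
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  if (sxx == 0 || syy == 0) return(0)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxy^2 / (sxx * syy)
}

# TRUE when some pair's r^2 lies within float noise of the threshold, where
# two algebraically equivalent formulas may round to opposite sides
has_r2_tie <- function(dos, r2_max, eps = 1e-9) {
  n <- nrow(dos)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (abs(oracle_r2(dos[i, ], dos[j, ]) - r2_max) < eps) return(TRUE)
  FALSE
}

# forward-greedy all-pairs pruning oracle (valid when window >= n)
oracle_greedy_prune <- function(dos, r2_max) {
  kept <- integer(0)
  for (j in seq_len(nrow(dos))) {
    clash <- any(vapply(kept, function(i)
      oracle_r2(dos[i, ], dos[j, ]) > r2_max, logical(1)))
    if (!clash) kept <- c(kept, j)
  }
  kept
}
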