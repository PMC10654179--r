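#' Construct a variant table
#'
#' The central sites-by-samples container of the package. Site metadata
#' (scaffold, 1-based position, ref/alt alleles, the six GATK-style site
#' annotations and a functional class) live in `sites`; genotypes are stored
#' as two allele-index matrices (`0` = ref, `1, 2, ...` = alt alleles, `NA` =
#' missing) so that multi-allelic records survive I/O, plus a per-genotype
#' read-depth matrix.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multi-allelic sites), optional numeric columns
#'   `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `SOR` (NA = annotation
#'   absent) and character column `fc` (functional class).
#' @param a1,a2 integer matrices, sites x samples, allele indices with
#'   `a1 <= a2`; `NA` marks a missing genotype (both must be NA together).
#' @param depth integer matrix, sites x samples, non-negative read depths;
#'   `NA` = depth absent.
#' @param samples character vector of sample ids (column order of the
#'   genotype matrices).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, a1, a2, depth, samples) {
  stopifnot(is.data.frame(sites), is.matrix(a1), is.matrix(a2))
  ann_cols <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  for (k in ann_cols) if (is.null(sites[[k]])) sites[[k]] <- NA_real_
  if (is.null(sites$fc)) sites$fc <- NA_character_
  sites$pos <- as.integer(sites$pos)
  n <- nrow(sites)
  if (nrow(a1) != n || nrow(a2) != n)
    stop("genotype matrices must have one row per site")
  if (ncol(a1) != length(samples))
    stop("genotype matrices must have one column per sample")
  if (is.null(depth)) depth <- matrix(NA_integer_, n, length(samples))
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  storage.mode(depth) <- "integer"
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotypes are not representable")
  colnames(a1) <- colnames(a2) <- colnames(depth) <- samples
  rownames(sites) <- NULL
  # positions must be strictly increasing within each scaffold
  if (n > 1) {
    same <- sites$chrom[-1] == sites$chrom[-n]
    if (any(same & diff(sites$pos) <= 0))
      stop("positions must be strictly increasing within a scaffold")
  }
  structure(
    list(sites = sites, a1 = a1, a2 = a2, depth = depth,
         samples = as.character(samples)),
    class = "variant_table"
  )
}

#' Number of sites in a variant table or dosage matrix
#' @param x a `variant_table` or `dosage_matrix`
#' @return integer count of sites
#' @export
n_sites <- function(x) UseMethod("n_sites")

#' @export
n_sites.variant_table <- function(x) nrow(x$sites)

#' @export
n_sites.dosage_matrix <- function(x) nrow(x$dosage)

#' Sample ids of a variant table or dosage matrix
#' @param x a `variant_table` or `dosage_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) x$samples

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%d scaffolds)\n",
              n_sites(x), length(x$samples), length(unique(x$sites$chrom))))
  cat(sprintf("  missing genotypes: %d\n", sum(is.na(x$a1))))
  invisible(x)
}

#' Subset a variant table by site index
#'
#' @param x a `variant_table`
#' @param idx integer or logical index over sites (genomic order preserved)
#' @return a `variant_table` with the selected sites
#' @export
subset_sites <- function(x, idx) {
  variant_table(x$sites[idx, , drop = FALSE],
                x$a1[idx, , drop = FALSE], x$a2[idx, , drop = FALSE],
                x$depth[idx, , drop = FALSE], x$samples)
}

#' Subset a variant table or dosage matrix by sample id
#'
#' @param x a `variant_table` or `dosage_matrix`
#' @param samples character vector of sample ids to keep
#' @return object of the same class restricted to those samples
#' @export
subset_samples <- function(x, samples) UseMethod("subset_samples")

#' @export
subset_samples.variant_table <- function(x, samples) {
  miss <- setdiff(samples, x$samples)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  j <- match(samples, x$samples)
  variant_table(x$sites, x$a1[, j, drop = FALSE], x$a2[, j, drop = FALSE],
                x$depth[, j, drop = FALSE], samples)
}

#' @export
subset_samples.dosage_matrix <- function(x, samples) {
  miss <- setdiff(samples, x$samples)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  j <- match(samples, x$samples)
  dosage_matrix(x$dosage[, j, drop = FALSE], x$chrom, x$pos, samples)
}

#' Count of alt alleles listed at each site
#' @param x a `variant_table`
#' @return integer vector, number of alt alleles per site
#' @export
n_alt_alleles <- function(x) {
  lengths(strsplit(x$sites$alt, ",", fixed = TRUE))
}

#' Construct a dosage matrix
#'
#' Numeric recode of biallelic genotypes: 0 or 2 = homozygous (ref or alt),
#' 1 = heterozygous, `NA` = missing.
#'
#' @param dosage integer matrix, sites x samples, values in `{0, 1, 2, NA}`
#' @param chrom character vector of scaffold ids per site
#' @param pos integer vector of 1-based positions per site
#' @param samples character vector of sample ids
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosage, chrom, pos, samples) {
  stopifnot(is.matrix(dosage), nrow(dosage) == length(chrom),
            length(chrom) == length(pos), ncol(dosage) == length(samples))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- samples
  structure(list(dosage = dosage, chrom = as.character(chrom),
                 pos = as.integer(pos), samples = as.character(samples)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d sites x %d samples\n",
              nrow(x$dosage), length(x$samples)))
  invisible(x)
}
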