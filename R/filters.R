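#' Hard-filter and site-selection configuration
#'
#' Thresholds follow the GATK-style hard filters used for the macaw panel:
#' sites are removed when QD < 6, FS > 40, MQ < 59, MQRankSum < -0.3,
#' ReadPosRankSum < -2 or SOR > 2 (all comparisons strict). `depth_min` is
#' the per-genotype no-call threshold (8x for marker selection, 15x for the
#' diversity sites), `max_nocall` the number of missing genotypes tolerated
#' per site, and `classes` the functional classes retained.
#'
#' @param qd_min,fs_max,mq_min,mqranksum_min,readpos_min,sor_max numeric
#'   hard-filter thresholds
#' @param depth_min integer minimum per-genotype depth
#' @param max_nocall integer maximum missing genotypes per site
#' @param classes character vector of functional classes to keep, or NULL
#' @return a list of class `filter_config`
#' @export
filter_config <- function(qd_min = 6.0, fs_max = 40.0, mq_min = 59.0,
                          mqranksum_min = -0.3, readpos_min = -2.0,
                          sor_max = 2.0, depth_min = 8L, max_nocall = 0L,
                          classes = NULL) {
  thr <- c(qd_min, fs_max, mq_min, mqranksum_min, readpos_min, sor_max)
  if (any(!is.finite(thr))) stop("hard-filter thresholds must be finite")
  if (depth_min < 0) stop("depth_min must be non-negative")
  structure(list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
                 mqranksum_min = mqranksum_min, readpos_min = readpos_min,
                 sor_max = sor_max, depth_min = as.integer(depth_min),
                 max_nocall = as.integer(max_nocall), classes = classes),
            class = "filter_config")
}

# a site lacking an annotation passes that single criterion
.fails <- function(x, bad) !is.na(x) & bad

#' Apply the six GATK-style site hard filters
#'
#' Removes sites failing any of: QD < `qd_min`, FS > `fs_max`, MQ < `mq_min`,
#' MQRankSum < `mqranksum_min`, ReadPosRankSum < `readpos_min`,
#' SOR > `sor_max`. All comparisons are strict; a site lacking a given
#' annotation passes that single criterion (rank-sum annotations are
#' undefined at sites with no heterozygotes).
#'
#' @param table a [variant_table()]
#' @param cfg a [filter_config()]
#' @return the filtered `variant_table`
#' @export
apply_hard_filters <- function(table, cfg = filter_config()) {
  s <- table$sites
  fail <- .fails(s$QD, s$QD < cfg$qd_min) |
    .fails(s$FS, s$FS > cfg$fs_max) |
    .fails(s$MQ, s$MQ < cfg$mq_min) |
    .fails(s$MQRankSum, s$MQRankSum < cfg$mqranksum_min) |
    .fails(s$ReadPosRankSum, s$ReadPosRankSum < cfg$readpos_min) |
    .fails(s$SOR, s$SOR > cfg$sor_max)
  subset_sites(table, !fail)
}

#' Mask low-depth genotypes as no-call
#'
#' A genotype whose depth is below `depth_min`, or whose depth is absent,
#' becomes missing. Sites are retained.
#'
#' @param table a [variant_table()]
#' @param depth_min integer minimum depth to keep a call
#' @return a `variant_table` with low-depth genotypes set to missing
#' @export
mask_low_depth <- function(table, depth_min) {
  mask <- is.na(table$depth) | table$depth < depth_min
  a1 <- table$a1; a2 <- table$a2
  a1[mask] <- NA_integer_
  a2[mask] <- NA_integer_
  variant_table(table$sites, a1, a2, table$depth, table$samples)
}

#' Keep sites genotyped in (almost) all samples
#'
#' @param table a [variant_table()]
#' @param max_nocall integer; sites with more missing genotypes are dropped
#'   (0 reproduces "all samples genotyped")
#' @return the filtered `variant_table`
#' @export
require_complete <- function(table, max_nocall = 0L) {
  keep <- rowSums(is.na(table$a1)) <= max_nocall
  subset_sites(table, keep)
}

#' Keep single-nucleotide variants
#'
#' Retains sites whose ref and every alt allele are single bases
#' (multi-allelic SNPs pass; indels do not).
#'
#' @param table a [variant_table()]
#' @return the filtered `variant_table`
#' @export
select_snps <- function(table) {
  alt_list <- strsplit(table$sites$alt, ",", fixed = TRUE)
  keep <- nchar(table$sites$ref) == 1L &
    vapply(alt_list, function(a) length(a) >= 1L && all(nchar(a) == 1L),
           logical(1))
  subset_sites(table, keep)
}

#' Keep biallelic SNPs
#'
#' Retains sites with a single-base ref and exactly one single-base alt.
#'
#' @param table a [variant_table()]
#' @return the filtered `variant_table`
#' @export
select_biallelic_snps <- function(table) {
  keep <- nchar(table$sites$ref) == 1L & n_alt_alleles(table) == 1L &
    !grepl(",", table$sites$alt, fixed = TRUE) & nchar(table$sites$alt) == 1L
  subset_sites(table, keep)
}

#' Keep sites of given functional classes
#'
#' @param table a [variant_table()]
#' @param classes character vector of classes to keep, e.g.
#'   `c("intronic", "synonymous")` for the likely-neutral set or
#'   `"four_fold_synonymous"` for the phylogenetic markers
#' @return the filtered `variant_table`
#' @export
select_site_class <- function(table, classes) {
  subset_sites(table, table$sites$fc %in% classes)
}

#' Drop sites no longer segregating in a sample subset
#'
#' Keeps sites where, among the called genotypes of the given samples, at
#' least two distinct alleles are observed (for biallelic sites: both ref
#' and alt present).
#'
#' @param table a [variant_table()]
#' @param samples sample ids defining the subset (default: all samples)
#' @return the filtered `variant_table`
#' @export
drop_nonsegregating <- function(table, samples = NULL) {
  if (is.null(samples)) samples <- table$samples
  j <- match(samples, table$samples)
  if (anyNA(j)) stop("unknown samples in subset")
  a1 <- table$a1[, j, drop = FALSE]
  a2 <- table$a2[, j, drop = FALSE]
  keep <- vapply(seq_len(n_sites(table)), function(i) {
    al <- c(a1[i, ], a2[i, ])
    length(unique(al[!is.na(al)])) >= 2L
  }, logical(1))
  subset_sites(table, keep)
}
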