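#' Per-site nucleotide diversity of one diploid sample
#'
#' Nei's within-sample per-site diversity with the unbiased n/(n-1)
#' correction at n = 2 alleles: a heterozygous call contributes 1, a
#' homozygous call 0. Values are per segregating site (relative diversity),
#' not per genomic base.
#'
#' @param dosage dosage value(s) in `{0, 1, 2}` (vectorized)
#' @return numeric vector of per-site pi values
#' @export
site_pi <- function(dosage) {
  if (anyNA(dosage)) stop("site_pi expects called dosages")
  as.numeric(dosage == 1L)
}

#' Mean per-site diversity of a sample
#'
#' Mean of [site_pi()] over the sites of an already-filtered dosage matrix;
#' sites where the sample is not called are excluded.
#'
#' @param matrix a [dosage_matrix()]
#' @param sample a sample id
#' @return mean pi (heterozygous fraction) of that sample
#' @export
sample_pi <- function(matrix, sample) {
  d <- matrix$dosage[, .sample_col(matrix, sample)]
  mean(d[!is.na(d)] == 1L)
}

.sample_col <- function(matrix, sample) {
  j <- match(sample, matrix$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  j
}

#' Per-site divergence between two samples
#'
#' Mean mismatch over the four cross-sample allele pairs: with alt-allele
#' frequencies p = dosage/2 within each diploid sample, returns
#' `px (1 - py) + py (1 - px)`.
#'
#' @param dx,dy dosage values in `{0, 1, 2}` (vectorized)
#' @return per-site dXY in `[0, 1]`
#' @export
site_dxy <- function(dx, dy) {
  if (anyNA(dx) || anyNA(dy)) stop("site_dxy expects called dosages")
  px <- dx / 2
  py <- dy / 2
  px * (1 - py) + py * (1 - px)
}

#' Mean pairwise divergence between two samples
#'
#' Mean of [site_dxy()] over the sites where both samples are called.
#'
#' @param matrix a [dosage_matrix()]
#' @param sample_x,sample_y sample ids
#' @return mean dXY of the pair
#' @export
pair_dxy <- function(matrix, sample_x, sample_y) {
  dx <- matrix$dosage[, .sample_col(matrix, sample_x)]
  dy <- matrix$dosage[, .sample_col(matrix, sample_y)]
  ok <- !is.na(dx) & !is.na(dy)
  mean(site_dxy(dx[ok], dy[ok]))
}

#' Net divergence between two samples
#'
#' Nei's net number of substitutions per site: dXY minus the mean
#' within-sample diversity of the pair.
#'
#' @param dxy mean pairwise dXY
#' @param pi_x,pi_y mean pi of the two samples
#' @return dA = dxy - (pi_x + pi_y) / 2
#' @export
pair_da <- function(dxy, pi_x, pi_y) dxy - (pi_x + pi_y) / 2

#' Per-sample diversity table
#'
#' @param matrix a [dosage_matrix()]
#' @return data.frame with columns `sample`, `pi`
#' @export
diversity_table <- function(matrix) {
  data.frame(sample = matrix$samples,
             pi = vapply(matrix$samples, function(s) sample_pi(matrix, s), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' All pairwise sample divergences
#'
#' @param matrix a [dosage_matrix()]
#' @return data.frame with one row per unordered sample pair and columns
#'   `sample_x`, `sample_y`, `dxy`, `da`
#' @export
divergence_table <- function(matrix) {
  s <- matrix$samples
  pis <- vapply(s, function(x) sample_pi(matrix, x), 0)
  pairs <- utils::combn(s, 2)
  dxy <- apply(pairs, 2, function(p) pair_dxy(matrix, p[1], p[2]))
  da <- dxy - (pis[pairs[1, ]] + pis[pairs[2, ]]) / 2
  data.frame(sample_x = pairs[1, ], sample_y = pairs[2, ],
             dxy = dxy, da = as.numeric(da),
             row.names = NULL, stringsAsFactors = FALSE)
}

.mean_sd <- function(v) {
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
}

#' Aggregate per-sample values by population
#'
#' Arithmetic mean and SD (n-1 denominator) of per-sample values within each
#' population; single-sample populations report `NA` for the SD.
#'
#' @param values named numeric vector (names = sample ids) or a data.frame
#'   with columns `sample` and a single value column
#' @param pops a `pop_map`
#' @return data.frame with columns `population`, `n`, `mean`, `sd`
#' @export
aggregate_populations <- function(values, pops) {
  if (is.data.frame(values)) {
    val_col <- setdiff(names(values), "sample")
    if (length(val_col) != 1) stop("need exactly one value column")
    v <- stats::setNames(values[[val_col]], values$sample)
  } else v <- values
  miss <- setdiff(names(v), pops$sample)
  if (length(miss)) stop("samples not in population map: ",
                         paste(miss, collapse = ", "))
  pop_levels <- unique(pops$population[pops$sample %in% names(v)])
  rows <- lapply(pop_levels, function(p) {
    vv <- v[names(v) %in% pops$sample[pops$population == p]]
    ms <- .mean_sd(vv)
    data.frame(population = p, n = length(vv), mean = ms[["mean"]],
               sd = ms[["sd"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate pairwise divergences by population pair
#'
#' For each unordered population pair (including a population with itself,
#' when it has at least two samples), the mean and SD of the constituent
#' sample-pair dXY and dA values.
#'
#' @param pair_tbl output of [divergence_table()]
#' @param pops a `pop_map`
#' @return data.frame with columns `pop_x`, `pop_y`, `n_pairs`, `mean_dxy`,
#'   `sd_dxy`, `mean_da`, `sd_da`
#' @export
aggregate_divergence <- function(pair_tbl, pops) {
  px <- pops$population[match(pair_tbl$sample_x, pops$sample)]
  py <- pops$population[match(pair_tbl$sample_y, pops$sample)]
  if (anyNA(px) || anyNA(py)) stop("samples not in population map")
  key <- ifelse(px <= py, paste(px, py, sep = "\r"), paste(py, px, sep = "\r"))
  rows <- lapply(unique(key), function(k) {
    i <- key == k
    labs <- strsplit(k, "\r", fixed = TRUE)[[1]]
    mdxy <- .mean_sd(pair_tbl$dxy[i])
    mda <- .mean_sd(pair_tbl$da[i])
    data.frame(pop_x = labs[1], pop_y = labs[2], n_pairs = sum(i),
               mean_dxy = mdxy[["mean"]], sd_dxy = mdxy[["sd"]],
               mean_da = mda[["mean"]], sd_da = mda[["sd"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Population-by-population divergence matrix
#'
#' Square matrix with mean dXY above the diagonal and mean dA below it
#' (the layout of the macaw divergence table); intra-population mean dXY
#' on the diagonal where defined.
#'
#' @param agg output of [aggregate_divergence()]
#' @param order optional character vector fixing the population order
#' @return numeric matrix with population row/column names
#' @export
divergence_matrix <- function(agg, order = NULL) {
  pops <- if (is.null(order)) sort(unique(c(agg$pop_x, agg$pop_y))) else order
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_len(nrow(agg))) {
    a <- match(agg$pop_x[i], pops); b <- match(agg$pop_y[i], pops)
    if (is.na(a) || is.na(b)) next
    if (a == b) { m[a, a] <- agg$mean_dxy[i]; next }
    hi <- min(a, b); lo <- max(a, b)
    m[hi, lo] <- agg$mean_dxy[i]  # upper triangle: dXY
    m[lo, hi] <- agg$mean_da[i]   # lower triangle: dA
  }
  m
}
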