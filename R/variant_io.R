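ANNOTATION_KEYS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")

FUNCTIONAL_CLASSES <- c("four_fold_synonymous", "synonymous", "intronic",
                        "missense", "other")

#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF v4.2 file (plain or gzipped; parsing is delegated to
#' \pkg{vcfR}) into a [variant_table()]. Genotypes must be diploid and are
#' treated as unphased (`0|1` becomes `0/1`); `./.` becomes a missing
#' genotype. The six GATK-style INFO annotations (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, SOR) are read when present and recorded as absent (`NA`)
#' otherwise, as is the functional-class tag `FC` and the per-genotype `DP`.
#'
#' @param path path to a VCF file
#' @return a [variant_table()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF header in '", path,
                                         "': ", conditionMessage(e)))
  fix <- v@fix
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character(0)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  bad <- which(!is.na(gt) & !grepl("^(\\.|[0-9]+)/(\\.|[0-9]+)$", gt))
  if (length(bad)) {
    rec <- ((bad[1] - 1) %% n) + 1
    stop(sprintf("non-diploid or malformed GT '%s' at VCF record %d",
                 gt[bad[1]], rec))
  }
  gt[gt %in% c("./.", ".")] <- NA_character_
  half <- which(!is.na(gt) & grepl("\\.", gt))
  if (length(half)) {
    rec <- ((half[1] - 1) %% n) + 1
    stop(sprintf("half-missing GT '%s' at VCF record %d", gt[half[1]], rec))
  }
  split_al <- function(k) {
    out <- matrix(NA_integer_, n, length(samples))
    idx <- !is.na(gt)
    parts <- strsplit(gt[idx], "/", fixed = TRUE)
    out[idx] <- as.integer(vapply(parts, `[[`, "", k))
    out
  }
  a1 <- split_al(1L)
  a2 <- split_al(2L)
  # unordered pairs: store sorted
  swp <- !is.na(a1) & a1 > a2
  if (any(swp)) { tmp <- a1[swp]; a1[swp] <- a2[swp]; a2[swp] <- tmp }

  has_dp <- any(grepl("(^|:)DP(:|$)", v@gt[, 1]))
  depth <- if (has_dp && length(samples)) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else {
    matrix(NA_real_, n, length(samples))
  }
  storage.mode(depth) <- "integer"
  dimnames(depth) <- NULL

  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  for (k in ANNOTATION_KEYS) {
    sites[[k]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = k)))
  }
  fc <- vcfR::extract.info(v, element = "FC")
  sites$fc <- ifelse(is.na(fc), "other", fc)

  # allele indices must point at declared alleles
  nalt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  over <- which(!is.na(a2) & a2 > nalt)
  if (length(over)) {
    rec <- ((over[1] - 1) %% n) + 1
    stop(sprintf("allele index beyond declared ALT at VCF record %d", rec))
  }
  variant_table(sites, a1, a2, depth, samples)
}

#' Write a variant table as VCF v4.2
#'
#' Site annotations are written as INFO keys under their GATK names, the
#' functional class as INFO key `FC`, and per-genotype depth in FORMAT
#' (`GT:DP`). Sites are emitted sorted by (scaffold, position). Output is
#' gzip-compressed (via \pkg{vcfR}), so use a `.vcf.gz` path.
#'
#' @param table a [variant_table()]
#' @param path output path
#' @param extra_meta optional character vector of extra `##` header lines
#'   (e.g. a simulation-seed comment)
#' @return `path`, invisibly
#' @export
write_vcf <- function(table, path, extra_meta = NULL) {
  stopifnot(inherits(table, "variant_table"))
  ord <- order(table$sites$chrom, table$sites$pos)
  s <- table$sites[ord, , drop = FALSE]
  a1 <- table$a1[ord, , drop = FALSE]
  a2 <- table$a2[ord, , drop = FALSE]
  dp <- table$depth[ord, , drop = FALSE]
  n <- nrow(s)

  info <- vapply(seq_len(n), function(i) {
    kv <- character(0)
    for (k in ANNOTATION_KEYS) {
      val <- s[[k]][i]
      if (!is.na(val)) kv <- c(kv, paste0(k, "=", format(val, digits = 15,
                                                         scientific = FALSE)))
    }
    if (!is.na(s$fc[i])) kv <- c(kv, paste0("FC=", s$fc[i]))
    if (length(kv)) paste(kv, collapse = ";") else "."
  }, "")

  gt_str <- matrix(".", n, length(table$samples))
  called <- !is.na(a1)
  gt_str[called] <- paste0(a1[called], "/", a2[called])
  gt_str[!called] <- "./."
  dp_str <- ifelse(is.na(dp), ".", as.character(dp))
  cells <- matrix(paste0(gt_str, ":", dp_str), n, length(table$samples))
  colnames(cells) <- table$samples

  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos), ID = ".",
               REF = s$ref, ALT = s$alt, QUAL = ".", FILTER = ".",
               INFO = info)
  gt <- cbind(FORMAT = rep("GT:DP", n), cells)
  meta <- c("##fileformat=VCFv4.2",
            vapply(ANNOTATION_KEYS, function(k) sprintf(
              '##INFO=<ID=%s,Number=1,Type=Float,Description="%s">', k, k),
              ""),
            '##INFO=<ID=FC,Number=1,Type=String,Description="Functional class">',
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
            extra_meta)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  con <- file(path)  # probe writability early for a clear error
  tryCatch(open(con, "wb"), error = function(e)
    stop("cannot write VCF to '", path, "': ", conditionMessage(e)))
  close(con)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Convert a variant table to a dosage matrix
#'
#' Recode genotypes at biallelic sites as alt-allele counts: ref/ref -> 0,
#' ref/alt -> 1, alt/alt -> 2, missing -> NA (0 or 2 = homozygous,
#' 1 = heterozygous).
#'
#' @param table a [variant_table()] containing only biallelic sites
#' @return a [dosage_matrix()]
#' @export
to_dosage <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  if (any(n_alt_alleles(table) != 1L))
    stop("to_dosage requires biallelic sites; run select_biallelic_snps() first")
  d <- table$a1 + table$a2
  dosage_matrix(d, table$sites$chrom, table$sites$pos, table$samples)
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated file: sample id, population label. An optional
#' role assignment links the D-statistic roles P1/P2/P3/outgroup to
#' population labels via [assign_roles()].
#'
#' @param path path to the TSV file (no header)
#' @return a data.frame of class `pop_map` with columns `sample`, `population`
#' @export
read_pop_map <- function(path) {
  m <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("sample", "population"),
                         colClasses = "character")
  pop_map(m$sample, m$population)
}

#' Construct a population map
#' @param samples character vector of sample ids
#' @param populations character vector of population labels, same length
#' @return a data.frame of class `pop_map`
#' @export
pop_map <- function(samples, populations) {
  stopifnot(length(samples) == length(populations),
            !anyDuplicated(samples))
  structure(data.frame(sample = as.character(samples),
                       population = as.character(populations),
                       stringsAsFactors = FALSE),
            class = c("pop_map", "data.frame"))
}

#' Write a population map as TSV
#' @param pops a `pop_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pop_map <- function(pops, path) {
  utils::write.table(pops[, c("sample", "population")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign D-statistic roles to populations
#'
#' Each role names one or more population labels (the trio arms may pool
#' populations, e.g. two sampling countries of one subspecies form P1).
#' Role populations must be disjoint and non-empty.
#'
#' @param pops a `pop_map`
#' @param p1,p2,p3,outgroup character vectors of population labels
#' @return `pops` with a `roles` attribute (named list of label vectors)
#' @export
assign_roles <- function(pops, p1, p2, p3, outgroup) {
  roles <- list(P1 = p1, P2 = p2, P3 = p3, outgroup = outgroup)
  all_lab <- unlist(roles)
  if (anyDuplicated(all_lab))
    stop("role populations must be disjoint")
  missing <- setdiff(all_lab, pops$population)
  if (length(missing))
    stop("role names unknown populations: ", paste(missing, collapse = ", "))
  for (r in names(roles))
    if (!length(roles[[r]])) stop("role ", r, " must name at least one population")
  attr(pops, "roles") <- roles
  pops
}

#' Samples belonging to a role
#' @param pops a `pop_map` with roles assigned
#' @param role one of "P1", "P2", "P3", "outgroup"
#' @return character vector of sample ids
#' @export
role_samples <- function(pops, role) {
  roles <- attr(pops, "roles")
  if (is.null(roles)) stop("no roles assigned; see assign_roles()")
  pops$sample[pops$population %in% roles[[role]]]
}
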