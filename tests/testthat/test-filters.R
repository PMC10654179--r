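# a table of n sites with given annotation columns over a fixed genotype grid
ann_table <- function(ann) {
  n <- nrow(ann)
  sites <- toy_sites(n)
  for (k in names(ann)) sites[[k]] <- ann[[k]]
  variant_table(sites, matrix(0L, n, 2), matrix(1L, n, 2),
                matrix(30L, n, 2), c("S1", "S2"))
}

test_that("hard-filter comparisons are strict and missing annotations pass", {
  ann <- data.frame(QD = c(6.0, 5.99, NA, 10), FS = c(10, 10, 10, 10),
                    MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
                    SOR = c(2.0, 1.0, 1.0, 2.1))
  out <- apply_hard_filters(ann_table(ann))
  # QD = 6.0 retained (strict "<"), 5.99 removed, NA passes, SOR 2.1 removed
  expect_equal(out$sites$pos, ann_table(ann)$sites$pos[c(1, 3)])
})

test_that("hard-filter survivors match a brute-force evaluation of all six predicates", {
  set.seed(42)
  n <- 1000
  maybe_na <- function(x) { x[runif(n) < 0.1] <- NA; x }
  ann <- data.frame(
    QD = maybe_na(runif(n, 0, 20)), FS = maybe_na(runif(n, 0, 80)),
    MQ = maybe_na(runif(n, 50, 62)), MQRankSum = maybe_na(runif(n, -1, 1)),
    ReadPosRankSum = maybe_na(runif(n, -4, 4)),
    SOR = maybe_na(runif(n, 0, 4)))
  vt <- ann_table(ann)
  out <- apply_hard_filters(vt)
  pass1 <- function(x, bad) is.na(x) | !bad
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    keep[i] <- pass1(ann$QD[i], ann$QD[i] < 6) &&
      pass1(ann$FS[i], ann$FS[i] > 40) &&
      pass1(ann$MQ[i], ann$MQ[i] < 59) &&
      pass1(ann$MQRankSum[i], ann$MQRankSum[i] < -0.3) &&
      pass1(ann$ReadPosRankSum[i], ann$ReadPosRankSum[i] < -2) &&
      pass1(ann$SOR[i], ann$SOR[i] > 2)
  }
  expect_identical(out$sites$pos, vt$sites$pos[keep])
  expect_equal(n_sites(out), sum(keep))
})

test_that("raising a threshold can only shrink the surviving site set", {
  set.seed(43)
  ann <- data.frame(QD = runif(500, 0, 20), FS = runif(500, 0, 80),
                    MQ = runif(500, 50, 62), MQRankSum = runif(500, -1, 1),
                    ReadPosRankSum = runif(500, -4, 4), SOR = runif(500, 0, 4))
  vt <- ann_table(ann)
  loose <- apply_hard_filters(vt, filter_config(qd_min = 4))
  for (q in c(6, 8, 12)) {
    strict <- apply_hard_filters(vt, filter_config(qd_min = q))
    expect_true(all(strict$sites$pos %in% loose$sites$pos))
    loose <- strict
  }
})

test_that("depth masking is strict at the boundary and matches a direct count", {
  dos <- random_dosage(200, 3, seed = 44)
  vt <- table_from_dosage(dos)
  set.seed(45)
  vt$depth[] <- rpois(length(vt$depth), 10)
  vt$depth[1, 1] <- 7L; vt$depth[1, 2] <- 8L; vt$depth[2, 3] <- NA_integer_
  out <- mask_low_depth(vt, 8L)
  expect_true(is.na(out$a1[1, 1]))   # depth 7 -> no call
  expect_false(is.na(out$a1[1, 2]))  # depth 8 -> retained
  expect_true(is.na(out$a1[2, 3]))   # absent depth -> no call
  expect_equal(n_sites(out), n_sites(vt))  # sites retained
  expect_equal(sum(is.na(out$a1)), sum(is.na(vt$depth) | vt$depth < 8))
})

test_that("completeness filter tallies missing genotypes per site", {
  dos <- random_dosage(100, 4, p_missing = 0.05, seed = 46)
  vt <- table_from_dosage(dos)
  miss <- rowSums(is.na(dos))
  expect_equal(n_sites(require_complete(vt, 0L)), sum(miss == 0))
  expect_equal(n_sites(require_complete(vt, 1L)), sum(miss <= 1))
  one_missing <- table_from_dosage(rbind(c(0L, NA, 1L)))
  expect_equal(n_sites(require_complete(one_missing, 0L)), 0L)
})

test_that("biallelic-SNP and site-class selection keep exactly the right sites", {
  sites <- data.frame(chrom = "s1", pos = c(10L, 20L, 30L, 40L),
                      ref = c("A", "C", "AT", "G"),
                      alt = c("G", "T,A", "A", "C"))
  sites$fc <- c("intronic", "missense", "synonymous", "four_fold_synonymous")
  n <- 4
  vt <- variant_table(sites, matrix(0L, n, 2), matrix(0L, n, 2),
                      matrix(30L, n, 2), c("S1", "S2"))
  bi <- select_biallelic_snps(vt)
  expect_equal(bi$sites$pos, c(10L, 40L))  # multi-alt and indel dropped
  cls <- select_site_class(vt, c("intronic", "synonymous"))
  expect_equal(cls$sites$fc, c("intronic", "synonymous"))
  expect_equal(n_sites(select_site_class(vt, "four_fold_synonymous")), 1L)
})

test_that("non-segregating sites are dropped per the examined sample subset", {
  dos <- rbind(c(0L, 0L, 2L), c(0L, 0L, 0L), c(1L, 0L, 0L), c(2L, 2L, 2L))
  vt <- table_from_dosage(dos)
  expect_equal(n_sites(drop_nonsegregating(vt)), 2L)
  # restricting to S1+S2 makes the first site monomorphic too
  sub <- drop_nonsegregating(vt, c("S1", "S2"))
  expect_equal(sub$sites$pos, vt$sites$pos[3])
  # brute-force allele scan over a random fixture
  dosr <- random_dosage(200, 4, p_missing = 0.1, seed = 47)
  vtr <- table_from_dosage(dosr)
  seg <- apply(dosr, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0 && any(r > 0) && any(r < 2)
  })
  expect_equal(n_sites(drop_nonsegregating(vtr)), sum(seg))
})

test_that("hard filters and site-class selection commute", {
  ds <- simulate_dataset(sim_config(n_sites = 300L, seed = 48L))
  vt <- ds$table
  a <- select_site_class(apply_hard_filters(vt), c("intronic", "synonymous"))
  b <- apply_hard_filters(select_site_class(vt, c("intronic", "synonymous")))
  expect_identical(a$sites, b$sites)
  expect_identical(a$a1, b$a1)
})
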