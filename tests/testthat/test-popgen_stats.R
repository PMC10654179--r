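test_that("per-site pi is the unbiased two-allele heterozygosity", {
  expect_equal(site_pi(1L), 1.0)
  expect_equal(site_pi(0L), 0.0)
  expect_equal(site_pi(2L), 0.0)
  expect_equal(site_pi(c(0L, 1L, 2L, 1L)), c(0, 1, 0, 1))
})

test_that("sample pi is the heterozygous fraction across sites", {
  hom <- table_from_dosage(matrix(rep(c(0L, 2L), 5), ncol = 1))
  expect_equal(sample_pi(to_dosage(hom), "S1"), 0.0)
  d <- matrix(c(rep(1L, 3), rep(0L, 7)), ncol = 1)
  expect_equal(sample_pi(to_dosage(table_from_dosage(d)), "S1"), 0.3)
  dos <- random_dosage(200, 3, seed = 70)
  dm <- to_dosage(table_from_dosage(dos))
  for (s in dm$samples)
    expect_equal(sample_pi(dm, s), mean(dos[, s] == 1L))
})

test_that("per-site dXY equals enumeration over the four cross-sample allele pairs", {
  expect_equal(site_dxy(0L, 2L), 1.0)
  expect_equal(site_dxy(1L, 1L), 0.5)
  expect_equal(site_dxy(0L, 1L), 0.5)
  enumerate_dxy <- function(dx, dy) {
    ax <- c(rep(1, dx), rep(0, 2 - dx))  # the two alleles of each diploid
    ay <- c(rep(1, dy), rep(0, 2 - dy))
    mean(outer(ax, ay, `!=`))
  }
  for (dx in 0:2) for (dy in 0:2)
    expect_equal(site_dxy(dx, dy), enumerate_dxy(dx, dy))
})

test_that("pairwise dXY averages sites and the self-pair equals pi/2", {
  same <- to_dosage(table_from_dosage(cbind(c(0L, 2L, 0L), c(0L, 2L, 0L))))
  expect_equal(pair_dxy(same, "S1", "S2"), 0.0)
  dos <- random_dosage(300, 4, p_missing = 0.05, seed = 71)
  dm <- to_dosage(table_from_dosage(dos))
  for (s in dm$samples)
    expect_equal(pair_dxy(dm, s, s), sample_pi(dm, s) / 2)
  # brute force over called pairs, and symmetry
  x <- dos[, 1]; y <- dos[, 3]
  ok <- !is.na(x) & !is.na(y)
  brute <- mean((x / 2 * (1 - y / 2) + y / 2 * (1 - x / 2))[ok])
  expect_equal(pair_dxy(dm, "S1", "S3"), brute)
  expect_equal(pair_dxy(dm, "S3", "S1"), pair_dxy(dm, "S1", "S3"))
})

test_that("net divergence subtracts the mean within-sample diversity", {
  expect_equal(round(pair_da(0.2462, 0.1591, 0.1657), 4), 0.0838)
  expect_equal(pair_da(0.25, 0.25, 0.25), 0.0)
  set.seed(72)
  for (i in 1:10) {
    v <- runif(3)
    expect_equal(pair_da(v[1], v[2], v[3]), v[1] - mean(v[2:3]))
  }
})

test_that("population aggregation gives the n-1 SD and NA for singletons", {
  pops <- pop_map(sprintf("S%d", 1:6),
                  c("a", "a", "b", "b", "b", "c"))
  v <- c(S1 = 0.1287, S2 = 0.1155, S3 = 0.1741, S4 = 0.1787, S5 = 0.1706,
         S6 = 0.1548)
  agg <- aggregate_populations(v, pops)
  expect_equal(agg$mean[agg$population == "a"], mean(v[1:2]))
  expect_equal(agg$sd[agg$population == "b"], sd(v[3:5]))
  expect_true(is.na(agg$sd[agg$population == "c"]))
  expect_equal(agg$n, c(2L, 3L, 1L))
})

test_that("population mean dA is mean dXY minus the mean of mean pis", {
  ds <- simulate_dataset(sim_config(n_sites = 400L, seed = 73L))
  dm <- to_dosage(select_biallelic_snps(ds$table))
  pair <- divergence_table(dm)
  div <- diversity_table(dm)
  pops <- ds$pops
  agg <- aggregate_divergence(pair, pops)
  pi_by_pop <- aggregate_populations(
    setNames(div$pi, div$sample), pops)
  for (i in seq_len(nrow(agg))) {
    if (agg$pop_x[i] == agg$pop_y[i]) next
    mpx <- pi_by_pop$mean[pi_by_pop$population == agg$pop_x[i]]
    mpy <- pi_by_pop$mean[pi_by_pop$population == agg$pop_y[i]]
    expect_equal(agg$mean_da[i], agg$mean_dxy[i] - (mpx + mpy) / 2,
                 tolerance = 1e-12)
  }
})

test_that("intra-population divergence is below inter-population divergence on drifted data", {
  cfg <- sim_config(n_sites = 3000L, f_out = 0.4, f_stem = 0.2, f_p3 = 0.2,
                    f_p1 = 0.15, f_p2 = 0.15, seed = 74L)
  ds <- simulate_dataset(cfg)
  dm <- to_dosage(select_biallelic_snps(ds$table))
  pair <- divergence_table(dm)
  agg <- aggregate_divergence(pair, ds$pops)
  intra <- agg$mean_dxy[agg$pop_x == agg$pop_y]
  inter <- agg$mean_dxy[agg$pop_x != agg$pop_y]
  expect_true(max(intra) < min(inter))
})

test_that("the divergence matrix carries dXY above and dA below the diagonal", {
  pair <- data.frame(sample_x = c("A1", "A1", "B1"),
                     sample_y = c("A2", "B1", "A2"),
                     dxy = c(0.10, 0.30, 0.28), da = c(0.02, 0.20, 0.18))
  pops <- pop_map(c("A1", "A2", "B1"), c("a", "a", "b"))
  m <- divergence_matrix(aggregate_divergence(pair, pops), order = c("a", "b"))
  expect_equal(m["a", "a"], 0.10)            # intra-population mean dXY
  expect_equal(m["a", "b"], mean(c(0.30, 0.28)))  # dXY above diagonal
  expect_equal(m["b", "a"], mean(c(0.20, 0.18)))  # dA below diagonal
})
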