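test_that("zero drift and no pulse leave all populations at the ancestral frequency", {
  set.seed(100)
  cfg <- sim_config(n_sites = 200L, f_out = 0, f_stem = 0, f_p3 = 0,
                    f_p1 = 0, f_p2 = 0, f_introgression = 0)
  fr <- simulate_frequencies(cfg)
  expect_equal(fr$p1, fr$p2)
  expect_equal(fr$p2, fr$p3)
  expect_equal(fr$p3, fr$p4)
})

test_that("a full pulse with no post-pulse drift makes P2 identical to P3", {
  set.seed(101)
  cfg <- sim_config(n_sites = 200L, f_introgression = 1, f_p2 = 0)
  fr <- simulate_frequencies(cfg)
  expect_equal(fr$p2, fr$p3)
})

test_that("degenerate parameters are rejected", {
  expect_error(sim_config(f_p1 = 1), "\\[0, 1\\)")
  expect_error(sim_config(f_introgression = 1.2), "f_introgression")
  expect_error(sim_config(n_sites = 0), "at least one site")
  expect_error(sim_config(class_props = c(intronic = 0.5)), "sum to 1")
})

test_that("fixed frequencies produce fixed dosages", {
  cfg <- sim_config(n_sites = 50L)
  set.seed(102)
  zero <- simulate_genotypes(data.frame(p1 = rep(0, 50), p2 = 0, p3 = 0,
                                        p4 = 0), cfg)
  expect_true(all(zero$a1 == 0L & zero$a2 == 0L))
  one <- simulate_genotypes(data.frame(p1 = rep(1, 50), p2 = 1, p3 = 1,
                                       p4 = 1), cfg)
  expect_true(all(one$a1 == 1L & one$a2 == 1L))
})

test_that("empirical alt-allele frequencies track the simulated frequencies", {
  cfg <- sim_config(n_sites = 10000L, n_p1 = 10L, n_p2 = 10L, n_p3 = 10L,
                    n_out = 10L, seed = 103L)
  ds <- simulate_dataset(cfg)
  dm <- to_dosage(ds$table)
  for (role in c("p1", "p2", "p3")) {
    cols <- grep(paste0("^", role, "_"), dm$samples)
    obs <- rowMeans(dm$dosage[, cols, drop = FALSE]) / 2
    p <- ds$freqs[[role]]
    se <- sqrt(pmax(p * (1 - p), 1e-12) / (2 * length(cols)))
    inside <- abs(obs - p) <= 3 * se + 1e-12
    expect_gt(mean(inside), 0.95)
    expect_lt(abs(mean(obs - p)), 3 * sd(obs - p) / sqrt(length(p)))
  }
})

test_that("fixtures are byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "fx_a"); d2 <- file.path(tempdir(), "fx_b")
  f1 <- make_fixture("introgression", seed = 5L, dir = d1, n_sites = 300L)
  f2 <- make_fixture("introgression", seed = 5L, dir = d2, n_sites = 300L)
  for (k in names(f1))
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])))
})

test_that("the macaw-like preset mirrors the nine-sample study design", {
  f <- make_fixture("macaw_like", seed = 6L, dir = file.path(tempdir(), "mw"),
                    n_sites = 120L)
  vt <- read_vcf(f$vcf)
  pops <- read_pop_map(f$pops)
  expect_equal(length(vt$samples), 9L)
  expect_equal(n_sites(vt), 120L)
  tab <- table(pops$population)
  expect_equal(tab[["macao_cr"]], 3L)
  expect_equal(tab[["cyanoptera_cr"]], 1L)
  expect_equal(tab[["cyanoptera_gt"]], 2L)
  expect_equal(tab[["macao_br"]], 1L)
  expect_equal(tab[["chloropterus"]], 2L)
})

test_that("stronger drift increases between-population net divergence", {
  mean_inter_da <- function(f_branch, seed) {
    cfg <- sim_config(n_sites = 2000L, f_p1 = f_branch, f_p2 = f_branch,
                      f_p3 = f_branch, f_stem = f_branch, f_out = f_branch,
                      seed = seed)
    ds <- simulate_dataset(cfg)
    dm <- to_dosage(select_biallelic_snps(ds$table))
    agg <- aggregate_divergence(divergence_table(dm), ds$pops)
    mean(agg$mean_da[agg$pop_x != agg$pop_y])
  }
  das <- vapply(c(0.02, 0.1, 0.3), mean_inter_da, 0, seed = 104L)
  expect_true(all(diff(das) > 0))
})

test_that("mean sample heterozygosity matches the closed-form drift expectation", {
  # uniform ancestral law: E[het at a P1 tip] = (1 - F_p1)(1 - F_stem) / 3
  cfg <- sim_config(n_sites = 20000L, beta_a = 1, beta_b = 1,
                    f_stem = 0.1, f_p1 = 0.08, seed = 105L)
  ds <- simulate_dataset(cfg)
  dm <- to_dosage(ds$table)
  expected <- (1 - cfg$f_p1) * (1 - cfg$f_stem) / 3
  het <- dm$dosage[, "p1_1"] == 1L
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - expected), 3 * se)
})

test_that("estimated D grows with the introgression fraction", {
  d_for <- function(f, seed) {
    set.seed(seed)
    ds <- replicate(50, {
      cfg <- sim_config(n_sites = 3000L, f_introgression = f,
                        seed = sample.int(1e6, 1))
      dd <- simulate_dataset(cfg)
      dm <- to_dosage(select_biallelic_snps(dd$table))
      d_stat(dm, dd$pops)$D
    })
    mean(ds)
  }
  dbar <- vapply(c(0, 0.1, 0.2, 0.4), d_for, 0, seed = 106L)
  expect_true(all(diff(dbar) > 0))
  expect_true(all(dbar[-1] > 0))
})
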