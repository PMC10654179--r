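#' Simulation configuration for the four-population genotype generator
#'
#' Emulates the statistical structure of a small macaw-style resequencing
#' panel: a species tree (((P1, P2), P3), O), Balding-Nichols beta drift
#' along each branch, an optional P3 -> P2 introgression pulse, binomial
#' diploid genotype sampling, Poisson read depths, functional-class labels
#' and GATK-style site annotations with a contaminating fraction that
#' violates each hard-filter threshold.
#'
#' @param n_sites number of simulated variant sites
#' @param n_p1,n_p2,n_p3,n_out diploid samples per role (defaults mirror the
#'   macaw panel: 3 P1, 3 P2, 1 P3, 2 outgroup)
#' @param beta_a,beta_b ancestral alt-allele frequency law Beta(a, b)
#' @param f_out,f_stem,f_p3,f_p1,f_p2 Balding-Nichols drift parameters
#'   F in `[0, 1)` for the branches root -> outgroup, root -> ingroup stem,
#'   stem -> P3, stem -> P1 and stem -> P2 (F = 0 means no drift)
#' @param f_introgression per-site probability that the P2 lineage frequency
#'   is replaced by the P3 tip frequency before P2-branch drift
#' @param depth_mean Poisson mean of per-genotype read depth
#' @param class_props named proportions of functional classes
#' @param contam_frac fraction of sites whose value for each annotation is
#'   drawn beyond its hard-filter threshold
#' @param n_scaffolds number of scaffolds positions are spread over
#' @param seed integer seed fixing the full output bit-for-bit
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_sites = 5000L, n_p1 = 3L, n_p2 = 3L, n_p3 = 1L,
                       n_out = 2L, beta_a = 1, beta_b = 1,
                       f_out = 0.3, f_stem = 0.1, f_p3 = 0.1,
                       f_p1 = 0.05, f_p2 = 0.05, f_introgression = 0,
                       depth_mean = 30, class_props = c(
                         four_fold_synonymous = 0.10, synonymous = 0.15,
                         intronic = 0.45, missense = 0.15, other = 0.15),
                       contam_frac = 0.05, n_scaffolds = 5L, seed = 1L) {
  fs <- c(f_out, f_stem, f_p3, f_p1, f_p2)
  if (any(fs < 0) || any(fs >= 1))
    stop("drift parameters must lie in [0, 1)")
  if (f_introgression < 0 || f_introgression > 1)
    stop("f_introgression must lie in [0, 1]")
  if (n_sites < 1) stop("need at least one site")
  if (abs(sum(class_props) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  structure(list(n_sites = as.integer(n_sites), n_p1 = as.integer(n_p1),
                 n_p2 = as.integer(n_p2), n_p3 = as.integer(n_p3),
                 n_out = as.integer(n_out), beta_a = beta_a, beta_b = beta_b,
                 f_out = f_out, f_stem = f_stem, f_p3 = f_p3, f_p1 = f_p1,
                 f_p2 = f_p2, f_introgression = f_introgression,
                 depth_mean = depth_mean, class_props = class_props,
                 contam_frac = contam_frac,
                 n_scaffolds = as.integer(n_scaffolds),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols drift: p -> Beta(p (1-F)/F, (1-p)(1-F)/F); F = 0 identity.
.bn_drift <- function(p, f) {
  if (f == 0) return(p)
  out <- p
  mid <- p > 0 & p < 1
  k <- (1 - f) / f
  out[mid] <- stats::rbeta(sum(mid), p[mid] * k, (1 - p[mid]) * k)
  out
}

#' Simulate per-site population allele frequencies
#'
#' Draws ancestral frequencies from the Beta law and pushes them through the
#' tree (((P1, P2), P3), O) with Balding-Nichols drift per branch. With
#' probability `f_introgression` per site, the P2 lineage frequency at the
#' internal node is replaced by the P3 tip frequency (an introgression
#' pulse) before P2-branch drift is applied. Draws come from the current
#' RNG stream; seed at the call site (or use [simulate_dataset()]).
#'
#' @param cfg a [sim_config()]
#' @return data.frame with columns `p1`, `p2`, `p3`, `p4` (outgroup), one
#'   row per site
#' @export
simulate_frequencies <- function(cfg) {
  n <- cfg$n_sites
  p0 <- stats::rbeta(n, cfg$beta_a, cfg$beta_b)
  p4 <- .bn_drift(p0, cfg$f_out)
  p_stem <- .bn_drift(p0, cfg$f_stem)
  p3 <- .bn_drift(p_stem, cfg$f_p3)
  p1 <- .bn_drift(p_stem, cfg$f_p1)
  p2_base <- p_stem
  if (cfg$f_introgression > 0) {
    pulse <- stats::runif(n) < cfg$f_introgression
    p2_base[pulse] <- p3[pulse]
  }
  p2 <- .bn_drift(p2_base, cfg$f_p2)
  data.frame(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

# binomial(2, p) dosages for one role block: sites x n matrix
.role_dosage <- function(p, n) {
  matrix(stats::rbinom(length(p) * n, 2L, rep(p, n)), ncol = n)
}

# annotation value: passing law, with a contaminating fraction violating
# the threshold in the failing direction
.ann_values <- function(n, contam, pass_lo, pass_hi, fail_lo, fail_hi) {
  bad <- stats::runif(n) < contam
  v <- stats::runif(n, pass_lo, pass_hi)
  v[bad] <- stats::runif(sum(bad), fail_lo, fail_hi)
  v
}

#' Simulate genotypes, depths and annotations from population frequencies
#'
#' Each sample's dosage is Binomial(2, p) for its role's frequency; depths
#' are Poisson; functional classes are drawn from the configured
#' proportions; each hard-filter annotation is drawn from a passing uniform
#' law with a `contam_frac` fraction drawn beyond its threshold. Positions
#' are assigned in contiguous chunks over `n_scaffolds` scaffolds. Draws
#' come from the current RNG stream; seed at the call site.
#'
#' @param freqs output of [simulate_frequencies()]
#' @param cfg a [sim_config()]
#' @return a [variant_table()]; sample ids are `p1_1 ... p1_k, p2_1, ...,
#'   p3_1, ..., out_1, ...`
#' @export
simulate_genotypes <- function(freqs, cfg) {
  n <- nrow(freqs)
  dos <- cbind(.role_dosage(freqs$p1, cfg$n_p1),
               .role_dosage(freqs$p2, cfg$n_p2),
               .role_dosage(freqs$p3, cfg$n_p3),
               .role_dosage(freqs$p4, cfg$n_out))
  samples <- c(sprintf("p1_%d", seq_len(cfg$n_p1)),
               sprintf("p2_%d", seq_len(cfg$n_p2)),
               sprintf("p3_%d", seq_len(cfg$n_p3)),
               sprintf("out_%d", seq_len(cfg$n_out)))
  colnames(dos) <- samples

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  # contiguous chunks of sites per scaffold, positions strictly increasing
  sizes <- rep(n %/% cfg$n_scaffolds, cfg$n_scaffolds)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes <- sizes[sizes > 0]
  chrom <- rep(sprintf("scaffold_%d", seq_along(sizes)), times = sizes)
  pos <- unlist(lapply(sizes, function(k)
    cumsum(sample(1:200, k, replace = TRUE))), use.names = FALSE)

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  cf <- cfg$contam_frac
  sites$QD <- .ann_values(n, cf, 6, 35, 0, 6 - 1e-6)
  sites$FS <- .ann_values(n, cf, 0, 40, 40 + 1e-6, 100)
  sites$MQ <- .ann_values(n, cf, 59, 60, 30, 59 - 1e-6)
  sites$MQRankSum <- .ann_values(n, cf, -0.3, 0.3, -3, -0.3 - 1e-6)
  sites$ReadPosRankSum <- .ann_values(n, cf, -2, 2, -5, -2 - 1e-6)
  sites$SOR <- .ann_values(n, cf, 0, 2, 2 + 1e-6, 5)
  sites$fc <- sample(names(cfg$class_props), n, replace = TRUE,
                     prob = cfg$class_props)

  depth <- matrix(stats::rpois(n * length(samples), cfg$depth_mean),
                  nrow = n)
  a1 <- ifelse(dos == 2L, 1L, 0L)
  a2 <- ifelse(dos >= 1L, 1L, 0L)
  variant_table(sites, a1, a2, depth, samples)
}

#' Population map for a simulated dataset
#'
#' @param cfg a [sim_config()]
#' @param labels optional named list overriding the population label of each
#'   role's samples: elements `p1`, `p2`, `p3`, `out`, each a character
#'   vector of per-sample labels (recycled if length 1)
#' @return a `pop_map` with roles P1/P2/P3/outgroup assigned
#' @export
sim_pop_map <- function(cfg, labels = NULL) {
  lab <- list(p1 = "pop_p1", p2 = "pop_p2", p3 = "pop_p3", out = "pop_out")
  if (!is.null(labels)) lab[names(labels)] <- labels
  ns <- c(p1 = cfg$n_p1, p2 = cfg$n_p2, p3 = cfg$n_p3, out = cfg$n_out)
  samples <- c(sprintf("p1_%d", seq_len(ns["p1"])),
               sprintf("p2_%d", seq_len(ns["p2"])),
               sprintf("p3_%d", seq_len(ns["p3"])),
               sprintf("out_%d", seq_len(ns["out"])))
  pops <- c(rep_len(lab$p1, ns["p1"]), rep_len(lab$p2, ns["p2"]),
            rep_len(lab$p3, ns["p3"]), rep_len(lab$out, ns["out"]))
  assign_roles(pop_map(samples, pops),
               p1 = unique(rep_len(lab$p1, ns["p1"])),
               p2 = unique(rep_len(lab$p2, ns["p2"])),
               p3 = unique(rep_len(lab$p3, ns["p3"])),
               outgroup = unique(rep_len(lab$out, ns["out"])))
}

#' Simulate a complete dataset (seeded)
#'
#' Seeds the RNG from `cfg$seed` and produces frequencies, a variant table
#' and a role-annotated population map; bit-for-bit reproducible.
#'
#' @param cfg a [sim_config()]
#' @param labels optional population labels, see [sim_pop_map()]
#' @return list with elements `freqs`, `table`, `pops`, `cfg`
#' @export
simulate_dataset <- function(cfg, labels = NULL) {
  set.seed(cfg$seed)
  freqs <- simulate_frequencies(cfg)
  table <- simulate_genotypes(freqs, cfg)
  list(freqs = freqs, table = table, pops = sim_pop_map(cfg, labels), cfg = cfg)
}

#' Named simulation presets
#'
#' * `null_ils`: no introgression, symmetric P1/P2 drift — the calibration
#'   null for the D statistic.
#' * `introgression`: a P3 -> P2 pulse at f = 0.2.
#' * `macaw_like`: the 9-sample design of the macaw panel (3 Costa Rican
#'   P2 samples, 1 Costa Rican + 2 Guatemalan P1 samples, 1 Brazilian P3
#'   sample, 2 outgroup samples), no introgression.
#'
#' @param name preset id
#' @param seed integer seed
#' @param n_sites optional override of the preset's site count
#' @return a list: `cfg` ([sim_config()]) and `labels` for [sim_pop_map()]
#' @export
sim_preset <- function(name = c("null_ils", "introgression", "macaw_like"),
                       seed = 1L, n_sites = NULL) {
  name <- match.arg(name)
  labels <- NULL
  cfg <- switch(name,
    null_ils = sim_config(f_introgression = 0, seed = seed),
    introgression = sim_config(f_introgression = 0.2, seed = seed),
    macaw_like = {
      labels <- list(p1 = c("cyanoptera_cr", "cyanoptera_gt", "cyanoptera_gt"),
                     p2 = "macao_cr", p3 = "macao_br", out = "chloropterus")
      sim_config(n_p1 = 3L, n_p2 = 3L, n_p3 = 1L, n_out = 2L,
                 f_introgression = 0, seed = seed)
    })
  if (!is.null(n_sites)) cfg$n_sites <- as.integer(n_sites)
  list(cfg = cfg, labels = labels)
}

#' Write a named fixture to disk
#'
#' Simulates a preset and writes a VCF (gzipped, with the seed recorded in
#' a header line), a population-map TSV, and a JSON sidecar of the true
#' simulation parameters for recovery tests. Deterministic given the seed.
#'
#' @param name preset id, see [sim_preset()]
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @param n_sites optional override of the preset's site count
#' @return named list of the three file paths, invisibly
#' @export
make_fixture <- function(name, seed = 1L, dir = ".", n_sites = NULL) {
  pr <- sim_preset(name, seed = seed, n_sites = n_sites)
  ds <- simulate_dataset(pr$cfg, pr$labels)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, paste0(name, ".vcf.gz"))
  tsv <- file.path(dir, paste0(name, ".pops.tsv"))
  js <- file.path(dir, paste0(name, ".params.json"))
  write_vcf(ds$table, vcf,
            extra_meta = sprintf("##simulation_seed=%d", as.integer(seed)))
  write_pop_map(ds$pops, tsv)
  pars <- unclass(ds$cfg)
  pars$class_props <- as.list(pars$class_props)
  pars$preset <- name
  jsonlite::write_json(pars, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(vcf = vcf, pops = tsv, params = js))
}
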