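---
title: "Methods: filtering, diversity, clustering and introgression statistics for small resequencing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, diversity, clustering and introgression statistics for small resequencing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`macawpop` implements the post-variant-calling stages of a small-panel
population-genomic study — the kind of analysis used to compare scarlet
macaw (*Ara macao*) subspecies with a handful of resequenced genomes per
population. It consumes a genotyped multi-sample VCF (the product of an
upstream mapping/genotyping pipeline) plus a sample-to-population map, and
provides: composable site and genotype filters, windowed r² LD thinning,
Nei-style diversity and divergence statistics, genotype PCA, the
frequency-weighted ABBA/BABA D statistic with block-jackknife significance,
and a genotype simulator so that the whole pipeline is testable without any
sequence data. This vignette records the models, conventions and design
choices.

## Data model

A `variant_table` holds per-site metadata (scaffold, 1-based position,
ref/alt alleles, the six GATK site annotations QD, FS, MQ, MQRankSum,
ReadPosRankSum, SOR, and a functional class) and per-genotype allele pairs
and read depths. Functional class is carried as a single VCF INFO key
(`FC`, one of `four_fold_synonymous`, `synonymous`, `intronic`, `missense`,
`other`) rather than re-derived from codon degeneracy: annotation is an
upstream concern, and the analyses consume class labels only. Genotypes
are diploid and unphased; a phased `0|1` is accepted and treated as `0/1`.
Biallelic genotypes are recoded to a `dosage_matrix` of alt-allele counts
(0 or 2 = homozygous, 1 = heterozygous, `NA` = missing), the representation
every statistic operates on.

## Filters

`apply_hard_filters()` removes a site when QD < 6, FS > 40, MQ < 59,
MQRankSum < −0.3, ReadPosRankSum < −2 or SOR > 2 (defaults of
`filter_config()`; all six comparisons strict). A site lacking a given
annotation passes that single criterion. This mirrors how GATK's
`VariantFiltration` treats absent keys and is a deliberate, documented
assumption: rank-sum annotations are undefined at sites without
heterozygous reference reads, and silently dropping such sites would bias
the retained set.

`mask_low_depth()` turns genotypes below a depth threshold into no-calls
(8× for marker selection; 15× for diversity sites, where miscalled
heterozygosity directly inflates π). An absent depth is treated as
insufficient evidence and masked. `require_complete()` keeps sites with at
most `max_nocall` missing genotypes (0 by default: every sample
genotyped). `select_biallelic_snps()`, `select_site_class()` and
`drop_nonsegregating()` finish the chain; "segregating" means at least two
distinct alleles observed among the called genotypes of the examined
samples.

Three shipped recipes (`recipe_params()`) fix the stage order
SNP-select → hard filters → depth mask → completeness → biallelic →
class → segregating (→ LD prune), differing only in parameters:
`phylo_markers` (8×, 4-fold synonymous, pruned), `neutral_markers` (8×,
intronic + synonymous, pruned) and `diversity_sites` (15×, intronic +
synonymous, unpruned). The order follows the narrative order of the
original workflow; because the hard filters and the class/biallelic
selections act on disjoint site predicates they commute, and the tests
check this.

## LD thinning

`ld_prune()` reimplements PLINK-style `--indep-pairwise 50 10 0.5`
semantics: per scaffold, a sliding window of 50 currently-kept SNPs
advanced in 10-SNP increments; while any pair inside the window has
squared Pearson correlation of dosages above 0.5, one SNP of the offending
pair is removed. Missing dosages are pairwise-deleted; a pair with a
constant member contributes r² = 0 (no linkage evidence). Two dialect
choices differ from PLINK and are intentional:

* the *later-positioned* SNP of an offending pair is always removed
  (PLINK's victim choice depends on a MAF heuristic the original methods do
  not state); this makes output deterministic and oracle-testable, and
* window sweeps repeat until a full pass removes nothing, which guarantees
  the contract "no kept pair that ever shared a window exceeds the
  threshold" and makes pruning idempotent.

With the window at least as large as the scaffold, the procedure provably
reduces to a forward greedy scan (keep a SNP unless it conflicts with an
earlier kept SNP), which the test suite exploits as a brute-force oracle.

## Diversity and divergence

Per-site, per-sample diversity uses Nei's within-individual heterozygosity
with the unbiased n/(n−1) correction at n = 2 alleles: a heterozygous site
contributes π = 1, a homozygous site 0 (`site_pi()`). The uncorrected
2p(1−p) would give 0.5 per heterozygous site; whether the original custom
script applied the correction is not recoverable, so the corrected form was
chosen and documented. All divergence identities reported here
(d_A = d_XY − mean π) are invariant to that choice as long as one
convention is used throughout, which the package enforces. A sample's π
(`sample_pi()`) is the mean over the filtered sites — a *relative*
diversity over segregating sites, not per-base genomic diversity (the
denominator of all genomic sites is out of scope).

Between samples X and Y, per-site divergence is the mean mismatch over the
four cross-sample allele pairs, `site_dxy()` = p_x(1−p_y) + p_y(1−p_x) with
p = dosage/2, averaged over sites where both samples are called
(`pair_dxy()`). Net divergence `pair_da()` is d_XY − (π_X + π_Y)/2. The
identity `pair_dxy(X, X) = sample_pi(X)/2` holds exactly and is tested.
Population-level summaries are arithmetic means with n−1 standard
deviations over member samples (or member sample pairs); singleton groups
report no SD. `divergence_matrix()` lays out mean d_XY above and mean d_A
below the diagonal, the layout of the published divergence table, at the
4-decimal precision those tables print.

## PCA

`pca_genotypes()` follows the PLINK variance-standardized convention:
sites are mean-imputed (missingness is rare after the completeness filter),
centered by mean dosage and scaled by sqrt(2p̂(1−p̂)); monomorphic sites are
dropped. The sample × sample covariance (divided by the number of sites)
is eigendecomposed; coordinates are eigenvectors scaled by the square root
of their eigenvalues, and each component reports eigenvalue/trace as its
variance fraction. Signs are fixed by making each eigenvector's
largest-magnitude entry positive. Published variance percentages from the
real data depend on PLINK's internal denominator conventions and the real
genotypes; the package reports eigenvalue/trace and makes no attempt to
match those numbers.

## ABBA/BABA D and the block jackknife

For roles (P1, P2, P3, outgroup) — each of which may pool several
population labels, as when two sampling countries of one subspecies form a
single arm — `pop_freqs()` computes per-site alt-allele frequencies as
allele counts over called genotypes, skipping sites where any role is
entirely uncalled. The frequency-weighted pattern sums are

* ABBA = Σ (1−p1) p2 p3 (1−p4),
* BABA = Σ p1 (1−p2) p3 (1−p4),
* concordant = Σ p1 p2 (1−p3) (1−p4),

and D = (ABBA − BABA)/(ABBA + BABA). The concordant pattern is reported
under the label AABB, following the usage of the macaw study (the
conventional frequency estimator calls the same quantity BBAA). No
ancestral repolarization is performed: the (1−p4) factor downweights sites
where the outgroup carries the alt allele. Roles are taken as given and D
is signed — positive D means excess P2–P3 sharing — rather than reordered
to force D ≥ 0, preserving the directional hypothesis being tested.

Significance uses a block jackknife over contiguous genome-order blocks:
`floor(n/num_blocks)` sites per block with the remainder spread over the
first blocks (20 blocks by default; the exact block-size arithmetic of
other tools is not reproduced). The SE is the delete-m_j weighted
jackknife of Busing, Meijer & van der Leeden (1999), which reduces exactly
to the ordinary delete-one-block jackknife for equal blocks — the oracle
the tests use. Z = D/SE and p = 2(1 − Φ(|Z|)).

```{r dstat-example}
library(macawpop)
fx <- make_fixture("introgression", seed = 1, dir = tempdir())
vt <- read_vcf(fx$vcf)
res <- run_recipe(vt, "neutral_markers", overrides = list(prune = FALSE))
pops <- read_pop_map(fx$pops)
pops <- assign_roles(pops, p1 = "pop_p1", p2 = "pop_p2", p3 = "pop_p3",
                     outgroup = "pop_out")
d_stat(res$dosage, pops)
```

## The simulator

`simulate_frequencies()` uses the Balding–Nichols model: an ancestral
frequency p₀ ~ Beta(a, b) drifts along each branch of
(((P1, P2), P3), O) as p → Beta(p(1−F)/F, (1−p)(1−F)/F), a mean-preserving
transform whose variance grows with F ∈ [0, 1). Five branch parameters
cover root → outgroup, root → ingroup stem, and the three tip branches;
introgression is a per-site pulse replacing the P2 lineage frequency with
the P3 tip frequency with probability f before P2-branch drift.
`simulate_genotypes()` then draws Binomial(2, p) dosages per sample,
Poisson depths, class labels, and annotation values from per-filter uniform
laws with a configurable contaminating fraction beyond each threshold.

Defaults are chosen to resemble the macaw panel: 3 + 3 + 1 + 2 samples per
role (the `macaw_like` preset labels them as the three Costa Rican
*A. m. macao*, one Costa Rican + two Guatemalan *A. m. cyanoptera*, one
Brazilian *A. m. macao* and two outgroup samples), a uniform Beta(1, 1)
ancestral law for segregating sites, moderate tip drift (F = 0.05 on the
sister branches, 0.1 on the P3 branch and stem, 0.3 to the outgroup,
giving tip-vs-outgroup divergence clearly above within-ingroup
divergence), mean depth 30×, and 5% annotation contamination per filter so
every filter has work to do. These were fixed once as plausible values for
a study of this design.

What the simulator deliberately does **not** emulate: linkage (sites are
exchangeable, so LD pruning on simulated data removes only chance
correlations — real data have local LD structure); recombination maps;
selection (class labels are independent of the genotype process, so
"neutral" site selection changes counts but not frequencies); within-role
substructure (all samples of a role share one population frequency, so the
two *cyanoptera* sampling countries are statistically identical); and
mitochondrial data. Passing tests therefore demonstrate the correctness of
the statistics and their calibration under drift/ILS — not that the
pipeline recovers the published estimates from the real reads, which would
require the archived sequence data.

Choosing beta drift over coalescent or Wright–Fisher machinery keeps the
null exact and fast: under f = 0 with symmetric P1/P2 drift the expected
ABBA and BABA sums are equal by exchangeability, so the D statistic's
type-I calibration can be measured precisely. The test suite runs 200
replicates of 5,000 sites and requires the p ≤ 0.05 rejection rate to fall
in [0.02, 0.09] and mean D within 3 Monte-Carlo SE of 0, plus positive and
monotone mean D under pulses f ∈ {0.1, 0.2, 0.4}. Other problem sizes in
the suite (hundreds to a few thousand sites) were likewise chosen as the
smallest giving stable statistical checks.

## Numerical conventions and degenerate inputs

* All hard-filter comparisons strict; absent annotation passes its single
  criterion; absent depth masks the genotype.
* r² with fewer than 2 complete pairs is an error in `pairwise_r2()`;
  inside pruning windows an undefined correlation counts as 0.
* Dosage recoding refuses multi-allelic sites rather than guessing.
* PCA clips `n_components` to samples − 1 with a warning; an all-monomorphic
  matrix is an error; tiny negative eigenvalues (within 1e−9) are clamped
  to zero.
* D is an error when ABBA + BABA = 0, as is a jackknife with fewer sites
  than blocks or fewer than 2 blocks.
* The simulator rejects F = 1 and any class proportions not summing to 1;
  every fixture records its seed in the VCF header and sidecar JSON, and a
  fixed seed reproduces files byte-for-byte.

## Interfaces

The package's functions are the interface; the `analysis/` directory of
the source repository holds numbered driver scripts (simulate → filter →
diversity → PCA → D → calibration) that run the whole workflow over the
built-in presets and write tables under `results/`. `run_recipe_files()`
is the one-call entry point for a user VCF + population map, writing the
per-stage site-count ledger, filtered VCF, statistics tables and a
provenance record (package version, parameters, input digests) so a run
can be reproduced exactly.
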