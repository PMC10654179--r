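#' Shipped filtering recipes
#'
#' The three marker sets of the macaw analyses differ only in filter
#' composition; each recipe fixes the stage chain
#' SNP-select -> hard filters -> depth mask -> completeness -> biallelic ->
#' class -> segregating (-> LD prune), with these parameters:
#'
#' * `phylo_markers`: depth 8x, no missing calls, 4-fold synonymous sites,
#'   LD-pruned (the phylogenetic marker set).
#' * `neutral_markers`: depth 8x, no missing calls, intronic + synonymous
#'   sites, segregating after optional sample removal, LD-pruned (the
#'   clustering / D-statistic set).
#' * `diversity_sites`: depth 15x, no missing calls, biallelic, intronic +
#'   synonymous, segregating; no LD pruning (the diversity/divergence set).
#'
#' @param recipe recipe id
#' @return a list of stage parameters
#' @export
recipe_params <- function(recipe = c("phylo_markers", "neutral_markers",
                                     "diversity_sites")) {
  recipe <- match.arg(recipe)
  switch(recipe,
    phylo_markers = list(depth_min = 8L, max_nocall = 0L,
                         classes = "four_fold_synonymous",
                         segregating = TRUE, prune = TRUE),
    neutral_markers = list(depth_min = 8L, max_nocall = 0L,
                           classes = c("intronic", "synonymous"),
                           segregating = TRUE, prune = TRUE),
    diversity_sites = list(depth_min = 15L, max_nocall = 0L,
                           classes = c("intronic", "synonymous"),
                           segregating = TRUE, prune = FALSE))
}

#' Run a filtering recipe over a variant table
#'
#' Executes the fixed stage chain with the recipe's parameters (any of
#' which `overrides` may replace) and records the site count after every
#' stage. Samples in `drop_samples` are removed before the segregating
#' filter, mirroring the outgroup-removal steps of the clustering analyses.
#'
#' @param table a [variant_table()]
#' @param recipe recipe id, see [recipe_params()]
#' @param overrides named list of parameter overrides (`depth_min`,
#'   `max_nocall`, `classes`, `segregating`, `prune`, `window`, `step`,
#'   `r2_max`, plus any [filter_config()] threshold)
#' @param drop_samples sample ids to remove before the segregating filter
#' @return list of class `recipe_result`: `table` (filtered), `dosage`
#'   (a [dosage_matrix()] of the final sites), `counts` (data.frame of
#'   per-stage site counts), `recipe`, `params`
#' @export
run_recipe <- function(table, recipe = c("phylo_markers", "neutral_markers",
                                         "diversity_sites"),
                       overrides = list(), drop_samples = NULL) {
  recipe <- match.arg(recipe)
  par <- utils::modifyList(recipe_params(recipe), overrides)
  hard_keys <- c("qd_min", "fs_max", "mq_min", "mqranksum_min",
                 "readpos_min", "sor_max")
  hard <- do.call(filter_config, par[intersect(names(par), hard_keys)])

  counts <- data.frame(stage = "input", sites = n_sites(table),
                       stringsAsFactors = FALSE)
  step <- function(tab, name, fn) {
    out <- fn(tab)
    counts <<- rbind(counts, data.frame(stage = name, sites = n_sites(out)))
    out
  }
  t1 <- step(table, "snp_select", select_snps)
  t1 <- step(t1, "hard_filters", function(x) apply_hard_filters(x, hard))
  t1 <- step(t1, sprintf("depth_mask_%dx", par$depth_min),
             function(x) mask_low_depth(x, par$depth_min))
  t1 <- step(t1, "complete", function(x) require_complete(x, par$max_nocall))
  t1 <- step(t1, "biallelic", select_biallelic_snps)
  t1 <- step(t1, "site_class", function(x) select_site_class(x, par$classes))
  if (!is.null(drop_samples)) {
    keep <- setdiff(t1$samples, drop_samples)
    t1 <- step(t1, "drop_samples", function(x) subset_samples(x, keep))
  }
  if (isTRUE(par$segregating))
    t1 <- step(t1, "segregating", drop_nonsegregating)
  dm <- to_dosage(t1)
  if (isTRUE(par$prune)) {
    pc <- prune_config(window = par$window %||% 50L,
                       step = par$step %||% 10L,
                       r2_max = par$r2_max %||% 0.5)
    kept <- ld_prune(dm, pc)
    t1 <- subset_sites(t1, kept)
    dm <- subset_dosage(dm, kept)
    counts <- rbind(counts, data.frame(stage = "ld_prune", sites = n_sites(t1)))
  }
  structure(list(table = t1, dosage = dm, counts = counts,
                 recipe = recipe, params = par),
            class = "recipe_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a recipe end-to-end from files and write its report bundle
#'
#' Reads a VCF and population map, runs [run_recipe()], and writes the
#' filtered VCF, the per-stage site-count ledger, the recipe's terminal
#' statistics tables and a machine-readable provenance record into
#' `out_dir`:
#'
#' * all recipes: `site_counts.tsv`, `filtered.vcf.gz`, `provenance.json`;
#' * `diversity_sites`: per-sample `diversity.tsv`, per-pair
#'   `divergence_pairs.tsv`, population-aggregated `divergence_pops.tsv`
#'   and the dXY/dA `divergence_matrix.tsv`;
#' * `neutral_markers`: `pca_scores.tsv`, `pca_variance.tsv`, and (when the
#'   population map has roles) the one-row `dstat.tsv`.
#'
#' Outputs are deterministic: the same inputs and parameters give
#' byte-identical files.
#'
#' @param vcf_path input VCF
#' @param pop_path population-map TSV
#' @param recipe recipe id, see [recipe_params()]
#' @param out_dir output directory (created)
#' @param overrides,drop_samples passed to [run_recipe()]
#' @param roles optional named list (`p1`, `p2`, `p3`, `outgroup` label
#'   vectors) enabling the D-statistic output
#' @param n_components PCA components written for `neutral_markers`
#' @return the `recipe_result`, invisibly, with an `outputs` element of
#'   written paths
#' @export
run_recipe_files <- function(vcf_path, pop_path,
                             recipe = c("phylo_markers", "neutral_markers",
                                        "diversity_sites"),
                             out_dir, overrides = list(),
                             drop_samples = NULL, roles = NULL,
                             n_components = 2L) {
  recipe <- match.arg(recipe)
  table <- read_vcf(vcf_path)
  pops <- read_pop_map(pop_path)
  if (!is.null(roles))
    pops <- assign_roles(pops, roles$p1, roles$p2, roles$p3, roles$outgroup)
  res <- run_recipe(table, recipe, overrides, drop_samples)
  if (n_sites(res$table) == 0)
    stop("recipe '", recipe, "' left no sites: empty result")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- list()
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  out$site_counts <- wtsv(res$counts, "site_counts.tsv")
  out$vcf <- write_vcf(res$table, file.path(out_dir, "filtered.vcf.gz"))

  keep_pops <- pops[pops$sample %in% res$table$samples, , drop = FALSE]
  if (recipe == "diversity_sites") {
    div <- diversity_table(res$dosage)
    div$pi <- round(div$pi, 4)
    out$diversity <- wtsv(div, "diversity.tsv")
    pair <- divergence_table(res$dosage)
    pair$dxy <- round(pair$dxy, 4); pair$da <- round(pair$da, 4)
    out$divergence_pairs <- wtsv(pair, "divergence_pairs.tsv")
    agg <- aggregate_divergence(divergence_table(res$dosage), keep_pops)
    num <- vapply(agg, is.numeric, TRUE)
    agg[num] <- lapply(agg[num], round, 4)
    out$divergence_pops <- wtsv(agg, "divergence_pops.tsv")
    m <- divergence_matrix(aggregate_divergence(divergence_table(res$dosage),
                                                keep_pops))
    out$divergence_matrix <- wtsv(
      data.frame(population = rownames(m), round(m, 4), check.names = FALSE),
      "divergence_matrix.tsv")
  }
  if (recipe == "neutral_markers") {
    pca <- pca_genotypes(res$dosage, n_components)
    out$pca_scores <- wtsv(
      data.frame(sample = rownames(pca$scores), pca$scores,
                 check.names = FALSE), "pca_scores.tsv")
    out$pca_variance <- wtsv(
      data.frame(component = paste0("PC", seq_along(pca$eigenvalues)),
                 eigenvalue = pca$eigenvalues,
                 var_frac = pca$var_frac), "pca_variance.tsv")
    if (!is.null(attr(pops, "roles"))) {
      ds <- d_stat(res$dosage, pops)
      out$dstat <- wtsv(dstat_row(ds), "dstat.tsv")
    }
  }
  out$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(package = "macawpop",
         version = as.character(utils::packageVersion("macawpop")),
         recipe = recipe,
         params = res$params,
         drop_samples = drop_samples,
         inputs = list(
           vcf = list(path = vcf_path,
                      md5 = unname(tools::md5sum(vcf_path))),
           pop_map = list(path = pop_path,
                          md5 = unname(tools::md5sum(pop_path))))),
    out$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$outputs <- out
  invisible(res)
}
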