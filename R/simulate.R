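#' Configuration for the multi-study expression simulator
#'
#' Describes a set of independent two-group (case vs control) expression
#' studies simulated directly on the log2 scale. Defaults mirror a typical
#' five-study transplant-rejection compendium: five platforms with
#' case/control sizes 7/27, 3/6, 18/14, 7/10 and 18/8, redundant probes per
#' gene, and platform-specific missing genes.
#'
#' @param n_genes number of genes in the simulated genome.
#' @param study_sizes list of `c(n_case, n_control)` integer pairs, one per
#'   study; every group must have at least 2 samples.
#' @param de_fraction fraction of genes planted as differentially expressed
#'   (ignored when `de_gene_source` supplies an explicit gene set).
#' @param de_gene_source `"random"`, or a character vector of gene ids (a
#'   signature) whose members receive the planted effects.
#' @param effect_size mean planted shift, log2 units (case minus control).
#' @param effect_sd between-gene SD of the planted shift, log2 units.
#' @param effect_direction `"both"` (random sign per gene), `"up"`, or
#'   `"down"`.
#' @param noise_sd within-group residual SD, log2 units; must be positive.
#' @param probes_per_gene integer pair `c(min, max)`; the number of probes
#'   interrogating a gene on a given platform is uniform on that range.
#' @param missing_gene_prob per-study probability that a gene is absent from
#'   the platform, in `[0, 1)`.
#' @param baseline_mean,baseline_sd distribution of gene-level baseline
#'   log2 expression.
#' @param probe_sd SD of the probe-specific affinity offset around the gene
#'   baseline, log2 units.
#' @param seed master integer seed; per-study substreams are derived from it.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_studies()], [null_config()]
#' @export
sim_config <- function(n_genes = 5000,
                       study_sizes = list(c(7L, 27L), c(3L, 6L), c(18L, 14L),
                                          c(7L, 10L), c(18L, 8L)),
                       de_fraction = 0.1,
                       de_gene_source = "random",
                       effect_size = 1,
                       effect_sd = 0.25,
                       effect_direction = c("both", "up", "down"),
                       noise_sd = 0.7,
                       probes_per_gene = c(1L, 3L),
                       missing_gene_prob = 0.1,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       probe_sd = 0.25,
                       seed = 1L) {
  effect_direction <- match.arg(effect_direction)
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stopf("invalid sim_config field 'n_genes': must be a positive count")
  if (!is.list(study_sizes) || length(study_sizes) < 1L)
    stopf("invalid sim_config field 'study_sizes': need at least one study")
  for (s in study_sizes) {
    if (length(s) != 2L || any(!is.finite(s)) || any(s < 2))
      stopf("invalid sim_config field 'study_sizes': each study needs c(n_case, n_control) with both >= 2")
  }
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction > 1)
    stopf("invalid sim_config field 'de_fraction': must lie in [0, 1]")
  if (!is.character(de_gene_source))
    stopf("invalid sim_config field 'de_gene_source': must be \"random\" or a character vector of gene ids")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stopf("invalid sim_config field 'noise_sd': must be positive")
  if (length(probes_per_gene) != 2L || any(probes_per_gene < 1) ||
      probes_per_gene[2] < probes_per_gene[1])
    stopf("invalid sim_config field 'probes_per_gene': need c(min, max) with 1 <= min <= max")
  if (!is.numeric(missing_gene_prob) || missing_gene_prob < 0 || missing_gene_prob >= 1)
    stopf("invalid sim_config field 'missing_gene_prob': must lie in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("invalid sim_config field 'seed': must be a single integer")
  structure(list(
    n_genes = as.integer(n_genes),
    study_sizes = lapply(study_sizes, as.integer),
    de_fraction = de_fraction,
    de_gene_source = de_gene_source,
    effect_size = effect_size,
    effect_sd = effect_sd,
    effect_direction = effect_direction,
    noise_sd = noise_sd,
    probes_per_gene = as.integer(probes_per_gene),
    missing_gene_prob = missing_gene_prob,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    probe_sd = probe_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Null (no-effect) simulation configuration
#'
#' A convenience configuration for calibration runs: no planted effects, the
#' default five-study sizes, exactly one probe per gene and no missing genes.
#'
#' @param n_genes number of genes.
#' @param seed master integer seed.
#' @return a `sim_config` with `de_fraction = 0`.
#' @export
null_config <- function(n_genes, seed) {
  sim_config(n_genes = n_genes, de_fraction = 0,
             probes_per_gene = c(1L, 1L), missing_gene_prob = 0,
             seed = seed)
}

#' Simulate a multi-study expression compendium with ground truth
#'
#' Generates one [expression_study] per entry of `config$study_sizes`.
#' Control samples are gene baseline + probe offset + Gaussian noise; case
#' samples are additionally shifted by the gene's planted effect. Probes of
#' one gene share its effect but receive independent noise. Effects are
#' drawn once per gene and shared across studies (a fixed-effects world).
#' A gene may be absent from a study's platform; every gene is guaranteed
#' present in at least one study.
#'
#' @param config a [sim_config()].
#' @return a list with components:
#'   \describe{
#'     \item{studies}{list of [expression_study] objects (`S1`, `S2`, ...).}
#'     \item{probe_map}{data.frame with columns `study_id`, `probe_id`,
#'       `gene_id` mapping every simulated probe to its gene.}
#'     \item{truth}{a `sim_truth` list: `de_genes` (character),
#'       `true_effect` (named numeric over all genes, log2 case minus
#'       control), `presence` (genes x studies logical matrix).}
#'   }
#'   Identical configurations (including seed) give bit-identical output.
#' @export
simulate_studies <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))
  n_studies <- length(config$study_sizes)
  study_ids <- sprintf("S%d", seq_len(n_studies))

  # gene-level draws under the master seed
  set.seed(config$seed)
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  names(baseline) <- gene_ids
  if (identical(config$de_gene_source, "random")) {
    n_de <- round(config$de_fraction * n)
    de_genes <- if (n_de > 0) sort(sample(gene_ids, n_de)) else character(0)
  } else {
    de_genes <- sort(intersect(config$de_gene_source, gene_ids))
  }
  true_effect <- setNames(numeric(n), gene_ids)
  if (length(de_genes) > 0) {
    magnitude <- rnorm(length(de_genes), config$effect_size, config$effect_sd)
    sign <- switch(config$effect_direction,
                   both = sample(c(-1, 1), length(de_genes), replace = TRUE),
                   up = rep(1, length(de_genes)),
                   down = rep(-1, length(de_genes)))
    true_effect[de_genes] <- sign * magnitude
  }

  presence <- matrix(TRUE, n, n_studies, dimnames = list(gene_ids, study_ids))
  studies <- vector("list", n_studies)
  names(studies) <- study_ids
  maps <- vector("list", n_studies)

  for (i in seq_len(n_studies)) {
    set.seed(substream_seed(config$seed, i))
    if (config$missing_gene_prob > 0)
      presence[, i] <- rbinom(n, 1L, 1 - config$missing_gene_prob) == 1L
  }
  # every gene must appear on at least one platform (deterministic repair)
  orphan <- which(rowSums(presence) == 0L)
  if (length(orphan) > 0)
    presence[cbind(orphan, 1L + (orphan - 1L) %% n_studies)] <- TRUE

  for (i in seq_len(n_studies)) {
    set.seed(substream_seed(config$seed, n_studies + i))
    sz <- config$study_sizes[[i]]
    n_case <- sz[1]; n_control <- sz[2]
    present <- gene_ids[presence[, i]]
    n_probes <- if (config$probes_per_gene[1] == config$probes_per_gene[2]) {
      rep(config$probes_per_gene[1], length(present))
    } else {
      sample(config$probes_per_gene[1]:config$probes_per_gene[2],
             length(present), replace = TRUE)
    }
    row_gene <- rep(present, n_probes)
    probe_ids <- sprintf("%s_%s_p%d", study_ids[i], row_gene,
                         sequence(n_probes))
    n_rows <- length(probe_ids)
    n_samp <- n_case + n_control
    probe_base <- baseline[row_gene] + rnorm(n_rows, 0, config$probe_sd)
    m <- probe_base +
      matrix(rnorm(n_rows * n_samp, 0, config$noise_sd), n_rows, n_samp)
    m[, seq_len(n_case)] <- m[, seq_len(n_case)] + true_effect[row_gene]
    dimnames(m) <- list(probe_ids,
                        c(sprintf("%s_AR%d", study_ids[i], seq_len(n_case)),
                          sprintf("%s_STA%d", study_ids[i], seq_len(n_control))))
    groups <- c(rep("case", n_case), rep("control", n_control))
    studies[[i]] <- expression_study(study_ids[i], m, groups)
    maps[[i]] <- data.frame(study_id = study_ids[i], probe_id = probe_ids,
                            gene_id = row_gene, row.names = NULL)
  }

  truth <- structure(list(de_genes = de_genes, true_effect = true_effect,
                          presence = presence), class = "sim_truth")
  list(studies = studies,
       probe_map = do.call(rbind, maps),
       truth = truth)
}

#' Write a simulated compendium to disk in the pipeline's TSV formats
#'
#' Writes, per study, an expression matrix TSV and a sample annotation TSV,
#' plus one probe map TSV, a ground-truth TSV (`gene_id`, `is_de`,
#' `true_effect`) and a manifest TSV that [run_pipeline()] can consume.
#'
#' @param sim result of [simulate_studies()].
#' @param dir output directory, created if needed.
#' @return (invisibly) the path of the manifest TSV.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim$studies, function(st) {
    expr <- file.path(dir, paste0(st$study_id, "_expression.tsv"))
    annot <- file.path(dir, paste0(st$study_id, "_samples.tsv"))
    write_expression_study(st, expr, annot)
    data.frame(study_id = st$study_id, expression = expr, annotation = annot)
  })
  manifest <- do.call(rbind, rows)
  map_path <- file.path(dir, "probe_map.tsv")
  write_probe_map(sim$probe_map, map_path)
  manifest$probe_map <- map_path
  truth <- data.frame(gene_id = names(sim$truth$true_effect),
                      is_de = names(sim$truth$true_effect) %in% sim$truth$de_genes,
                      true_effect = unname(sim$truth$true_effect))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}
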