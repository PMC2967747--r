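#' A named gene signature
#'
#' A set of gene identifiers (e.g. an MSigDB set such as IMMUNE RESPONSE)
#' used as the positive class when evaluating a gene ranking.
#'
#' @param name signature name.
#' @param genes character vector of gene ids; duplicates are removed.
#' @return object of class `gene_signature` with elements `name`, `genes`.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stopf("signature '%s' is empty", name)
  structure(list(name = as.character(name), genes = genes),
            class = "gene_signature")
}

#' Rank genes by a meta-analysis criterion
#'
#' `"meta_fc_abs"` ranks by the absolute meta fold-change, descending
#' (magnitude of effect, either direction); `"meta_p"` ranks by the meta
#' p-value, ascending (most significant first). Ties are broken by
#' `gene_id`. The returned score is oriented so that larger means higher
#' priority (for `"meta_p"` the score is `-log10(meta_p)`).
#'
#' @param results gene-level meta results from [combine_all()].
#' @param criterion `"meta_fc_abs"` or `"meta_p"`.
#' @return data.frame of class `gene_ranking` with columns `gene_id`,
#'   `score`, ordered best first; the criterion is kept in
#'   `attr(, "criterion")`.
#' @export
rank_genes <- function(results, criterion = c("meta_fc_abs", "meta_p")) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stopf("rank_genes: need a non-empty results table")
  criterion <- match.arg(criterion)
  score <- switch(criterion,
                  meta_fc_abs = abs(results$meta_fc),
                  meta_p = -log10(clip_pvalues(results$meta_p)))
  ord <- order(-score, results$gene_id)
  out <- data.frame(gene_id = results$gene_id[ord], score = score[ord],
                    row.names = NULL)
  attr(out, "criterion") <- criterion
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' ROC curve of a gene ranking against a signature
#'
#' Sweeps the ranking's score thresholds (tied scores grouped into a single
#' threshold) and reports (false-positive rate, true-positive rate) points
#' from (0,0) to (1,1). Positives are the signature genes present in the
#' universe; signature genes outside the universe are dropped with a
#' message, since unmeasured genes cannot be ranked. The AUC (trapezoidal
#' over the tie-grouped curve) equals the Mann-Whitney probability that a
#' random positive outranks a random negative, ties counting one half.
#'
#' @param ranking a [rank_genes()] result (or any data.frame with `gene_id`
#'   and `score`, best first, higher score = higher priority).
#' @param signature a [gene_signature].
#' @param universe gene ids defining the evaluation universe; defaults to
#'   the ranked genes.
#' @return list of class `roc_result`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(ranking, signature, universe = ranking$gene_id) {
  if (!inherits(signature, "gene_signature"))
    stopf("roc_curve: signature must be a gene_signature")
  keep <- ranking$gene_id %in% universe
  r <- ranking[keep, , drop = FALSE]
  n_dropped <- length(setdiff(signature$genes, universe))
  if (n_dropped > 0)
    message(sprintf("signature '%s': %d gene(s) outside the ranked universe dropped",
                    signature$name, n_dropped))
  pos <- r$gene_id %in% signature$genes
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stopf("roc_curve: AUC undefined (%d positives, %d negatives)", n_pos, n_neg)
  ord <- order(-r$score)
  score <- r$score[ord]
  pos <- pos[ord]
  last <- !duplicated(score, fromLast = TRUE)  # end of each tie group
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  points <- data.frame(threshold = c(Inf, score[last]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Correlation between meta significance and meta effect size
#'
#' Pearson correlation of `-log10(meta_p)` with `|meta_fc|` across genes —
#' a one-number summary of how coupled the two meta criteria are (the meta
#' volcano's shape).
#'
#' @param results gene-level meta results from [combine_all()].
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
significance_effect_correlation <- function(results) {
  if (!is.data.frame(results) || nrow(results) < 3L)
    stopf("significance_effect_correlation: need at least 3 genes")
  x <- -log10(clip_pvalues(results$meta_p))
  y <- abs(results$meta_fc)
  if (var(x) == 0 || var(y) == 0)
    stopf("significance_effect_correlation: undefined for constant input")
  cor(x, y)
}

#' Meta volcano plot table
#'
#' One row per gene with the meta fold-change and the -log10 transforms of
#' the directional and minimum meta p-values — the data behind a
#' meta-analysis volcano plot. Rendering is left to the caller (e.g.
#' `plot(neg_log10_p ~ meta_fc, data = tab)`).
#'
#' @param results gene-level meta results from [combine_all()].
#' @return data.frame with columns `gene_id`, `meta_fc`, `neg_log10_p_up`,
#'   `neg_log10_p_down`, `neg_log10_p`.
#' @export
meta_volcano_table <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stopf("meta_volcano_table: need a non-empty results table")
  data.frame(gene_id = results$gene_id,
             meta_fc = results$meta_fc,
             neg_log10_p_up = -log10(clip_pvalues(results$meta_p_up)),
             neg_log10_p_down = -log10(clip_pvalues(results$meta_p_down)),
             neg_log10_p = -log10(clip_pvalues(results$meta_p)),
             row.names = NULL)
}

#' Null calibration of the directional meta p-values
#'
#' Runs the full pipeline (simulate, quantile-normalize, per-probe tests,
#' Fisher combination) on a no-effect simulation with the default
#' five-study design and reports the fraction of genes whose directional
#' meta p-value falls below `alpha`. Under the null both fractions should
#' be close to `alpha` (about 1% at the conventional 0.01 cutoff).
#'
#' @param n_genes number of simulated genes (>= 1000 recommended for stable
#'   estimates).
#' @param alpha significance cutoff in `(0, 1]`.
#' @param seed master simulation seed.
#' @return named numeric `c(fraction_up, fraction_down)`.
#' @export
null_calibration <- function(n_genes, alpha = 0.01, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stopf("null_calibration: alpha must be in (0, 1]")
  sim <- simulate_studies(null_config(n_genes, seed))
  stats <- lapply(sim$studies, function(st) {
    st$matrix <- quantile_normalize(st$matrix)
    compute_study_stats(st)
  })
  res <- combine_all(stats, sim$probe_map)
  c(fraction_up = mean(res$meta_p_up < alpha),
    fraction_down = mean(res$meta_p_down < alpha))
}

#' Per-study gene rankings (single-study baselines)
#'
#' For each study, a gene's probes are Fisher-combined within that study for
#' each direction and the directional minimum is used to rank the study's
#' genes (most significant first). These rankings serve as the single-study
#' baselines against which the meta rankings are compared.
#'
#' @param stats per-probe statistics, a data.frame or list of data.frames.
#' @param map probe-to-gene map.
#' @param p_clip lower p-value clip bound.
#' @return named list of `gene_ranking` data.frames, one per study; genes
#'   absent from a study are absent from its ranking.
#' @export
single_study_rankings <- function(stats, map, p_clip = 1e-300) {
  if (is.list(stats) && !is.data.frame(stats))
    stats <- do.call(rbind, stats)
  out <- lapply(split(stats, stats$study_id), function(st) {
    up <- pool_gene_pvalues(st, map, "up", p_clip)
    down <- pool_gene_pvalues(st, map, "down", p_clip)
    stopifnot(identical(up$gene_id, down$gene_id))
    score <- -log10(clip_pvalues(pmin(up$meta_p, down$meta_p), p_clip))
    ord <- order(-score, up$gene_id)
    r <- data.frame(gene_id = up$gene_id[ord], score = score[ord],
                    row.names = NULL)
    attr(r, "criterion") <- paste0("single_study:", st$study_id[1])
    class(r) <- c("gene_ranking", "data.frame")
    r
  })
  out[order(names(out))]
}
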