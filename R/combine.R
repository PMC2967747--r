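#' Fisher's omnibus combination of p-values
#'
#' Combines independent p-values with Fisher's method: the statistic
#' `X = -2 * sum(log(p_i))` over the `k` inputs is referred to a chi-squared
#' distribution with `2k` degrees of freedom and the upper-tail probability
#' is returned. Decreasing any input decreases the output; a single p-value
#' is returned unchanged.
#'
#' @param ps non-empty numeric vector of probabilities; values are clipped
#'   to `[p_clip, 1]` before the logarithm.
#' @param p_clip lower clip bound (also applied to the result).
#' @return the combined meta p-value, in `(0, 1]`.
#' @export
fisher_combine <- function(ps, p_clip = 1e-300) {
  if (length(ps) == 0L) stopf("fisher_combine: need at least one p-value")
  ps <- clip_pvalues(ps, p_clip)
  x <- -2 * sum(log(ps))
  clip_pvalues(pchisq(x, df = 2 * length(ps), lower.tail = FALSE), p_clip)
}

# merge probe stats with the probe->gene map; unmapped probes are dropped
map_stats_to_genes <- function(stats, map) {
  if (!all(c("study_id", "probe_id", "gene_id") %in% names(map)))
    stopf("probe map must have columns study_id, probe_id, gene_id")
  merge(stats, map[, c("study_id", "probe_id", "gene_id")],
        by = c("study_id", "probe_id"), sort = FALSE)
}

#' Pool one direction's p-values per gene with Fisher's method
#'
#' For each gene, all p-values of the requested direction from every mapped
#' probe in every study are combined with [fisher_combine()]. `k` is the
#' number of pooled p-values (probes x studies). Probes absent from the map
#' contribute to no gene; genes with no mapped probe are absent from the
#' output.
#'
#' @param stats per-probe statistics (one or several studies row-bound), as
#'   produced by [compute_study_stats()].
#' @param map probe-to-gene map: data.frame with columns `study_id`,
#'   `probe_id`, `gene_id`.
#' @param direction `"up"` or `"down"`.
#' @param p_clip lower clip bound applied before logarithms.
#' @return data.frame with columns `gene_id`, `meta_p`, `k`, sorted by
#'   `gene_id`.
#' @export
pool_gene_pvalues <- function(stats, map, direction = c("up", "down"),
                              p_clip = 1e-300) {
  direction <- match.arg(direction)
  merged <- map_stats_to_genes(stats, map)
  if (nrow(merged) == 0L)
    return(data.frame(gene_id = character(0), meta_p = numeric(0),
                      k = integer(0)))
  p <- clip_pvalues(merged[[if (direction == "up") "p_up" else "p_down"]],
                    p_clip)
  x <- rowsum(-2 * log(p), merged$gene_id)
  k <- rowsum(rep(1L, nrow(merged)), merged$gene_id)
  data.frame(gene_id = rownames(x),
             meta_p = clip_pvalues(pchisq(x[, 1], df = 2 * k[, 1],
                                          lower.tail = FALSE), p_clip),
             k = as.integer(k[, 1]),
             row.names = NULL)
}

#' Directional minimum of the two one-sided meta p-values
#'
#' The smaller of the up- and down-direction meta p-values is taken as the
#' gene's meta p-value; ties resolve to `"up"`. Vectorized.
#'
#' @param meta_p_up,meta_p_down probabilities in `(0, 1]` (recycled to a
#'   common length).
#' @return list with numeric `meta_p` and character `direction`.
#' @export
directional_min <- function(meta_p_up, meta_p_down) {
  list(meta_p = pmin(meta_p_up, meta_p_down),
       direction = ifelse(meta_p_down < meta_p_up, "down", "up"))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (via [stats::p.adjust()]), returned in
#' the input order.
#'
#' @param ps numeric vector of probabilities.
#' @return adjusted probabilities, same length and order.
#' @export
bh_adjust <- function(ps) {
  if (length(ps) == 0L) return(numeric(0))
  p.adjust(ps, method = "BH")
}

#' Inverse-variance fixed-effects combination of effect sizes
#'
#' Pools log2 fold-change estimates with weights `w_i = 1/var_i`:
#' `meta_fc = sum(w_i f_i) / sum(w_i)` with fixed-effects standard error
#' `sqrt(1 / sum(w_i))`. Noisier studies therefore contribute less.
#'
#' @param fs numeric vector of log2 effect estimates.
#' @param vars positive sampling variances, same length as `fs`.
#' @return named numeric `c(meta_fc, meta_fc_se)`.
#' @export
inverse_variance_combine <- function(fs, vars) {
  if (length(fs) == 0L || length(fs) != length(vars))
    stopf("inverse_variance_combine: fs and vars must be non-empty and of equal length")
  if (any(!is.finite(vars)) || any(vars <= 0))
    stopf("inverse_variance_combine: variances must be positive and finite")
  w <- 1 / vars
  c(meta_fc = sum(w * fs) / sum(w), meta_fc_se = sqrt(1 / sum(w)))
}

#' Combine per-probe statistics into per-gene meta results
#'
#' The full gene-level meta-analysis: per gene, Fisher-combines the
#' directional p-values of all mapped probes across all studies (both
#' directions), takes the directional minimum as the meta p-value, adjusts
#' the minima across genes with Benjamini-Hochberg, and pools the probes'
#' log2 fold-changes with inverse-variance fixed-effects weighting.
#'
#' By default every mapped probe from every study contributes one
#' `(f, var_f)` pair to the effect pooling (probe-as-unit policy). With
#' `within_study_first = TRUE`, a gene's probes are inverse-variance
#' combined within each study first and the per-study summaries are then
#' combined across studies; with one probe per gene per study the two
#' policies coincide.
#'
#' @param stats a data.frame of per-probe statistics (multiple studies
#'   row-bound), or a list of such data.frames.
#' @param map probe-to-gene map (`study_id`, `probe_id`, `gene_id`).
#' @param within_study_first logical; see Details.
#' @param p_clip lower p-value clip bound.
#' @return data.frame sorted by `gene_id` with columns `gene_id`,
#'   `meta_p_up`, `meta_p_down`, `meta_p`, `direction`, `meta_p_bh`,
#'   `meta_fc`, `meta_fc_se`, `k` (pooled p-values per direction) and
#'   `n_studies` (distinct contributing studies).
#' @export
combine_all <- function(stats, map, within_study_first = FALSE,
                        p_clip = 1e-300) {
  if (is.list(stats) && !is.data.frame(stats))
    stats <- do.call(rbind, stats)
  if (!is.data.frame(stats) || nrow(stats) == 0L)
    stopf("combine_all: no probe statistics supplied")
  merged <- map_stats_to_genes(stats, map)
  if (nrow(merged) == 0L) {
    warning("combine_all: no probe mapped to any gene; empty result")
    return(data.frame(gene_id = character(0), meta_p_up = numeric(0),
                      meta_p_down = numeric(0), meta_p = numeric(0),
                      direction = character(0), meta_p_bh = numeric(0),
                      meta_fc = numeric(0), meta_fc_se = numeric(0),
                      k = integer(0), n_studies = integer(0)))
  }
  merged <- merged[order(merged$gene_id, merged$study_id, merged$probe_id), ]
  gene <- merged$gene_id

  fisher_by_gene <- function(p, group) {
    x <- rowsum(-2 * log(clip_pvalues(p, p_clip)), group)
    k <- rowsum(rep(1L, length(p)), group)
    list(p = clip_pvalues(pchisq(x[, 1], df = 2 * k[, 1],
                                 lower.tail = FALSE), p_clip),
         k = as.integer(k[, 1]), gene_id = rownames(x))
  }
  up <- fisher_by_gene(merged$p_up, gene)
  down <- fisher_by_gene(merged$p_down, gene)

  if (within_study_first) {
    gs <- paste(gene, merged$study_id, sep = "\r")
    w1 <- 1 / merged$var_f
    sw1 <- rowsum(w1, gs)[, 1]
    swf1 <- rowsum(w1 * merged$f, gs)[, 1]
    g2 <- sub("\r.*$", "", names(sw1))
    sw <- rowsum(sw1, g2)   # combining per-study summaries: w = sum of w1
    swf <- rowsum(swf1, g2)
  } else {
    w <- 1 / merged$var_f
    sw <- rowsum(w, gene)
    swf <- rowsum(w * merged$f, gene)
  }
  meta_fc <- swf[, 1] / sw[, 1]
  meta_fc_se <- sqrt(1 / sw[, 1])

  pair <- !duplicated(paste(gene, merged$study_id, sep = "\r"))
  n_studies <- rowsum(as.integer(pair), gene)[, 1]

  dm <- directional_min(up$p, down$p)
  out <- data.frame(gene_id = up$gene_id,
                    meta_p_up = up$p,
                    meta_p_down = down$p,
                    meta_p = dm$meta_p,
                    direction = dm$direction,
                    meta_p_bh = bh_adjust(dm$meta_p),
                    meta_fc = meta_fc[up$gene_id],
                    meta_fc_se = meta_fc_se[up$gene_id],
                    k = up$k,
                    n_studies = as.integer(n_studies[up$gene_id]),
                    row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}
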