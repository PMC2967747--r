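#' A single two-group expression study
#'
#' Container for one study's log2 expression matrix (probes x samples) and
#' its case/control sample labels. In the transplant-rejection setting the
#' case class is acute rejection (AR) and the control class is stable (STA).
#'
#' @param study_id character study identifier.
#' @param matrix numeric matrix, probes x samples, log2 scale; rownames are
#'   probe ids, colnames are sample ids.
#' @param sample_groups character/factor of per-sample labels, `"case"` or
#'   `"control"`, aligned with the matrix columns.
#' @return an object of class `expression_study` with elements `study_id`,
#'   `matrix`, `sample_groups` (factor) and `probe_ids`.
#' @export
expression_study <- function(study_id, matrix, sample_groups) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stopf("study '%s': expression must be a numeric matrix", study_id)
  if (is.null(rownames(matrix)))
    stopf("study '%s': matrix must have probe ids as rownames", study_id)
  if (anyDuplicated(rownames(matrix)))
    stopf("study '%s': duplicate probe ids", study_id)
  if (!is.null(colnames(matrix)) && anyDuplicated(colnames(matrix)))
    stopf("study '%s': duplicate sample ids", study_id)
  groups <- factor(as.character(sample_groups), levels = c("case", "control"))
  if (length(groups) != ncol(matrix))
    stopf("study '%s': %d sample labels for %d columns", study_id,
          length(groups), ncol(matrix))
  if (anyNA(groups))
    stopf("study '%s': sample labels must be 'case' or 'control'", study_id)
  counts <- table(groups)
  if (any(counts < 2))
    stopf("study '%s': need at least 2 case and 2 control samples (got %d/%d)",
          study_id, counts[["case"]], counts[["control"]])
  structure(list(study_id = as.character(study_id), matrix = matrix,
                 sample_groups = groups, probe_ids = rownames(matrix)),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  counts <- table(x$sample_groups)
  cat(sprintf("expression_study '%s': %d probes, %d case + %d control samples\n",
              x$study_id, nrow(x$matrix), counts[["case"]], counts[["control"]]))
  invisible(x)
}

#' Quantile normalization of an expression matrix
#'
#' Forces every column to the same empirical distribution (the per-rank
#' means of the sorted columns) while preserving each column's rank order.
#' Ties within a column receive the mean of the rank-means they span.
#'
#' @param m numeric matrix, probes x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) == 0L || ncol(m) == 0L)
    stopf("quantile_normalize: need a non-empty numeric matrix")
  if (anyNA(m)) stopf("quantile_normalize: matrix contains missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

# Vectorised Welch machinery shared by the scalar and matrix entry points.
# Returns list(t, df, mean_diff) for case/control summary stats.
welch_parts <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1 / n1
  v2 <- s2 / n2
  se2 <- v1 + v2
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  list(t = t, df = df, diff = m1 - m2)
}

#' Directional (one-sided) Welch t-tests
#'
#' Computes both one-sided tails of the Welch unequal-variance t statistic
#' on log2 expression values: `p_up` for the hypothesis of increased
#' expression in cases, `p_down` for decreased. The two tails are
#' complementary (`p_up + p_down = 1`). When both groups are constant with
#' equal means the statistic is undefined and both tails are 0.5 by
#' convention; constant groups with unequal means give a degenerate extreme
#' tail, clipped by [clip_pvalues()].
#'
#' @param case,control numeric vectors of log2 values, each of length >= 2.
#' @return named numeric `c(p_up, p_down)`, both in (0, 1).
#' @export
one_sided_tests <- function(case, control) {
  if (length(case) < 2 || length(control) < 2)
    stopf("one_sided_tests: need at least 2 values per group")
  w <- welch_parts(mean(case), var(case), length(case),
                   mean(control), var(control), length(control))
  if (!is.finite(w$t)) {
    # zero pooled variance: equal constants are a perfect null observation,
    # unequal constants are infinitely extreme in the sign of the difference
    p_up <- if (w$diff == 0) 0.5 else if (w$diff > 0) 0 else 1
    p_down <- 1 - p_up
  } else {
    p_up <- pt(w$t, w$df, lower.tail = FALSE)
    p_down <- pt(w$t, w$df, lower.tail = TRUE)
  }
  c(p_up = clip_pvalues(p_up), p_down = clip_pvalues(p_down))
}

#' Log2 fold-change between case and control
#'
#' The log ratio of the geometric means of the raw-scale expression values,
#' computed as the difference of arithmetic means on the log2 scale.
#'
#' @param case,control numeric vectors of log2 values, each non-empty.
#' @return `mean(case) - mean(control)`, log2 units.
#' @export
log_fold_change <- function(case, control) {
  if (length(case) < 1 || length(control) < 1)
    stopf("log_fold_change: both groups must be non-empty")
  mean(case) - mean(control)
}

#' Sampling variance of the log2 fold-change
#'
#' Variance of a difference of independent sample means:
#' `s2_case/n_case + s2_control/n_control`, floored at `floor` so that
#' downstream inverse-variance weights stay finite on constant probes.
#'
#' @param case,control numeric vectors of log2 values, each of length >= 2.
#' @param floor positive lower bound on the returned variance.
#' @return positive variance, log2^2 units.
#' @export
fold_change_variance <- function(case, control, floor = 1e-8) {
  if (length(case) < 2 || length(control) < 2)
    stopf("fold_change_variance: need at least 2 values per group")
  max(var(case) / length(case) + var(control) / length(control), floor)
}

#' Per-probe directional statistics for one study
#'
#' For every probe computes the directional Welch p-values, the log2
#' fold-change and its sampling variance. Probes with fewer than 2 finite
#' values in either group are omitted (with a message). The matrix is
#' assumed already normalized.
#'
#' @param study an [expression_study].
#' @param var_floor lower bound on the fold-change variance (see
#'   [fold_change_variance()]).
#' @return data.frame with one row per usable probe and columns `study_id`,
#'   `probe_id`, `p_up`, `p_down`, `f`, `var_f`, `n_case`, `n_control`.
#' @export
compute_study_stats <- function(study, var_floor = 1e-8) {
  if (!inherits(study, "expression_study"))
    stopf("compute_study_stats: study must be an expression_study")
  m <- study$matrix
  case_idx <- study$sample_groups == "case"
  ca <- m[, case_idx, drop = FALSE]
  co <- m[, !case_idx, drop = FALSE]
  ok <- rowSums(is.finite(ca)) >= 2 & rowSums(is.finite(co)) >= 2
  if (!all(ok))
    message(sprintf("study '%s': dropping %d probe(s) with <2 usable values per group",
                    study$study_id, sum(!ok)))
  if (!any(ok)) {
    warning(sprintf("study '%s': no usable probes", study$study_id))
    return(data.frame(study_id = character(0), probe_id = character(0),
                      p_up = numeric(0), p_down = numeric(0), f = numeric(0),
                      var_f = numeric(0), n_case = integer(0),
                      n_control = integer(0)))
  }
  ca <- ca[ok, , drop = FALSE]
  co <- co[ok, , drop = FALSE]
  n1 <- ncol(ca); n2 <- ncol(co)
  m1 <- rowMeans(ca); m2 <- rowMeans(co)
  s1 <- rowSums((ca - m1)^2) / (n1 - 1)
  s2 <- rowSums((co - m2)^2) / (n2 - 1)
  w <- welch_parts(m1, s1, n1, m2, s2, n2)
  p_up <- pt(w$t, w$df, lower.tail = FALSE)
  p_down <- pt(w$t, w$df, lower.tail = TRUE)
  degen <- !is.finite(w$t)
  if (any(degen)) {
    p_up[degen] <- ifelse(w$diff[degen] == 0, 0.5,
                          ifelse(w$diff[degen] > 0, 0, 1))
    p_down[degen] <- 1 - p_up[degen]
  }
  data.frame(study_id = study$study_id,
             probe_id = rownames(ca),
             p_up = clip_pvalues(p_up),
             p_down = clip_pvalues(p_down),
             f = w$diff,
             var_f = pmax(s1 / n1 + s2 / n2, var_floor),
             n_case = n1,
             n_control = n2,
             row.names = NULL)
}
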