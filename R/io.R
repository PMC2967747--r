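#' Read one study's expression matrix and sample annotation
#'
#' The expression TSV has a header row of sample ids and a first column of
#' probe ids; the annotation TSV has columns `sample_id` and `group`, with
#' group `AR` (acute rejection, the case class) or `STA` (stable, the
#' control class), matched case-insensitively. Samples must match one-to-one
#' between the two files.
#'
#' @param expr_path path to the expression TSV (probes x samples).
#' @param annot_path path to the sample annotation TSV.
#' @param study_id study identifier to attach.
#' @param raw_scale if `TRUE` the values are raw-scale intensities and
#'   `log2(x + 1)` is applied; by default values are assumed log2 already.
#' @return an [expression_study].
#' @export
read_expression_study <- function(expr_path, annot_path, study_id,
                                  raw_scale = FALSE) {
  expr <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(expr) < 2L)
    stopf("%s: expected a probe id column plus at least one sample column", expr_path)
  probe_ids <- as.character(expr[[1]])
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup) > 0)
    stopf("%s: duplicate probe id '%s'", expr_path, dup[1])
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))[1]
    stopf("%s: non-numeric expression value near row %d", expr_path,
          ((bad - 1) %% nrow(m)) + 2)
  }
  rownames(m) <- probe_ids

  annot <- read.delim(annot_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(annot)))
    stopf("%s: annotation needs columns sample_id and group", annot_path)
  missing_in_matrix <- setdiff(annot$sample_id, colnames(m))
  if (length(missing_in_matrix) > 0)
    stopf("%s: annotated sample '%s' absent from %s", annot_path,
          missing_in_matrix[1], expr_path)
  missing_in_annot <- setdiff(colnames(m), annot$sample_id)
  if (length(missing_in_annot) > 0)
    stopf("%s: sample '%s' has no annotation in %s", expr_path,
          missing_in_annot[1], annot_path)
  grp <- toupper(trimws(annot$group))
  if (!all(grp %in% c("AR", "STA")))
    stopf("%s: group must be AR or STA (got '%s')", annot_path,
          annot$group[!grp %in% c("AR", "STA")][1])
  groups <- setNames(ifelse(grp == "AR", "case", "control"), annot$sample_id)
  if (raw_scale) m <- log2(m + 1)
  expression_study(study_id, m, groups[colnames(m)])
}

#' Write one study's expression matrix and sample annotation
#'
#' Inverse of [read_expression_study()]; group labels are written as
#' `AR`/`STA`.
#'
#' @param study an [expression_study].
#' @param expr_path,annot_path output TSV paths.
#' @return (invisibly) `expr_path`.
#' @export
write_expression_study <- function(study, expr_path, annot_path) {
  df <- data.frame(probe_id = rownames(study$matrix), study$matrix,
                   check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  annot <- data.frame(sample_id = colnames(study$matrix),
                      group = ifelse(study$sample_groups == "case", "AR", "STA"))
  write.table(annot, annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

#' Read a probe-to-gene mapping table
#'
#' TSV with columns `study_id`, `probe_id`, `gene_id`. Identical duplicate
#' rows are deduplicated; a (study, probe) pair mapped to two different
#' genes is an error.
#'
#' @param path path to the TSV.
#' @return data.frame with the three columns.
#' @export
read_probe_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "probe_id", "gene_id")
  if (!all(need %in% names(map)))
    stopf("%s: probe map needs columns %s", path, paste(need, collapse = ", "))
  map <- unique(map[, need])
  key <- paste(map$study_id, map$probe_id, sep = "\t")
  if (anyDuplicated(key)) {
    clash <- key[duplicated(key)][1]
    stopf("%s: probe '%s' mapped to multiple genes",
          path, sub("\t", "/", clash, fixed = TRUE))
  }
  if (nrow(map) == 0L) warning(sprintf("%s: empty probe map", path))
  map
}

#' @rdname read_probe_map
#' @param map data.frame with columns `study_id`, `probe_id`, `gene_id`.
#' @export
write_probe_map <- function(map, path) {
  write.table(map[, c("study_id", "probe_id", "gene_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT dialect: one set per line — name, description, then member
#' gene symbols, tab-separated. The description is discarded; duplicate
#' genes within a line are deduplicated; blank lines are ignored.
#'
#' @param path path to the GMT file.
#' @return named list of [gene_signature] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stopf("%s: line %d has %d field(s); need name, description and at least one gene",
            path, i, length(fields))
    gene_signature(fields[1], fields[-(1:2)])
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' @rdname read_gmt
#' @param signatures list of [gene_signature] objects.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a study manifest
#'
#' TSV with columns `study_id`, `expression`, `annotation`, `probe_map`
#' (one row per study; relative paths are resolved against the manifest's
#' directory). Study ids must be unique and all files must exist.
#'
#' @param path manifest TSV path.
#' @return data.frame with the four columns, paths resolved.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "expression", "annotation", "probe_map")
  if (!all(need %in% names(man)))
    stopf("%s: manifest needs columns %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(man$study_id))
    stopf("%s: duplicate study_id '%s'", path,
          man$study_id[duplicated(man$study_id)][1])
  base <- dirname(normalizePath(path))
  for (col in c("expression", "annotation", "probe_map")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
    missing <- man[[col]][!file.exists(man[[col]])]
    if (length(missing) > 0)
      stopf("%s: %s file not found: %s", path, col, missing[1])
  }
  man
}

#' Assemble a pipeline run configuration
#'
#' @param manifest path to a manifest TSV (see [read_manifest()]) or an
#'   equivalent data.frame.
#' @param out_dir output directory.
#' @param signatures optional path to a GMT file; when given, ROC tables
#'   are produced for every signature against both meta rankings.
#' @param alpha significance cutoff used in the run log's summary counts.
#' @param within_study_first effect-pooling policy (see [combine_all()]).
#' @param var_floor fold-change variance floor.
#' @param p_clip p-value clip bound.
#' @param raw_scale apply `log2(x + 1)` to input expression values.
#' @param seed integer recorded in the log (the real-data path itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(manifest, out_dir, signatures = NULL, alpha = 0.01,
                       within_study_first = FALSE, var_floor = 1e-8,
                       p_clip = 1e-300, raw_scale = FALSE, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stopf("run_config: alpha must be in (0, 1)")
  if (var_floor <= 0 || p_clip <= 0)
    stopf("run_config: var_floor and p_clip must be positive")
  structure(list(manifest = manifest, out_dir = out_dir,
                 signatures = signatures, alpha = alpha,
                 within_study_first = isTRUE(within_study_first),
                 var_floor = var_floor, p_clip = p_clip,
                 raw_scale = isTRUE(raw_scale), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' Recognized keys match the arguments of [run_config()]; `manifest` is
#' required. JSON files parse as well (YAML superset).
#'
#' @param path YAML/JSON configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$manifest)) stopf("%s: config needs a 'manifest' path", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  run_config(manifest = resolve(cfg$manifest),
             out_dir = resolve(cfg$out_dir %||% "metamux_out"),
             signatures = resolve(cfg$signatures),
             alpha = cfg$alpha %||% 0.01,
             within_study_first = cfg$within_study_first %||% FALSE,
             var_floor = cfg$var_floor %||% 1e-8,
             p_clip = cfg$p_clip %||% 1e-300,
             raw_scale = cfg$raw_scale %||% FALSE,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_num <- function(x) formatC(x, digits = 15, format = "g")

write_tsv_deterministic <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], format_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole meta-analysis pipeline
#'
#' Reads every study in the manifest, quantile-normalizes it, computes
#' per-probe directional statistics, combines them per gene
#' ([combine_all()]) and writes to `out_dir`:
#' `results.tsv` (the gene-level meta table), `volcano.tsv`
#' (the meta volcano coordinates), `roc_<criterion>_<signature>.tsv`
#' tables when a GMT file is configured, and `run_log.txt` with per-stage
#' probe/gene counts and the full option set. Output is deterministic:
#' running twice on the same inputs gives byte-identical files.
#'
#' @param config a [run_config()] (or a path to a YAML config file).
#' @return (invisibly) the gene-level results data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stopf("run_pipeline: need a run_config")
  man <- if (is.data.frame(config$manifest)) config$manifest
         else read_manifest(config$manifest)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("metamux run: %d studies; seed=%d alpha=%g within_study_first=%s var_floor=%g p_clip=%g raw_scale=%s",
            nrow(man), config$seed, config$alpha, config$within_study_first,
            config$var_floor, config$p_clip, config$raw_scale))

  maps <- unique(do.call(rbind, lapply(unique(man$probe_map), read_probe_map)))
  stats <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    st <- read_expression_study(man$expression[i], man$annotation[i],
                                man$study_id[i], raw_scale = config$raw_scale)
    st$matrix <- quantile_normalize(st$matrix)
    stats[[i]] <- compute_study_stats(st, var_floor = config$var_floor)
    log_lines <- c(log_lines,
                   sprintf("study %s: %d probes, %d case, %d control, %d usable probes",
                           st$study_id, nrow(st$matrix),
                           sum(st$sample_groups == "case"),
                           sum(st$sample_groups == "control"),
                           nrow(stats[[i]])))
  }
  res <- combine_all(stats, maps, within_study_first = config$within_study_first,
                     p_clip = config$p_clip)
  log_lines <- c(log_lines,
                 sprintf("combined: %d genes; %d with meta_p < %g; %d with meta_p_bh < %g",
                         nrow(res), sum(res$meta_p < config$alpha),
                         config$alpha, sum(res$meta_p_bh < config$alpha),
                         config$alpha))
  write_tsv_deterministic(res, file.path(config$out_dir, "results.tsv"))
  write_tsv_deterministic(meta_volcano_table(res),
                          file.path(config$out_dir, "volcano.tsv"))

  if (!is.null(config$signatures)) {
    sigs <- read_gmt(config$signatures)
    for (crit in c("meta_fc_abs", "meta_p")) {
      ranking <- rank_genes(res, crit)
      for (sig in sigs) {
        roc <- try(roc_curve(ranking, sig), silent = TRUE)
        if (inherits(roc, "try-error")) {
          log_lines <- c(log_lines, sprintf("roc %s vs %s: skipped (%s)",
                                            crit, sig$name,
                                            trimws(attr(roc, "condition")$message)))
          next
        }
        safe <- gsub("[^A-Za-z0-9_.-]", "_", sig$name)
        write_tsv_deterministic(roc$points,
                                file.path(config$out_dir,
                                          sprintf("roc_%s_%s.tsv", crit, safe)))
        log_lines <- c(log_lines, sprintf("roc %s vs %s: AUC=%s (%d pos, %d neg)",
                                          crit, sig$name, format_num(roc$auc),
                                          roc$n_pos, roc$n_neg))
      }
    }
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(res)
}

#' Read a gene-level results table written by [run_pipeline()]
#'
#' @param path path to `results.tsv`.
#' @return data.frame with the [combine_all()] columns.
#' @export
read_results <- function(path) {
  res <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "meta_p_up", "meta_p_down", "meta_p", "direction",
            "meta_p_bh", "meta_fc", "meta_fc_se", "k", "n_studies")
  if (!all(need %in% names(res)))
    stopf("%s: results table needs columns %s", path, paste(need, collapse = ", "))
  res
}
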