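test_that("fisher_combine handles the boundary cases exactly", {
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  set.seed(5)
  for (p in runif(10)) expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("fisher_combine matches a Monte-Carlo chi-square tail", {
  # independent oracle: simulate the null statistic -2 sum log(U_i)
  set.seed(101)
  B <- 2e5
  for (ps in list(0.37, c(0.5, 0.5, 0.5, 0.5, 0.5),
                  c(0.001, 0.2, 0.8, 0.05, 0.5), c(0.1, 0.2, 0.3))) {
    k <- length(ps)
    x_obs <- -2 * sum(log(ps))
    x_null <- -2 * rowSums(matrix(log(runif(B * k)), B, k))
    p_mc <- mean(x_null >= x_obs)
    se <- sqrt(p_mc * (1 - p_mc) / B)
    expect_lt(abs(fisher_combine(ps) - p_mc), 3 * se + 1e-12)
  }
  # the five-halves case has a known tail value near 0.732
  expect_equal(fisher_combine(rep(0.5, 5)), 0.7319, tolerance = 1e-3)
})

test_that("fisher_combine is monotone in every coordinate and uniform under the null", {
  set.seed(17)
  for (i in 1:20) {
    ps <- runif(5)
    j <- sample(5, 1)
    smaller <- ps; smaller[j] <- ps[j] * 0.5
    expect_lt(fisher_combine(smaller), fisher_combine(ps))
  }
  meta <- replicate(2000, fisher_combine(runif(5)))
  expect_gt(stats::ks.test(meta, "punif")$p.value, 0.001)
})

test_that("pool_gene_pvalues pools all probe p-values per gene across studies", {
  stats <- rbind(probe_stats_row("S1", "a1", 0.1),
                 probe_stats_row("S1", "a2", 0.2),
                 probe_stats_row("S2", "b1", 0.3),
                 probe_stats_row("S2", "stray", 0.01),
                 probe_stats_row("S1", "c1", 0.7))
  map <- data.frame(study_id = c("S1", "S1", "S2", "S1"),
                    probe_id = c("a1", "a2", "b1", "c1"),
                    gene_id = c("GA", "GA", "GA", "GC"))
  up <- pool_gene_pvalues(stats, map, "up")
  expect_equal(up$gene_id, c("GA", "GC"))
  expect_equal(up$k, c(3L, 1L))
  # oracle: direct call on the concatenated list
  expect_equal(up$meta_p[1], fisher_combine(c(0.1, 0.2, 0.3)))
  expect_equal(up$meta_p[2], 0.7)  # single probe passes through
  down <- pool_gene_pvalues(stats, map, "down")
  expect_equal(down$meta_p[1], fisher_combine(1 - c(0.1, 0.2, 0.3)))
})

test_that("directional minimum keeps the smaller tail, ties resolve up", {
  expect_equal(directional_min(0.2, 0.9), list(meta_p = 0.2, direction = "up"))
  expect_equal(directional_min(0.9, 0.2), list(meta_p = 0.2, direction = "down"))
  expect_equal(directional_min(1, 1), list(meta_p = 1, direction = "up"))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
})

test_that("inverse-variance combination weights by precision", {
  expect_equal(inverse_variance_combine(c(1, 3, 5), c(2, 2, 2)),
               c(meta_fc = 3, meta_fc_se = sqrt(2 / 3)))
  expect_equal(inverse_variance_combine(1.7, 0.09),
               c(meta_fc = 1.7, meta_fc_se = 0.3))
  # hand-derived: weights (0.5, 1) -> (0.5*2 + 1*4) / 1.5 = 10/3
  out <- inverse_variance_combine(c(2, 4), c(2, 1))
  expect_equal(out[["meta_fc"]], 10 / 3)
  expect_equal(out[["meta_fc_se"]], sqrt(2 / 3))
  expect_error(inverse_variance_combine(c(1, 2), 1), "equal length")
  expect_error(inverse_variance_combine(c(1, 2), c(1, 0)), "positive")
})

test_that("inverse-variance combination agrees with a fixed-effects meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(23)
  for (i in 1:5) {
    fs <- rnorm(6)
    vars <- rexp(6) + 0.05
    fit <- metafor::rma(yi = fs, vi = vars, method = "FE")
    out <- inverse_variance_combine(fs, vars)
    expect_equal(out[["meta_fc"]], as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(out[["meta_fc_se"]], fit$se, tolerance = 1e-8)
  }
})

test_that("combine_all degenerates correctly for one study with one probe per gene", {
  st <- make_tiny_study("S1", n_probes = 5, seed = 8, shift = 1)
  stats <- compute_study_stats(st)
  map <- data.frame(study_id = "S1", probe_id = stats$probe_id,
                    gene_id = sprintf("G%d", 5:1))  # scrambled on purpose
  res <- combine_all(stats, map)
  expect_equal(res$gene_id, sort(map$gene_id))
  i <- match(map$gene_id, res$gene_id)
  expect_equal(res$meta_fc[i], stats$f)
  expect_equal(res$meta_fc_se[i], sqrt(stats$var_f))
  expect_equal(res$meta_p[i], pmin(stats$p_up, stats$p_down))
  expect_equal(res$k, rep(1L, 5))
  expect_equal(res$n_studies, rep(1L, 5))
  expect_equal(res$meta_p_bh, bh_adjust(res$meta_p))
})

test_that("genes in a subset of studies are retained with their own k and n_studies", {
  stats <- rbind(probe_stats_row("S1", "a1", 0.1, f = 1, var_f = 0.5),
                 probe_stats_row("S1", "a2", 0.2, f = 2, var_f = 1),
                 probe_stats_row("S2", "a3", 0.4, f = 0, var_f = 2),
                 probe_stats_row("S1", "b1", 0.6, f = -1, var_f = 1))
  map <- data.frame(study_id = c("S1", "S1", "S2", "S1"),
                    probe_id = c("a1", "a2", "a3", "b1"),
                    gene_id = c("GA", "GA", "GA", "GB"))
  res <- combine_all(stats, map)
  expect_equal(res$k, c(3L, 1L))
  expect_equal(res$n_studies, c(2L, 1L))
  ga <- res[res$gene_id == "GA", ]
  expect_equal(ga$meta_fc, inverse_variance_combine(c(1, 2, 0), c(0.5, 1, 2))[["meta_fc"]])
  # pooled effect stays inside the span of its inputs, with se below any input sd
  expect_true(ga$meta_fc >= 0 && ga$meta_fc <= 2)
  expect_lte(ga$meta_fc_se, sqrt(0.5))
})

test_that("combine_all is invariant to probe and study permutation", {
  sim <- simulate_studies(sim_config(n_genes = 60, seed = 12))
  stats <- sim_stats(sim)
  res <- combine_all(stats, sim$probe_map)
  all_stats <- do.call(rbind, stats)
  set.seed(1)
  shuffled <- all_stats[sample(nrow(all_stats)), ]
  res2 <- combine_all(shuffled, sim$probe_map[sample(nrow(sim$probe_map)), ])
  expect_equal(res2, res)
  # meta_fc bounded by the per-gene span of probe effects
  merged <- merge(all_stats, sim$probe_map)
  lo <- tapply(merged$f, merged$gene_id, min)
  hi <- tapply(merged$f, merged$gene_id, max)
  expect_true(all(res$meta_fc >= lo[res$gene_id] - 1e-12))
  expect_true(all(res$meta_fc <= hi[res$gene_id] + 1e-12))
  expect_true(all(res$meta_fc_se <=
                    sqrt(tapply(merged$var_f, merged$gene_id, min))[res$gene_id] + 1e-12))
})

test_that("within-study-first pooling coincides with probe-as-unit at one probe per study", {
  sim <- simulate_studies(sim_config(n_genes = 50, probes_per_gene = c(1, 1),
                                     seed = 14))
  stats <- sim_stats(sim)
  a <- combine_all(stats, sim$probe_map, within_study_first = FALSE)
  b <- combine_all(stats, sim$probe_map, within_study_first = TRUE)
  expect_equal(a, b)
  # and differs in general but stays a valid convex combination
  sim2 <- simulate_studies(sim_config(n_genes = 50, probes_per_gene = c(2, 4),
                                      seed = 15))
  stats2 <- sim_stats(sim2)
  b2 <- combine_all(stats2, sim2$probe_map, within_study_first = TRUE)
  merged <- merge(do.call(rbind, stats2), sim2$probe_map)
  lo <- tapply(merged$f, merged$gene_id, min)
  hi <- tapply(merged$f, merged$gene_id, max)
  expect_true(all(b2$meta_fc >= lo[b2$gene_id] - 1e-12 &
                    b2$meta_fc <= hi[b2$gene_id] + 1e-12))
})

test_that("unmapped probes raise the empty-result warning path", {
  stats <- probe_stats_row("S1", "a1", 0.1)
  map <- data.frame(study_id = "S9", probe_id = "zz", gene_id = "G1")
  expect_warning(res <- combine_all(stats, map), "no probe mapped")
  expect_equal(nrow(res), 0)
})
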