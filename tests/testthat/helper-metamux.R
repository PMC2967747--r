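# Small builders shared across the test files.

# a tiny deterministic two-group study built by hand
make_tiny_study <- function(study_id = "T1", n_probes = 4,
                            n_case = 3, n_control = 4, seed = 11,
                            shift = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * (n_case + n_control), 8, 1),
              n_probes, n_case + n_control,
              dimnames = list(sprintf("p%d", seq_len(n_probes)),
                              sprintf("%s_s%d", study_id,
                                      seq_len(n_case + n_control))))
  m[, seq_len(n_case)] <- m[, seq_len(n_case)] + shift
  expression_study(study_id, m,
                   c(rep("case", n_case), rep("control", n_control)))
}

# probe stats row constructed directly (for combine-level tests)
probe_stats_row <- function(study_id, probe_id, p_up, f = 0, var_f = 1,
                            n_case = 5L, n_control = 5L) {
  data.frame(study_id = study_id, probe_id = probe_id,
             p_up = p_up, p_down = 1 - p_up, f = f, var_f = var_f,
             n_case = n_case, n_control = n_control)
}

# exact Mann-Whitney AUC by pair enumeration (ties count one half)
auc_brute_force <- function(score, is_pos) {
  pos <- score[is_pos]
  neg <- score[!is_pos]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# per-probe stats for a simulated compendium, without renormalization
# (the generator emits clean log2 data)
sim_stats <- function(sim) lapply(sim$studies, compute_study_stats)
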