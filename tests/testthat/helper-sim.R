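# Small simulation configurations for fast unit tests. The acceptance
# suite uses the package defaults; unit tests use a compact genome.

small_cfg <- function(seed = 1, n_uces = 40, ...) {
  sim_config(n_chromosomes = 2L, chrom_length = 4e5, n_uces = n_uces,
             seed = seed, ...)
}

# Per-stage truth/called agreement for a simulated dataset.
calling_recovery <- function(cfg) {
  g <- generate_genome(cfg)
  pm <- generate_probe_matrix(g$truth, cfg)
  norm <- quantile_normalize(pm$values)
  calls <- call_expression(norm, pm$meta)
  prof <- expression_profile(calls, cfg$stage_labels)
  tr <- g$truth$uce
  per_stage <- lapply(cfg$stage_labels, function(st) {
    cc <- calls[calls$stage == st, ]
    cm <- match(tr$uce_id, cc$uce_id)
    data.frame(stage = st,
               truth_on = g$truth$expr_plus[, st] | g$truth$expr_minus[, st],
               called = cc$plus_called[cm] | cc$minus_called[cm])
  })
  list(genome = g, probes = pm, norm = norm, calls = calls, profile = prof,
       truth = tr, per_stage = do.call(rbind, per_stage))
}
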