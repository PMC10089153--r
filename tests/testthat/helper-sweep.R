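# The scaled-down criticality scan is expensive, so it is computed once per
# session and shared by the acceptance tests: default k grid, three sheet
# sizes, five replicates, default run lengths (burn-in 100 time units,
# 80 sampled frames at interval 1.0).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function() {
  if (is.null(.acceptance_cache$sweep)) {
    .acceptance_cache$sweep <- criticality_sweep(
      k_values = c(0.5, 1, 2, 3, 3.5, 4, 5, 8),
      n_values = c(100, 400, 1600),
      replicates = 5,
      base_params = model_params(k = 1),
      seed = 714)
  }
  .acceptance_cache$sweep
}

# extra runs at the critical coupling for the largest sheet, giving a
# 7x equivalent-diameter range against N = 100
critical_size_scan <- function() {
  if (is.null(.acceptance_cache$big)) {
    .acceptance_cache$big <- criticality_sweep(
      3.5, 4900, replicates = 3, base_params = model_params(k = 3.5),
      seed = 714)
  }
  .acceptance_cache$big
}
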