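# shared small fixtures, built in code

fx_stimuli <- function() stimulus_set()

fx_run <- function(seed = 1) {
  st <- fx_stimuli()
  generate_run(build_tpm(st), st, seed = seed)
}

fx_rdms <- function(seed = 5, n_instances = 2) {
  layer_rdms(fx_stimuli(), n_instances = n_instances, seed = seed)
}

# tiny planted volume: selective (scaling + null) regions + non-selective rest
fx_truth <- function(dim = c(8, 8, 4), slope = 2, seed = 9) {
  fh <- synth_feature_hierarchy(fx_stimuli(), seed = seed)
  default_truth(dim, fh[[8]], slope = slope, seed = seed)
}

# a surprise tibble with chosen z values (z-scored internally)
fx_surprise <- function(trial, raw, model_id = "m") {
  out <- tibble::tibble(trial = trial, raw = raw,
                        z = as.numeric(scale(raw)), model_id = model_id)
  class(out) <- c("surprise", class(out))
  out
}

# trial table with widely spaced go trials (for LSS/LSA equivalence)
fx_spaced_trials <- function(n = 16, gap = 24, stimuli = fx_stimuli()) {
  ids <- rep(stimuli$stimulus_id, length.out = n)
  pairing <- setNames(stimuli$stimulus_id, stimuli$cue_letter)
  cues <- names(pairing)[match(ids, pairing)]
  out <- tibble::tibble(
    trial = seq_len(n), cue = cues, stimulus_id = ids, expected_id = ids,
    condition = "expected", onset = 10 + (seq_len(n) - 1) * gap,
    duration = 0.5, iti = gap - 1)
  class(out) <- c("trial_table", class(out))
  out
}
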