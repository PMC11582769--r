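## shared fixtures: cheap parameter sets and a coarse protocol for unit tests

quick_protocol <- function(dose_nM, knockdown = NULL, sp = sig_params("III")) {
  protocol(dose_nM, knockdown = knockdown, exposure_h = 100, params = sp)
}

## states drawn reproducibly inside the positive orthant
random_states <- function(model_id, n, seed = 1, max = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    stats::setNames(stats::runif(length(signaling_states(model_id)), 0, max),
                    signaling_states(model_id)))
}
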