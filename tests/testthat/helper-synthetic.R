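# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

default_column <- function(...) cortical_column_spec(...)

task_design <- function(cts) {
  glm_design(cbind(task = attr(cts, "ground_truth")$response))
}

# Canonical three-layer sampling windows (no "overall")
three_layer_windows <- function() {
  canonical_layer_windows()[c("superficial", "middle", "deep")]
}

# Band-pass then sample the three canonical layers for every ROI of one run
layer_sampled_run <- function(run) {
  lapply(run, function(cts) {
    mag <- bandpass(cts$magnitude, TR_s = cts$TR_s)
    do.call(rbind, sample_layers(mag, cts$sites$depth, three_layer_windows()))
  })
}

local_maxima <- function(y) which(diff(sign(diff(y))) == -2) + 1
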