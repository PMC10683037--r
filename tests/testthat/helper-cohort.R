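# Shared, lazily built cohort fixtures. The heavy noise-free benchmark
# cohort (79/44 subjects, 30 s recordings — the study's minimum recording
# length, chosen to keep the suite fast) is built once per session and
# reused by the recovery and discrimination tests.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Noise-free study-scale cohort: 79 positive / 44 negative.
nf_cohort <- function() {
  memo("nf_cohort", function() {
    generate_cohort(cohort_spec(n_pos = 79, n_neg = 44,
                                duration_range = c(30, 30),
                                noise = noise_free(), seed = 20260927))
  })
}

nf_features <- function() {
  memo("nf_features", function() cohort_features(nf_cohort()))
}

# Null cohort: both classes drawn from one distribution (negative-class
# parameters); discrimination should be at chance.
null_features <- function() {
  memo("null_features", function() {
    co <- generate_cohort(cohort_spec(n_pos = 40, n_neg = 24,
                                      duration_range = c(30, 30),
                                      noise = noise_free(),
                                      identical_classes = TRUE, seed = 4044))
    cohort_features(co)
  })
}

# One clean fixed-rate subject plus its filtered epochs, for detector and
# averaging tests.
clean_subject <- function() {
  memo("clean_subject", function() {
    s <- generate_recording("CS1", morph = beat_morphology(p_duration_ms = 136,
                                                           pr_ms = 177),
                            duration_s = 30, hr_bpm = 60, rr_sd_s = 0,
                            noise = noise_free(), seed = 7)
    list(subject = s, epochs = segment_epochs(preprocess_recording(s$recording)))
  })
}
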