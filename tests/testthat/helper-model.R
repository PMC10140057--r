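# The reference study (cohort generation + two-phase training) takes a
# couple of minutes, so it is run once per test session and shared by all
# tests that need a trained model.
.toy_cache <- new.env(parent = emptyenv())

toy_study_cached <- function(seed = 1L) {
  key <- paste0("study_", seed)
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- toy_study(seed)
  }
  .toy_cache[[key]]
}
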