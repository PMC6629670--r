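## Small shared phantom fixtures, rendered once per test session.
.fixtures <- new.env(parent = emptyenv())

small_base_spec <- function(frame_size = 96, n_frames = 20) {
  phantom_spec(frame_size = frame_size, n_frames = n_frames,
               peak_frame = min(9L, n_frames - 1L))
}

## 40-patient balanced mini-cohort at reduced resolution, preprocessed.
mini_cohort <- function() {
  if (is.null(.fixtures$mini)) {
    specs <- sample_cohort_specs(40, prevalence = 0.5,
                                 base_spec = small_base_spec(), seed = 314)
    .fixtures$mini <- list(specs = specs,
                           manifest = cohort_manifest(specs),
                           aligned = preprocess_cohort(specs,
                                                       channels = "MAG"))
  }
  .fixtures$mini
}
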