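# Shared simulated cohort for the end-to-end acceptance checks: 4 training
# nights and 10 test nights of 960 epochs spanning the fragmentation
# (severity) range, staged by the KDE-HMM and reviewed by a slightly
# imperfect simulated technologist. Built once and cached, since several
# test files assert different properties of the same study.
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_cache$study)) {
    .cohort_cache$study <- run_cohort(
      n_nights = 10, seed = 42, stager = "hmm", n_epochs = 960,
      policy = review_policy(reviewer_accuracy = 0.85,
                             reviewer_error_rate = 0.1))
    .cohort_cache$summary <- summarize_cohort(.cohort_cache$study)
  }
  .cohort_cache
}
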