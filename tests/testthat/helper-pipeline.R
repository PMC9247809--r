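# desk-scale pipeline config used by the pipeline unit tests
small_pipeline_config <- function(seed = 7, n_posts = 6000) {
  pipeline_config(
    generator = generator_config(n_posts = n_posts, seed = seed),
    topic_grid = data.frame(n_topics = 13, seed = 1),
    lda_iter = 150, fit_subsample = 4000, n_labeled = 1500,
    classifiers = c("nbsvm", "logreg_cv", "multinomial_nb"),
    seed = seed)
}

# the full-scale acceptance run is expensive; compute it once per session
acceptance_env <- new.env()
acceptance_run <- function() {
  if (is.null(acceptance_env$report)) {
    cfg <- pipeline_config(
      generator = generator_config(n_posts = 100000, seed = 7), seed = 7)
    acceptance_env$report <- run_pipeline(cfg)
  }
  acceptance_env$report
}
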