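# shared fixtures: all synthetic, built in code

# a deterministic noisy 128-sample sum-vector-like window
fixture_window <- function(seed = 1, n = 128) {
  set.seed(seed)
  1 + 0.3 * sin(2 * pi * seq_len(n) / 32) + rnorm(n, sd = 0.1)
}

# small labelled dataset shared by classifier tests (built once per run)
fixture_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- gen_labelled_dataset(60, 60, sim_config(seed = 101))
      cache <<- extract_features(d)
    }
    cache
  }
})

expect_no_na <- function(x) expect_false(anyNA(x))
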