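# 4 pre-neuron x 2 post-neuron toy array (the small worked example used to
# explain the half-bias scheme)
toy_config <- function(...) learning_config(n_pre = 4, n_post = 2, ...)

toy_crossbar <- function(config = toy_config(), params = device_params()) {
  init_crossbar(config, params)
}

# small, fast code generator settings for model-interface tests
small_codes <- function(seed = 7) {
  gen_codes(code_gen_config(n_train = 12, n_test = 6, seed = seed))
}

# two-class toy trials with variance planted on disjoint channel subsets
planted_trials <- function(n, hot, n_ch = 6, len = 300, sd_hot = 4) {
  lapply(seq_len(n), function(i) {
    X <- matrix(rnorm(n_ch * len), n_ch)
    X[hot, ] <- X[hot, ] * sd_hot
    X
  })
}

# fraction of a channel's periodogram power within f0 +/- 2 Hz
power_fraction_near <- function(ch, fs, f0) {
  n <- length(ch)
  p <- Mod(stats::fft(ch))^2
  fr <- (seq_len(n) - 1) * fs / n
  keep <- fr <= fs / 2
  sum(p[keep & abs(fr - f0) < 2]) / sum(p[keep])
}
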