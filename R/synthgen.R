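#' Configuration for the synthetic feature-code generator
#'
#' Emulates the binarized 32-bit EEG feature codes: one random prototype per
#' vowel class, pairwise well separated in Hamming distance, with per-bit
#' noise flips. Defaults produce 65 distinct training and 15 distinct testing
#' codes over the classes a/i/u.
#'
#' @param n_bits code length (pre-neuron count).
#' @param classes class labels.
#' @param separation minimum pairwise Hamming distance between prototypes.
#' @param p per-bit flip probability when sampling codes from a prototype;
#'   must satisfy \code{p < separation / (2 * n_bits)} so classes stay
#'   separable in expectation.
#' @param n_train,n_test number of distinct codes per split.
#' @param structure prototype geometry. \code{"pairwise_blocks"} (default)
#'   mirrors the pairwise-CSP binarization that produces the real codes: the
#'   32 bits split into one block per class pair (3 x 10, padded with 2 zero
#'   bits); within block (x, y) class x sets one half of the bits, class y
#'   the complementary half, and the third class a random half. Cross-class
#'   active-bit overlap is then small (about 5 of 15), as the front-end's
#'   block structure enforces. \code{"random"} draws unstructured balanced
#'   prototypes subject only to the separation constraint.
#' @param seed RNG seed.
#' @return An object of class \code{code_gen_config}.
#' @export
code_gen_config <- function(n_bits = 32, classes = c("a", "i", "u"),
                            separation = 12, p = 0.05,
                            n_train = 65, n_test = 15,
                            structure = c("pairwise_blocks", "random"),
                            seed = 42) {
  stopifnot(n_bits >= 1, separation >= 1, p >= 0,
            n_train >= length(classes), n_test >= 0)
  structure <- match.arg(structure)
  if (p >= separation / (2 * n_bits))
    stop("flip probability too high for the configured prototype separation")
  if (structure == "pairwise_blocks" &&
      n_bits < 2 * choose(length(classes), 2))
    stop("too few bits for pairwise block prototypes")
  structure(list(n_bits = n_bits, classes = classes, separation = separation,
                 p = p, n_train = n_train, n_test = n_test,
                 structure = structure, seed = seed),
            class = "code_gen_config")
}

# one prototype per class laid out in pairwise blocks (see code_gen_config)
block_prototypes <- function(config) {
  k <- length(config$classes)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  bsize <- (config$n_bits %/% length(pairs)) %/% 2 * 2  # even block size
  half <- bsize %/% 2
  protos <- replicate(k, integer(config$n_bits), simplify = FALSE)
  for (b in seq_along(pairs)) {
    off <- (b - 1) * bsize
    side <- sample.int(bsize, half)
    protos[[pairs[[b]][1]]][off + side] <- 1L
    protos[[pairs[[b]][2]]][off + setdiff(seq_len(bsize), side)] <- 1L
    for (z in setdiff(seq_len(k), pairs[[b]]))
      protos[[z]][off + sample.int(bsize, half)] <- 1L
  }
  protos
}

hamming <- function(a, b) sum(a != b)

# near-equal split of n over the classes (balance within 1)
class_quota <- function(n, classes) {
  k <- length(classes)
  q <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) q[seq_len(r)] <- q[seq_len(r)] + 1
  stats::setNames(q, classes)
}

#' Generate synthetic 32-bit feature codes
#'
#' Draws one prototype per class (block-structured by default, mirroring the
#' pairwise-CSP binarization; see \code{\link{code_gen_config}}), redrawn
#' until all pairwise Hamming distances reach the configured separation, then
#' samples each code as its class prototype with independent bit flips at
#' rate \code{p}. Codes are distinct within each split; the class counts are
#' balanced to within one.
#'
#' @param config a \code{\link{code_gen_config}}.
#' @return List: \code{train} and \code{test} (lists of labelled
#'   \code{\link{feature_code}}), and \code{prototypes} (one 0/1 vector per
#'   class).
#' @examples
#' d <- gen_codes(code_gen_config(seed = 1))
#' length(d$train); length(d$test)  # 65, 15
#' @export
gen_codes <- function(config = code_gen_config()) {
  set.seed(config$seed)
  k <- length(config$classes)
  protos <- NULL
  weight <- floor(config$n_bits / 2)   # median binarization => balanced codes
  for (try in 1:500) {
    cand <- if (config$structure == "pairwise_blocks") {
      block_prototypes(config)
    } else {
      lapply(seq_len(k), function(i) {
        b <- integer(config$n_bits)
        b[sample.int(config$n_bits, weight)] <- 1L
        b
      })
    }
    d <- utils::combn(k, 2, function(ij) hamming(cand[[ij[1]]], cand[[ij[2]]]))
    if (all(d >= config$separation)) { protos <- cand; break }
  }
  if (is.null(protos))
    stop("could not draw prototypes at the requested separation")
  names(protos) <- config$classes
  # codes are distinct across splits, except at p = 0 where every sample IS
  # its class prototype and distinctness is vacuous
  seen <- character(0)
  draw_split <- function(n) {
    quota <- class_quota(n, config$classes)
    out <- list()
    for (cl in config$classes) {
      got <- 0
      tries <- 0
      while (got < quota[cl]) {
        tries <- tries + 1
        if (tries > 1000 * quota[cl])
          stop("could not generate enough distinct codes; lower n or raise p")
        flips <- stats::rbinom(config$n_bits, 1, config$p)
        bits <- (protos[[cl]] + flips) %% 2L
        key <- paste(bits, collapse = "")
        if (config$p > 0) {
          if (key %in% seen) next
          seen <<- c(seen, key)
        }
        out[[length(out) + 1]] <- feature_code(bits, cl)
        got <- got + 1
      }
    }
    out[sample.int(length(out))]
  }
  train <- draw_split(config$n_train)
  test <- draw_split(config$n_test)
  list(train = train, test = test, prototypes = protos)
}

#' Configuration for the synthetic EEG generator
#'
#' Emulates the imagined-speech recording protocol: multi-channel trials at
#' 250 samples/s, 3.5 s long, partitioned into a cue window, a pre-stimulus
#' baseline window and an imagery window. Each trial is 1/f (pink) background
#' noise on all channels; during the imagery window an alpha-band oscillation
#' is mixed in through one of three fixed, mutually orthogonal spatial
#' patterns — one per vowel class — scaled by \code{effect_size}.
#'
#' @param n_channels electrode count (16 by default for desk-scale runs; 64
#'   supported).
#' @param fs sampling rate (samples/s).
#' @param trial_length trial duration (seconds).
#' @param cue_window,baseline_window,imagery_window window boundaries in
#'   seconds, c(start, end); the three windows must partition the trial.
#' @param alpha_freq frequency of the planted class oscillation (Hz).
#' @param effect_size planted alpha amplitude over the noise standard
#'   deviation (dimensionless), through the class pattern's peak channel.
#' @param noise_exponent spectral exponent of the 1/f^a background noise.
#' @param noise_level background noise standard deviation (microvolts).
#' @param trials_per_class trials generated per class.
#' @param classes class labels.
#' @param seed RNG seed.
#' @return An object of class \code{eeg_gen_config}.
#' @export
eeg_gen_config <- function(n_channels = 16, fs = 250, trial_length = 3.5,
                           cue_window = c(0, 1), baseline_window = c(1, 2),
                           imagery_window = c(2, 3.5),
                           alpha_freq = 10, effect_size = 2,
                           noise_exponent = 1, noise_level = 1,
                           trials_per_class = 20,
                           classes = c("a", "i", "u"), seed = 42) {
  stopifnot(n_channels >= 2, fs > 0, trial_length > 0, effect_size >= 0,
            noise_level > 0, trials_per_class >= 1)
  ok <- isTRUE(all.equal(cue_window[2], baseline_window[1])) &&
        isTRUE(all.equal(baseline_window[2], imagery_window[1])) &&
        isTRUE(all.equal(imagery_window[2], trial_length)) &&
        cue_window[1] == 0
  if (!ok) stop("cue, baseline and imagery windows must partition the trial")
  structure(list(n_channels = n_channels, fs = fs, trial_length = trial_length,
                 cue_window = cue_window, baseline_window = baseline_window,
                 imagery_window = imagery_window, alpha_freq = alpha_freq,
                 effect_size = effect_size, noise_exponent = noise_exponent,
                 noise_level = noise_level, trials_per_class = trials_per_class,
                 classes = classes, seed = seed),
            class = "eeg_gen_config")
}

# 1/f^a noise via spectral shaping, unit variance, length n
pink_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  f <- stats::fft(w)
  freq <- c(1e-12, seq_len(n - 1))           # avoid dividing by zero at DC
  freq <- pmin(freq, n - freq)               # two-sided frequency index
  shape <- freq^(-exponent / 2)
  shape[1] <- 0                              # drop DC
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# fixed orthogonal spatial patterns (DCT basis), one column per class,
# normalized to peak amplitude 1
class_patterns <- function(n_channels, n_classes) {
  ch <- seq_len(n_channels)
  P <- sapply(seq_len(n_classes), function(k)
    cos(pi * k * (ch - 0.5) / n_channels))
  apply(P, 2, function(v) v / max(abs(v)))
}

window_samples <- function(window, fs) {
  seq(floor(window[1] * fs) + 1, floor(window[2] * fs))
}

#' Generate a synthetic imagined-speech EEG dataset
#'
#' See \code{\link{eeg_gen_config}} for the generative model. The baseline
#' window carries noise only; class information lives exclusively in the
#' alpha-band spatial pattern active during the imagery window, which is what
#' the band-pass/MEMD/CSP front-end is designed to recover.
#'
#' @param config an \code{\link{eeg_gen_config}}.
#' @return An object of class \code{eeg_dataset}: \code{trials} (list of
#'   channels x samples matrices, microvolts), \code{classes}, \code{fs},
#'   \code{baseline_window} and \code{task_window} (sample indices), and the
#'   generating \code{config}.
#' @export
gen_eeg <- function(config = eeg_gen_config()) {
  set.seed(config$seed)
  n <- round(config$trial_length * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  img <- window_samples(config$imagery_window, config$fs)
  P <- class_patterns(config$n_channels, length(config$classes))
  classes <- rep(config$classes, each = config$trials_per_class)
  classes <- classes[sample.int(length(classes))]
  trials <- lapply(classes, function(cl) {
    X <- t(vapply(seq_len(config$n_channels),
                  function(i) config$noise_level *
                    pink_noise(n, config$noise_exponent),
                  numeric(n)))
    if (config$effect_size > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- sin(2 * pi * config$alpha_freq * t[img] + phase)
      amp <- config$effect_size * config$noise_level
      k <- which(config$classes == cl)
      X[, img] <- X[, img] + amp * (P[, k] %o% osc)
    }
    X
  })
  structure(list(trials = trials, classes = classes, fs = config$fs,
                 baseline_window = window_samples(config$baseline_window, config$fs),
                 task_window = img, config = config),
            class = "eeg_dataset")
}

#' Majority-bit class prototypes of a labelled code set
#'
#' @param codes list of labelled \code{\link{feature_code}} objects.
#' @return Named list of 0/1 prototype vectors, one per class.
#' @export
code_prototypes <- function(codes) {
  cls <- codes_classes(codes, NULL)
  M <- codes_to_matrix(codes)
  protos <- lapply(split(seq_along(cls), cls), function(idx)
    as.integer(colMeans(M[idx, , drop = FALSE]) > 0.5))
  protos
}

#' Nearest-prototype (minimum Hamming distance) classification
#'
#' @param prototypes named list from \code{\link{code_prototypes}}.
#' @param codes codes to classify.
#' @return Character vector of predicted classes.
#' @export
nearest_prototype <- function(prototypes, codes) {
  M <- codes_to_matrix(codes)
  vapply(seq_len(nrow(M)), function(i) {
    d <- vapply(prototypes, function(p) hamming(M[i, ], p), numeric(1))
    names(prototypes)[which.min(d)]
  }, character(1))
}
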