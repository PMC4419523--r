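#' Zero-phase Butterworth band-pass filter
#'
#' Order-5 Butterworth band-pass (8--30 Hz by default) applied
#' forward-backward (\code{signal::filtfilt}) for zero phase distortion,
#' channel by channel.
#'
#' @param x an \code{eeg_dataset} (from \code{\link{gen_eeg}}) or a
#'   channels x samples matrix.
#' @param low,high band edges (Hz).
#' @param order filter order per pass.
#' @param fs sampling rate (required when \code{x} is a matrix).
#' @return The filtered dataset or matrix.
#' @export
bandpass <- function(x, low = 8, high = 30, order = 5, fs = NULL) {
  if (inherits(x, "eeg_dataset")) {
    x$trials <- lapply(x$trials, bandpass, low = low, high = high,
                       order = order, fs = x$fs)
    return(x)
  }
  if (is.null(fs)) stop("fs is required for matrix input")
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  t(apply(x, 1, function(ch) as.numeric(signal::filtfilt(bf, ch))))
}

#' Baseline correction from a pre-stimulus window
#'
#' Subtracts each channel's mean over the baseline window from the whole
#' trial.
#'
#' @param x an \code{eeg_dataset} or a channels x samples matrix.
#' @param baseline_window sample indices of the baseline window (taken from
#'   the dataset when \code{x} is an \code{eeg_dataset}).
#' @return The corrected dataset or matrix.
#' @export
baseline_correct <- function(x, baseline_window = NULL) {
  if (inherits(x, "eeg_dataset")) {
    if (is.null(baseline_window)) baseline_window <- x$baseline_window
    x$trials <- lapply(x$trials, baseline_correct, baseline_window)
    return(x)
  }
  if (is.null(baseline_window) || length(baseline_window) == 0)
    stop("empty baseline window")
  if (max(baseline_window) > ncol(x)) stop("baseline window outside trial")
  x - rowMeans(x[, baseline_window, drop = FALSE])
}

# --- MEMD ------------------------------------------------------------------

# Hammersley point set mapped to the unit hypersphere in d dimensions:
# base-p van der Corput sequences drive d-1 angular coordinates.
van_der_corput <- function(n, base) {
  vapply(seq_len(n), function(i) {
    v <- 0; f <- 1 / base; k <- i
    while (k > 0) { v <- v + f * (k %% base); k <- k %/% base; f <- f / base }
    v
  }, numeric(1))
}

hammersley_directions <- function(n_dir, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173, 179, 181,
              191, 193, 197, 199, 211, 223, 227, 229, 233, 239, 241, 251,
              257, 263, 269, 271, 277, 281, 283, 293, 307, 311)
  if (d - 1 > length(primes)) stop("too many channels for the direction set")
  U <- cbind(seq_len(n_dir) / n_dir,
             sapply(primes[seq_len(d - 1)],
                    function(p) van_der_corput(n_dir, p)))
  # inverse-normal map of low-discrepancy points, then normalize: a
  # quasi-uniform covering of the sphere
  Z <- stats::qnorm(pmin(pmax(U, 1e-6), 1 - 1e-6))
  Z / sqrt(rowSums(Z^2))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # collapse flat runs by keeping strict sign changes
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  which(diff(s) < 0) + 1L
}

# last-observation-carried-forward for the flat-run handling above
zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cumsum(ok)
  idx[idx == 0] <- 1
  x[ok][idx]
}

# natural cubic spline through shared knots `x`, one curve per row of Y;
# the tridiagonal system is factored once and solved for all rows at once
nat_spline_rows <- function(x, Y, xout) {
  n <- length(x)
  h <- diff(x)
  # second derivatives M (natural: M[1] = M[n] = 0), Thomas algorithm
  M <- matrix(0, nrow(Y), n)
  if (n > 2) {
    a <- h[1:(n - 2)]
    b <- 2 * (h[1:(n - 2)] + h[2:(n - 1)])
    cc <- h[2:(n - 1)]
    D <- 6 * ((Y[, 3:n, drop = FALSE] - Y[, 2:(n - 1), drop = FALSE]) /
                rep(h[2:(n - 1)], each = nrow(Y)) -
              (Y[, 2:(n - 1), drop = FALSE] - Y[, 1:(n - 2), drop = FALSE]) /
                rep(h[1:(n - 2)], each = nrow(Y)))
    m <- n - 2
    cp <- numeric(m)
    cp[1] <- cc[1] / b[1]
    D[, 1] <- D[, 1] / b[1]
    if (m > 1) for (i in 2:m) {
      den <- b[i] - a[i] * cp[i - 1]
      cp[i] <- cc[i] / den
      D[, i] <- (D[, i] - a[i] * D[, i - 1]) / den
    }
    M[, m + 1] <- D[, m]
    if (m > 1) for (i in (m - 1):1) M[, i + 1] <- D[, i] - cp[i] * M[, i + 2]
  }
  j <- findInterval(xout, x, all.inside = TRUE)
  hj <- h[j]
  u <- rep(x[j + 1] - xout, each = nrow(Y))   # distance to right knot
  v <- rep(xout - x[j], each = nrow(Y))       # distance to left knot
  hh <- rep(hj, each = nrow(Y))
  Mj <- M[, j, drop = FALSE]; Mj1 <- M[, j + 1, drop = FALSE]
  Yj <- Y[, j, drop = FALSE]; Yj1 <- Y[, j + 1, drop = FALSE]
  (Mj * u^3 + Mj1 * v^3) / (6 * hh) +
    (Yj / hh - Mj * hh / 6) * u + (Yj1 / hh - Mj1 * hh / 6) * v
}

# cubic-spline envelope of the multivariate signal through the instants
# `knots`, with up to two extrema mirrored at each boundary
envelope_through <- function(X, knots, n) {
  m <- length(knots)
  if (m < 2) return(NULL)
  li <- seq_len(min(2, m - 1)) + 1          # indices mirrored at the left end
  ri <- m - seq_len(min(2, m - 1))          # indices mirrored at the right end
  kk <- c(rev(2 * knots[1] - knots[li]), knots, 2 * knots[m] - knots[ri])
  ki <- c(rev(li), seq_len(m), ri)          # value source for each knot
  nat_spline_rows(kk, X[, knots[ki], drop = FALSE], seq_len(n))
}

# mean envelope and amplitude over all projection directions; NULL when too
# few extrema remain in every direction. Thin wrapper over the compiled
# kernel; memd_mean_envelope_r is the pure-R reference implementation.
memd_mean_envelope <- function(H, dirs) {
  env <- memd_envelope_cpp(H, dirs)
  if (env$used == 0) return(NULL)
  env
}

memd_mean_envelope_r <- function(H, dirs) {
  n <- ncol(H)
  proj <- dirs %*% H                       # n_dir x n
  env_sum <- matrix(0, nrow(H), n)
  amp_sum <- numeric(n)
  used <- 0
  for (k in seq_len(nrow(dirs))) {
    p <- proj[k, ]
    mx <- local_maxima(p)
    mn <- local_maxima(-p)
    if (length(mx) < 2 || length(mn) < 2) next
    eu <- envelope_through(H, mx, n)
    el <- envelope_through(H, mn, n)
    env_sum <- env_sum + (eu + el) / 2
    amp_sum <- amp_sum + sqrt(colSums(((eu - el) / 2)^2))
    used <- used + 1
  }
  if (used == 0) return(NULL)
  list(mean = env_sum / used, amp = amp_sum / used, n_dir_used = used)
}

#' Multivariate empirical mode decomposition
#'
#' Decomposes a multichannel signal into aligned intrinsic mode functions
#' (IMFs), fastest first. All channels are treated as one multivariate
#' signal: it is projected onto a quasi-uniform (Hammersley) set of
#' directions on the unit hypersphere, the signal is spline-interpolated at
#' each projection's extrema to get directional envelopes, and their mean is
#' subtracted (sifting) until a Rilling-style criterion is met; the IMF is
#' peeled off and the procedure repeats on the remainder. Because one mean
#' envelope is shared by all channels, every channel receives the same number
#' of IMFs (mode alignment). By construction the IMFs plus the residual
#' reconstruct the input exactly.
#'
#' @param x channels x samples matrix (>= 2 channels).
#' @param n_directions number of projection directions.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sift_tolerance Rilling tolerance: sifting stops when the fraction
#'   of samples with (mean envelope)/(envelope amplitude) above 0.05 falls
#'   below this value and no sample exceeds 0.5.
#' @param max_sifts per-IMF cap on sifting iterations.
#' @return An object of class \code{imf_set}: \code{imfs} (list of
#'   channels x samples matrices) and \code{residual}.
#' @export
memd <- function(x, n_directions = 64, max_imfs = 10,
                 sift_tolerance = 0.05, max_sifts = 15) {
  if (!is.matrix(x) || nrow(x) < 2) stop("memd needs a channels x samples matrix with >= 2 channels")
  if (!all(is.finite(x))) stop("non-finite samples in input")
  dirs <- hammersley_directions(n_directions, nrow(x))
  r <- x
  imfs <- list()
  for (m in seq_len(max_imfs)) {
    h <- r
    env <- memd_mean_envelope(h, dirs)
    if (is.null(env)) break                 # too few extrema: r is the residual
    for (s in seq_len(max_sifts)) {
      sx <- sqrt(colSums(env$mean^2)) / pmax(env$amp, 1e-12)
      if (mean(sx > 0.05) < sift_tolerance && all(sx < 0.5)) break
      h <- h - env$mean
      env <- memd_mean_envelope(h, dirs)
      if (is.null(env)) break
    }
    if (!is.null(env)) h <- h - env$mean
    imfs[[m]] <- h
    r <- r - h
    if (sum(r^2) < 1e-20 * sum(x^2)) break
  }
  structure(list(imfs = imfs, residual = r), class = "imf_set")
}

#' Select the dominant alpha-band IMF
#'
#' Returns the index of the IMF whose spectral power is most concentrated in
#' the given band: for each IMF the fraction of periodogram power inside the
#' band is averaged over channels, and the largest fraction wins (ties go to
#' the lowest index).
#'
#' @param imfset an \code{imf_set} from \code{\link{memd}}.
#' @param fs sampling rate (samples/s).
#' @param band frequency band (Hz), default the alpha band 8--12 Hz.
#' @return Integer index into \code{imfset$imfs}.
#' @export
select_alpha_imf <- function(imfset, fs, band = c(8, 12)) {
  if (length(imfset$imfs) == 0) stop("empty IMF set")
  frac <- vapply(imfset$imfs, function(M) {
    n <- ncol(M)
    freqs <- (seq_len(n) - 1) * fs / n
    keep <- freqs <= fs / 2
    inband <- keep & freqs >= band[1] & freqs <= band[2]
    mean(apply(M, 1, function(ch) {
      p <- Mod(stats::fft(ch))^2
      tot <- sum(p[keep])
      if (tot == 0) 0 else sum(p[inband]) / tot
    }))
  }, numeric(1))
  which.max(frac)
}

#' Morlet wavelet time-frequency power map
#'
#' Convolves the signal with complex Morlet atoms (fixed number of cycles)
#' and returns squared coefficient magnitudes.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (samples/s).
#' @param freqs analysis frequencies (Hz), default 1--40 Hz in 1 Hz steps.
#' @param n_cycles wavelet width in cycles.
#' @return Matrix of power, one row per frequency, one column per sample.
#' @export
morlet_tf <- function(x, fs, freqs = 1:40, n_cycles = 7) {
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("analysis frequencies must lie in (0, fs/2)")
  n <- length(x)
  X <- stats::fft(x)
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sd_t <- n_cycles / (2 * pi * f0)
    half <- min(floor(4 * sd_t * fs), floor((n - 1) / 2))
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sum(Mod(w))
    # FFT convolution, centred (same length as x)
    wp <- complex(length.out = n)
    wp[1:(half + 1)] <- w[(half + 1):(2 * half + 1)]
    wp[(n - half + 1):n] <- w[1:half]
    coef <- stats::fft(X * stats::fft(wp), inverse = TRUE) / n
    out[i, ] <- Mod(coef)^2
  }
  out
}

# --- CSP -------------------------------------------------------------------

# trace-normalized spatial covariance of one trial
spatial_cov <- function(X) {
  C <- tcrossprod(X)
  C / sum(diag(C))
}

#' Fit a common spatial patterns model for one class pair
#'
#' Averages the trace-normalized spatial covariances of each class and solves
#' the generalized eigenproblem \code{C1 w = lambda (C1 + C2) w} by whitening
#' the composite covariance. The eigenvalues lie in (0, 1); the
#' \code{n_filters/2} filters with the largest and smallest eigenvalues are
#' retained (variance maximally discriminative in either direction). If the
#' composite covariance is near-singular a small trace-scaled ridge is added.
#' Per-feature median binarization thresholds are fitted from the training
#' trials' own features.
#'
#' @param trials1,trials2 lists of channels x samples matrices, one class each.
#' @param n_filters number of spatial filters to keep (even).
#' @param class_pair length-2 character vector naming the two classes.
#' @return An object of class \code{csp_model}: \code{filters}
#'   (n_filters x channels), \code{eigenvalues}, \code{class_pair} and
#'   \code{feature_thresholds}.
#' @export
csp_fit <- function(trials1, trials2, n_filters = 10,
                    class_pair = c("1", "2")) {
  if (length(trials1) < 2 || length(trials2) < 2)
    stop("need at least 2 trials per class")
  if (n_filters %% 2 != 0) stop("n_filters must be even")
  C1 <- Reduce(`+`, lapply(trials1, spatial_cov)) / length(trials1)
  C2 <- Reduce(`+`, lapply(trials2, spatial_cov)) / length(trials2)
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values)) {
    Cc <- Cc + 1e-6 * (sum(diag(Cc)) / nrow(Cc)) * diag(nrow(Cc))
    ec <- eigen(Cc, symmetric = TRUE)
  }
  W <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)      # whitener of Cc
  S <- W %*% C1 %*% t(W)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  filters_all <- t(es$vectors) %*% W                    # rows: all filters
  lambda <- es$values                                   # sorted decreasing
  half <- n_filters / 2
  keep <- c(seq_len(half), nrow(filters_all) - rev(seq_len(half)) + 1)
  keep <- unique(keep[keep <= nrow(filters_all)])
  model <- structure(list(filters = filters_all[keep, , drop = FALSE],
                          eigenvalues = lambda[keep],
                          class_pair = class_pair,
                          feature_thresholds = NULL),
                     class = "csp_model")
  feats <- vapply(c(trials1, trials2), function(X) csp_features(model, X),
                  numeric(length(keep)))
  model$feature_thresholds <- apply(feats, 1, stats::median)
  model
}

#' Log-variance CSP features of one trial
#'
#' Applies the spatial filters and returns the log of each filtered
#' component's variance, normalized by the total retained variance.
#'
#' @param model a \code{\link{csp_fit}} model.
#' @param trial channels x samples matrix.
#' @return Numeric feature vector (one per filter).
#' @export
csp_features <- function(model, trial) {
  if (ncol(model$filters) != nrow(trial))
    stop("trial channel count does not match the CSP model")
  Z <- model$filters %*% trial
  v <- apply(Z, 1, stats::var)
  if (sum(v) == 0) stop("zero-variance trial")
  log(v / sum(v))
}

#' Binarize per-pair CSP features into one 32-bit code
#'
#' Each feature maps to 1 iff it strictly exceeds its training-set median
#' threshold; the three class-pair blocks are concatenated and zero-padded to
#' \code{n_bits}.
#'
#' @param feature_blocks list of numeric feature vectors, one per class pair.
#' @param models list of fitted \code{csp_model}s (same order), carrying the
#'   thresholds.
#' @param n_bits total code length (padded with zeros).
#' @param class class label to attach (NA for test codes).
#' @return A \code{\link{feature_code}}.
#' @export
binarize <- function(feature_blocks, models, n_bits = 32,
                     class = NA_character_) {
  bits <- unlist(mapply(function(f, m) {
    if (is.null(m$feature_thresholds)) stop("model thresholds not fitted")
    as.integer(f > m$feature_thresholds)
  }, feature_blocks, models, SIMPLIFY = FALSE))
  if (length(bits) > n_bits)
    stop("more features than bits; reduce n_filters")
  feature_code(c(bits, integer(n_bits - length(bits))), class)
}

#' Full EEG-to-feature-code extraction pipeline
#'
#' Chains band-pass filtering (8--30 Hz Butterworth, zero phase), baseline
#' correction, MEMD, dominant alpha-IMF selection, per-class-pair CSP fitted
#' on the training split only, log-variance features and median-threshold
#' binarization into 32-bit codes. CSP filters and thresholds never see the
#' test split. Duplicate codes within a split are collapsed (logged).
#'
#' @param dataset an \code{eeg_dataset}.
#' @param config list of pipeline settings; see Details. Unset entries take
#'   the defaults: \code{low = 8}, \code{high = 30}, \code{order = 5},
#'   \code{band = c(8, 12)}, \code{n_directions = 64}, \code{max_imfs = 8},
#'   \code{sift_tolerance = 0.05}, \code{n_filters = 10}, \code{n_bits = 32},
#'   \code{train_fraction = 0.75}, \code{seed = 1}, optional
#'   \code{train_idx} to fix the split, \code{artifact_hook} (a function
#'   applied to each trial matrix after baseline correction; identity by
#'   default — the slot where ICA-based artifact removal would sit).
#' @return List: \code{train} and \code{test} (lists of labelled
#'   \code{\link{feature_code}}), \code{models} (per-pair CSP), \code{split}
#'   (train/test trial indices), \code{log} (provenance messages).
#' @export
extract_pipeline <- function(dataset, config = list()) {
  defaults <- list(low = 8, high = 30, order = 5, band = c(8, 12),
                   n_directions = 64, max_imfs = 8, sift_tolerance = 0.05,
                   n_filters = 10, n_bits = 32, train_fraction = 0.75,
                   seed = 1, train_idx = NULL, artifact_hook = identity)
  cfg <- utils::modifyList(defaults, config)
  if (any(is.na(dataset$classes))) stop("pipeline needs labelled trials")
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  say("bandpass: Butterworth order %d, %g-%g Hz, zero phase", cfg$order,
      cfg$low, cfg$high)
  ds <- bandpass(dataset, cfg$low, cfg$high, cfg$order)
  ds <- baseline_correct(ds)
  ds$trials <- lapply(ds$trials, cfg$artifact_hook)

  say("memd: %d directions, max %d IMFs; alpha-IMF by %g-%g Hz power fraction",
      cfg$n_directions, cfg$max_imfs, cfg$band[1], cfg$band[2])
  task <- ds$task_window
  alpha <- lapply(ds$trials, function(X) {
    dec <- memd(X, cfg$n_directions, cfg$max_imfs, cfg$sift_tolerance)
    if (length(dec$imfs) == 0) return(X[, task, drop = FALSE])
    k <- select_alpha_imf(dec, ds$fs, cfg$band)
    dec$imfs[[k]][, task, drop = FALSE]
  })

  n <- length(alpha)
  if (is.null(cfg$train_idx)) {
    set.seed(cfg$seed)
    train_idx <- unlist(lapply(split(seq_len(n), dataset$classes), function(ix)
      sample(ix, round(cfg$train_fraction * length(ix)))))
  } else train_idx <- cfg$train_idx
  test_idx <- setdiff(seq_len(n), train_idx)
  say("split: %d train / %d test trials (stratified)", length(train_idx),
      length(test_idx))

  classes <- dataset$classes
  cls <- sort(unique(classes))
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    i1 <- intersect(train_idx, which(classes == pr[1]))
    i2 <- intersect(train_idx, which(classes == pr[2]))
    csp_fit(alpha[i1], alpha[i2], cfg$n_filters, pr)
  })
  say("csp: %d pairwise models, %d filters each; %d-bit codes (%d zero pad)",
      length(models), cfg$n_filters, cfg$n_bits,
      cfg$n_bits - length(models) * cfg$n_filters)

  make_code <- function(i) {
    blocks <- lapply(models, function(m) csp_features(m, alpha[[i]]))
    binarize(blocks, models, cfg$n_bits, classes[i])
  }
  dedupe <- function(codes, split_name) {
    keys <- vapply(codes, function(cd) paste(cd$bits, collapse = ""),
                   character(1))
    dup <- duplicated(keys)
    if (any(dup)) say("%s split: collapsed %d duplicate code(s)", split_name,
                      sum(dup))
    codes[!dup]
  }
  train <- dedupe(lapply(train_idx, make_code), "train")
  test <- dedupe(lapply(test_idx, make_code), "test")
  list(train = train, test = test, models = models,
       split = list(train_idx = train_idx, test_idx = test_idx), log = log)
}
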