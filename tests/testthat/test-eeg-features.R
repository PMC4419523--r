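fs <- 250

test_that("band-pass keeps the passband and kills the stopband", {
  t <- (0:999) / fs
  mid <- 200:800
  ten <- bandpass(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)), fs = fs)
  expect_gt(max(ten[1, mid]), 0.95)
  expect_lt(max(abs(ten[1, mid]) - 1), 0.05)
  two <- bandpass(rbind(sin(2 * pi * 2 * t), sin(2 * pi * 2 * t)), fs = fs)
  expect_lt(max(abs(two[1, mid])), 0.1)
  z <- bandpass(matrix(0, 2, 1000), fs = fs)
  expect_true(all(z == 0))
  expect_error(bandpass(matrix(0, 2, 100), low = 8, high = 200, fs = fs),
               "band edges")
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  x <- matrix(rnorm(2 * 300), 2)
  off <- x + 7
  expect_equal(baseline_correct(off, 50:100), baseline_correct(x, 50:100))
  const <- matrix(3.2, 2, 300)
  expect_true(all(baseline_correct(const, 1:50) == 0))
  zm <- x - rowMeans(x[, 50:100])
  expect_equal(baseline_correct(zm, 50:100), zm)
  expect_error(baseline_correct(x, integer(0)), "empty")
})

test_that("memd separates tones, reconstructs exactly, aligns modes", {
  set.seed(5)
  t <- (0:874) / fs
  x <- rbind(sin(2 * pi * 25 * t) + 0.8 * sin(2 * pi * 3 * t) + 0.05 * rnorm(875),
             0.9 * cos(2 * pi * 25 * t) + sin(2 * pi * 3 * t) + 0.05 * rnorm(875))
  dec <- memd(x)
  rec <- Reduce(`+`, dec$imfs) + dec$residual
  expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
  f25 <- vapply(dec$imfs, function(M)
    mean(apply(M, 1, power_fraction_near, fs, 25)), numeric(1))
  f3 <- vapply(dec$imfs, function(M)
    mean(apply(M, 1, power_fraction_near, fs, 3)), numeric(1))
  expect_gt(max(f25), 0.8)
  expect_gt(max(f3), 0.8)
  expect_lt(which.max(f25), which.max(f3))   # fast mode peeled first
  # every IMF has the same shape across channels (mode alignment)
  expect_true(all(vapply(dec$imfs, function(M)
    identical(dim(M), dim(x)), logical(1))))
  expect_error(memd(rbind(c(1, NA, 3), 1:3)), "non-finite")
  # constant signal: nothing to sift
  const <- matrix(1, 2, 100)
  dc <- memd(const)
  expect_length(dc$imfs, 0)
  expect_equal(dc$residual, const)
})

test_that("compiled envelope kernel matches the pure-R reference", {
  set.seed(6)
  x <- matrix(rnorm(3 * 400), 3)
  dirs <- memhnn:::hammersley_directions(16, 3)
  a <- memhnn:::memd_mean_envelope(x, dirs)
  b <- memhnn:::memd_mean_envelope_r(x, dirs)
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  expect_equal(a$amp, b$amp, tolerance = 1e-12)
  expect_equal(a$used, b$n_dir_used)
})

test_that("direction vectors cover the unit hypersphere evenly", {
  for (d in c(2, 4, 16)) {
    D <- memhnn:::hammersley_directions(64, d)
    expect_equal(dim(D), c(64, d))
    expect_equal(rowSums(D^2), rep(1, 64))
    expect_lt(max(abs(colMeans(D))), 0.3)   # roughly centred
  }
})

test_that("the dominant alpha-band IMF is selected", {
  set.seed(7)
  t <- (0:874) / fs
  x <- rbind(sin(2 * pi * 10 * t) + sin(2 * pi * 3 * t) + 0.05 * rnorm(875),
             cos(2 * pi * 10 * t) + 0.8 * sin(2 * pi * 3 * t) + 0.05 * rnorm(875))
  dec <- memd(x)
  k <- select_alpha_imf(dec, fs)
  expect_gt(mean(apply(dec$imfs[[k]], 1, power_fraction_near, fs, 10)), 0.8)
  one <- list(imfs = list(x), residual = 0 * x)
  expect_equal(select_alpha_imf(one, fs), 1)
})

test_that("Morlet map localizes tones and scales quadratically", {
  t <- (0:999) / fs
  x <- sin(2 * pi * 10 * t)
  m <- morlet_tf(x, fs, freqs = c(10, 20))
  mid <- 300:700
  expect_gt(mean(m[1, mid]) / mean(m[2, mid]), 10)
  expect_true(all(morlet_tf(rep(0, 500), fs) == 0))
  m2 <- morlet_tf(2 * x, fs, freqs = c(10, 20))
  expect_equal(m2, 4 * m, tolerance = 1e-10)
  expect_error(morlet_tf(x, fs, freqs = c(10, 200)), "frequencies")
})

test_that("CSP recovers planted variance structure and whitens the pencil", {
  set.seed(19)
  t1 <- planted_trials(12, hot = 1:2)
  t2 <- planted_trials(12, hot = 5:6)
  m <- csp_fit(t1, t2, n_filters = 4, class_pair = c("x", "y"))
  expect_equal(dim(m$filters), c(4, 6))
  expect_true(all(m$eigenvalues > 0 & m$eigenvalues < 1))
  # top filter: variance ratio between the classes >= 10
  v1 <- mean(vapply(t1, function(X) stats::var(as.numeric(m$filters[1, ] %*% X)),
                    numeric(1)))
  v2 <- mean(vapply(t2, function(X) stats::var(as.numeric(m$filters[1, ] %*% X)),
                    numeric(1)))
  expect_gt(v1 / v2, 10)
  # whitening identity on the retained subspace
  C1 <- Reduce(`+`, lapply(t1, memhnn:::spatial_cov)) / 12
  C2 <- Reduce(`+`, lapply(t2, memhnn:::spatial_cov)) / 12
  W <- m$filters %*% (C1 + C2) %*% t(m$filters)
  expect_lt(max(abs(W - diag(4))), 1e-8)
  # swapping class order complements the eigenvalues
  m2 <- csp_fit(t2, t1, n_filters = 4)
  expect_equal(sort(m2$eigenvalues), sort(1 - m$eigenvalues), tolerance = 1e-8)
  expect_error(csp_fit(t1[1], t2, 4), "at least 2")
})

test_that("CSP features are deterministic, equivariant, and maximal on the
           preferred pattern", {
  set.seed(23)
  t1 <- planted_trials(10, hot = 1:2)
  t2 <- planted_trials(10, hot = 5:6)
  m <- csp_fit(t1, t2, n_filters = 4)
  trial <- t1[[1]]
  expect_identical(csp_features(m, trial), csp_features(m, trial))
  # class-1 trial scores highest on a class-1-favoring filter
  f <- csp_features(m, trial)
  expect_equal(which.max(f), 1)
  # permuting channels in both model and trial leaves features unchanged
  perm <- sample(6)
  m_p <- m; m_p$filters <- m$filters[, perm]
  expect_equal(csp_features(m_p, trial[perm, ]), f)
  expect_error(csp_features(m, matrix(0, 6, 50)), "zero-variance")
})

test_that("binarization is strict, padded to 32 bits, and balanced", {
  set.seed(29)
  t1 <- planted_trials(10, hot = 1:3, n_ch = 12)
  t2 <- planted_trials(10, hot = 10:12, n_ch = 12)
  m <- csp_fit(t1, t2, n_filters = 10)
  # at exactly the median threshold the bit is 0 (strict inequality)
  cd0 <- binarize(list(m$feature_thresholds), list(m), 32)
  expect_equal(cd0$bits, rep(0L, 32))
  feats <- lapply(t1, function(X) csp_features(m, X))
  codes <- lapply(feats, function(f) binarize(list(f), list(m), 32))
  expect_true(all(vapply(codes, function(cd) length(cd$bits) == 32L, logical(1))))
  # training-set bit balance per feature is ~50% under median thresholds
  allf <- vapply(c(t1, t2), function(X) csp_features(m, X), numeric(10))
  bal <- rowMeans(allf > m$feature_thresholds)
  expect_true(all(abs(bal - 0.5) <= 0.05 + 1e-9))
  m_unfit <- m; m_unfit$feature_thresholds <- NULL
  expect_error(binarize(list(feats[[1]]), list(m_unfit)), "thresholds")
})

test_that("the extraction pipeline is deterministic and leak-free", {
  cfg <- eeg_gen_config(n_channels = 8, trials_per_class = 4, seed = 55)
  ds <- gen_eeg(cfg)
  pcfg <- list(n_filters = 4, seed = 55)
  e1 <- extract_pipeline(ds, pcfg)
  e2 <- extract_pipeline(ds, pcfg)
  expect_identical(lapply(e1$train, `[[`, "bits"), lapply(e2$train, `[[`, "bits"))
  # the split partitions the trials; emitted codes may be fewer (duplicates
  # within a split collapse, and the log records it)
  expect_setequal(c(e1$split$train_idx, e1$split$test_idx),
                  seq_along(ds$trials))
  expect_lte(length(e1$train) + length(e1$test), length(ds$trials))
  expect_true(all(vapply(e1$train, function(cd) length(cd$bits) == 32, logical(1))))
  # leakage guard: same training split, different (even absent) test trials,
  # identical CSP filters and thresholds
  idx <- e1$split$train_idx
  ds_cut <- ds
  keep <- sort(c(idx, e1$split$test_idx[1]))
  ds_cut$trials <- ds$trials[keep]
  ds_cut$classes <- ds$classes[keep]
  e3 <- extract_pipeline(ds_cut, c(pcfg, list(train_idx = match(idx, keep))))
  for (k in seq_along(e1$models)) {
    expect_equal(e1$models[[k]]$filters, e3$models[[k]]$filters)
    expect_equal(e1$models[[k]]$feature_thresholds,
                 e3$models[[k]]$feature_thresholds)
  }
  # empty test split is allowed
  e4 <- extract_pipeline(ds, c(pcfg, list(train_idx = seq_along(ds$trials))))
  expect_length(e4$test, 0)
})
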