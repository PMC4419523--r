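#' Pulse-train characterization of the synapse model
#'
#' Runs a potentiation train from the minimum-conductance state and a
#' depression train from the maximum, and summarizes endpoint rates and
#' saturation values — the simulated analogue of the device's measured
#' identical-pulse conductance response.
#'
#' @param n_pulses pulses per polarity.
#' @param params a \code{\link{device_params}}.
#' @param out_dir optional directory; when given, the two pulse tables and a
#'   key-value summary are written there.
#' @param seed RNG seed (only matters with rate jitter enabled).
#' @return List: \code{potentiation} and \code{depression} conductance
#'   sequences and \code{summary} (first-pulse rates and saturation values).
#' @export
simulate_device_response <- function(n_pulses = 200, params = device_params(),
                                     out_dir = NULL, seed = 1) {
  if (n_pulses < 1) stop("n_pulses must be >= 1 (usage: simulate-device --pulses N)")
  set.seed(seed)
  pot <- pulse_train(synapse_state(params$g_min, params), params, n_pulses,
                     "potentiation")
  dep <- pulse_train(synapse_state(params$g_max, params), params, n_pulses,
                     "depression")
  summ <- list(first_pulse_rate_pot = pot[1] - params$g_min,
               first_pulse_rate_dep = params$g_max - dep[1],
               saturation_pot = pot[n_pulses],
               saturation_dep = dep[n_pulses])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pulse_train(pot, file.path(out_dir, "potentiation.tsv"))
    write_pulse_train(dep, file.path(out_dir, "depression.tsv"))
    yaml::write_yaml(summ, file.path(out_dir, "device_summary.yaml"))
  }
  list(potentiation = pot, depression = dep, summary = summ)
}

#' End-to-end run: data generation, training and testing
#'
#' Orchestrates the whole system on synthetic data. With
#' \code{source = "codes"} it generates 32-bit feature codes directly
#' (65 train / 15 test at defaults); with \code{source = "eeg"} it generates
#' synthetic EEG and runs the full feature-extraction front-end first. The
#' crossbar is then trained with the half-bias scheme and the test codes are
#' classified by first-to-fire pairwise majority.
#'
#' @param source \code{"codes"} or \code{"eeg"}.
#' @param seed root seed; all randomness derives from it.
#' @param out_dir optional output directory for the report files (codes,
#'   trained crossbar, per-trial results, manifest).
#' @param code_config a \code{\link{code_gen_config}} (source "codes").
#' @param eeg_config an \code{\link{eeg_gen_config}} (source "eeg").
#' @param pipeline_config list for \code{\link{extract_pipeline}} (source
#'   "eeg").
#' @param config,device,neuron,grouping network parameter sets.
#' @param verbose print stage messages.
#' @return List: the fitted \code{\link{memhnn}} model, \code{results}
#'   (per-test-code data.frame from \code{\link{predict.memhnn}}),
#'   \code{test_accuracy}, \code{confusion} over classes plus abstain, and
#'   the \code{manifest}.
#' @export
run_all <- function(source = c("codes", "eeg"), seed = 42, out_dir = NULL,
                    code_config = NULL, eeg_config = NULL,
                    pipeline_config = list(),
                    config = learning_config(), device = device_params(),
                    neuron = neuron_params(), grouping = pair_grouping(),
                    verbose = FALSE) {
  source <- match.arg(source)
  say <- function(...) if (verbose) message(sprintf(...))
  if (source == "codes") {
    if (is.null(code_config)) code_config <- code_gen_config(seed = seed)
    say("stage gen-data: %d train / %d test codes", code_config$n_train,
        code_config$n_test)
    d <- gen_codes(code_config)
    train <- d$train; test <- d$test
  } else {
    if (is.null(eeg_config)) eeg_config <- eeg_gen_config(seed = seed)
    say("stage gen-data: synthetic EEG, %d channels, %d trials/class",
        eeg_config$n_channels, eeg_config$trials_per_class)
    ds <- gen_eeg(eeg_config)
    say("stage extract-features")
    pipeline_config$seed <- seed
    ext <- extract_pipeline(ds, pipeline_config)
    train <- ext$train; test <- ext$test
  }
  say("stage train: half-bias scheme, max %d epochs", config$epochs)
  fit <- memhnn(train, config = config, device = device, neuron = neuron,
                grouping = grouping)
  say("stage test: %d codes", length(test))
  results <- predict(fit, test)
  acc <- mean(results$predicted == results$true)
  confusion <- table(true = results$true,
                     predicted = factor(results$predicted,
                                        levels = c(grouping$classes, "abstain")))
  manifest <- list(source = source, seed = seed,
                   n_train = length(train), n_test = length(test),
                   epochs_run = fit$epochs_run,
                   train_accuracy = mean(fit$fitted == fit$classes),
                   test_accuracy = acc,
                   package_version = as.character(utils::packageVersion("memhnn")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_codes(train, file.path(out_dir, "train_codes.txt"))
    write_codes(test, file.path(out_dir, "test_codes.txt"))
    write_crossbar(fit$xbar, file.path(out_dir, "crossbar.tsv"))
    utils::write.table(results, file.path(out_dir, "results.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  say("test accuracy: %.1f%%", 100 * acc)
  list(fit = fit, results = results, test_accuracy = acc,
       confusion = confusion, manifest = manifest)
}
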