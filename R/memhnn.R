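#' 32-bit binary feature code
#'
#' The ordered binary vector driving the 32 pre-neurons, optionally carrying
#' the vowel class it encodes.
#'
#' @param bits 0/1 vector (length = number of pre-neurons, 32 by default).
#' @param class optional class label ("a", "i" or "u"); NA for test codes of
#'   unknown class.
#' @return An object of class \code{feature_code}.
#' @export
feature_code <- function(bits, class = NA_character_) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
  structure(list(bits = bits, class = class), class = "feature_code")
}

codes_to_matrix <- function(codes) {
  if (is.matrix(codes)) return(codes)
  do.call(rbind, lapply(codes, as_bits))
}

codes_to_list <- function(x) {
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  if (inherits(x, "feature_code")) return(list(x))
  x
}

codes_classes <- function(x, classes) {
  if (!is.null(classes)) return(as.character(classes))
  if (inherits(x, "feature_code")) return(as.character(x$class))
  if (is.list(x) && !is.matrix(x))
    return(vapply(x, function(cd)
      if (is.list(cd) && !is.null(cd$class)) as.character(cd$class)
      else NA_character_, character(1)))
  rep(NA_character_, if (is.matrix(x)) nrow(x) else length(x))
}

#' Fit (train) a memristive hybrid neural network
#'
#' The central fitting function. Initializes a cross-point synapse array at
#' mid-conductance and trains it with the modified half-bias scheme: for each
#' labelled 32-bit feature code, a potentiation phase raises the conductance
#' of the desired neurons' synapses at active bits (cell voltage 2 V) and a
#' depression phase lowers the rival neurons' synapses at active bits, while
#' every half-selected cell stays within the 1 V switching threshold and is
#' untouched. Training repeats over epochs until the network classifies its
#' training set perfectly or the epoch budget runs out.
#'
#' @param x training feature codes: a list of \code{\link{feature_code}}
#'   objects or 0/1 vectors, or a 0/1 matrix with one code per row.
#' @param classes character vector of class labels per code; may be omitted
#'   when \code{x} carries labelled \code{feature_code} objects.
#' @param config a \code{\link{learning_config}}.
#' @param device a \code{\link{device_params}}.
#' @param neuron a \code{\link{neuron_params}}.
#' @param grouping a \code{\link{pair_grouping}}.
#' @return An object of class \code{memhnn}: the trained crossbar, training
#'   history, fitted classes of the training codes and all parameter sets.
#'   Supports \code{print}, \code{summary}, \code{coef} (the 6 x 32
#'   conductance matrix), \code{predict} and \code{plot}.
#' @examples
#' set.seed(1)
#' d <- gen_codes(code_gen_config(n_train = 12, n_test = 6, seed = 7))
#' fit <- memhnn(d$train)
#' predict(fit, d$test)
#' @export
memhnn <- function(x, classes = NULL, config = learning_config(),
                   device = device_params(), neuron = neuron_params(),
                   grouping = pair_grouping()) {
  classes <- codes_classes(x, classes)
  codes <- codes_to_list(x)
  if (any(is.na(classes))) stop("every training code needs a class label")
  if (config$n_post != grouping$n_neurons)
    stop("config n_post does not match the grouping")
  xbar <- init_crossbar(config, device)
  tr <- train_crossbar(xbar, codes, classes, grouping, neuron)
  fitted <- vapply(codes, function(cd)
    classify(fire_record(tr$xbar, cd, neuron), grouping), character(1))
  structure(list(xbar = tr$xbar, config = config, device = device,
                 neuron = neuron, grouping = grouping,
                 epochs_run = tr$epochs_run, best_epoch = tr$best_epoch,
                 train_accuracy = tr$train_accuracy,
                 conductance_log = tr$log,
                 classes = classes, fitted = fitted,
                 call = match.call()),
            class = "memhnn")
}

#' @export
print.memhnn <- function(x, ...) {
  cat("Memristive hybrid neural network (half-bias trained crossbar)\n")
  cat(sprintf("  array: %d x %d (%d synapses), classes: %s\n",
              ncol(x$xbar$G), nrow(x$xbar$G), length(x$xbar$G),
              paste(x$grouping$classes, collapse = ", ")))
  cat(sprintf("  trained on %d codes, %d epoch(s); training accuracy %.1f%%\n",
              length(x$classes), x$epochs_run,
              100 * mean(x$fitted == x$classes)))
  invisible(x)
}

#' @export
summary.memhnn <- function(object, ...) {
  cm <- table(true = object$classes,
              predicted = factor(object$fitted,
                                 levels = c(object$grouping$classes, "abstain")))
  out <- list(epochs_run = object$epochs_run,
              train_accuracy = object$train_accuracy,
              confusion = cm,
              conductance = summary(as.numeric(object$xbar$G)),
              row_mean_conductance = rowMeans(object$xbar$G))
  class(out) <- "summary.memhnn"
  out
}

#' @export
print.summary.memhnn <- function(x, ...) {
  cat("Training accuracy by epoch:",
      paste(sprintf("%.2f", x$train_accuracy), collapse = " "), "\n")
  cat("Training confusion matrix:\n")
  print(x$confusion)
  cat("Row mean conductances (nA/V):",
      paste(sprintf("%.2f", x$row_mean_conductance), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.memhnn <- function(object, ...) object$xbar$G

#' Classify feature codes with a trained network
#'
#' Runs each code through the testing mode: row currents drive the six leaky
#' integrate-and-fire neurons, the fire record is reduced to per-group
#' first-to-fire winners and the majority class over the three groups is
#' returned (or \code{"abstain"}).
#'
#' @param object a fitted \code{\link{memhnn}}.
#' @param newdata feature codes (list, matrix or single
#'   \code{\link{feature_code}}).
#' @param classes optional true classes (for the \code{true} column).
#' @param ... unused.
#' @return A data.frame with one row per code: \code{true} (may be NA),
#'   \code{predicted}, \code{n_fired}, per-group winners and the six fire
#'   times (seconds; NA = did not fire).
#' @export
predict.memhnn <- function(object, newdata, classes = NULL, ...) {
  cls <- codes_classes(newdata, classes)
  codes <- codes_to_list(newdata)
  fires <- do.call(rbind, lapply(codes, function(cd)
    fire_record(object$xbar, cd, object$neuron)))
  pred <- apply(fires, 1, classify, grouping = object$grouping)
  winners <- t(apply(fires, 1, group_winners, grouping = object$grouping))
  out <- data.frame(true = cls, predicted = pred,
                    n_fired = rowSums(!is.na(fires)),
                    stringsAsFactors = FALSE)
  colnames(winners) <- paste0("group", seq_len(ncol(winners)))
  colnames(fires) <- paste0("t_fire", seq_len(ncol(fires)))
  cbind(out, winners, fires)
}

#' Plot a trained network
#'
#' \code{type = "weights"} draws the trained conductance matrix as an image
#' (rows = post-neurons); \code{type = "traces"} draws the six integrator
#' outputs for one feature code, the simulated analogue of the measured
#' testing-mode integrator traces (reset at 4 V, threshold at 3 V,
#' refractory return to 4 V).
#'
#' @param x a fitted \code{\link{memhnn}}.
#' @param type \code{"weights"} or \code{"traces"}.
#' @param code feature code for \code{type = "traces"}.
#' @param ... passed to the underlying graphics call.
#' @return Invisibly, the matrix drawn.
#' @export
plot.memhnn <- function(x, type = c("weights", "traces"), code = NULL, ...) {
  type <- match.arg(type)
  if (type == "weights") {
    G <- x$xbar$G
    graphics::image(t(G)[, nrow(G):1], axes = FALSE,
                    xlab = "pre-neuron (feature bit)", ylab = "post-neuron",
                    main = "Trained synapse conductances (nA/V)", ...)
    return(invisible(G))
  }
  if (is.null(code)) stop("type = 'traces' needs a feature code")
  tr <- run_trial(x$xbar, code, x$neuron, x$grouping)
  graphics::matplot(tr$time * 1e3, tr$traces, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "integrator output (V)",
                    main = "Post-neuron integrator outputs", ...)
  graphics::abline(h = x$neuron$v_th, lty = 2)
  invisible(tr$traces)
}
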