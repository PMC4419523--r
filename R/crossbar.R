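#' Learning configuration for the cross-point array
#'
#' Line voltages and training-loop settings of the modified half-bias scheme.
#' The spike levels are V_H = 5 V and V_L = 3 V; the common-mode level V_CM
#' sits at their midpoint (4 V), the unique choice for which every
#' half-selected cell sees at most \code{|V_H - V_CM| = 1 V}, i.e. at most
#' the device switching threshold V_R, so unselected synapses are never
#' disturbed. Targeted cells see the full \code{V_H - V_L = 2 V}.
#'
#' @param v_h high spike level (volts).
#' @param v_l low spike level (volts).
#' @param v_cm common-mode line level (volts).
#' @param pulses_per_phase identical pulses applied per phase per code.
#' @param epochs maximum training epochs (training stops early once training
#'   accuracy reaches 100\%).
#' @param init_g initial conductance of every cell (nA/V); default the
#'   mid-value between the device minimum and maximum.
#' @param n_pre number of pre-neurons (columns).
#' @param n_post number of post-neurons (rows).
#' @param depress_scheme which synapses the depression phase targets.
#'   \code{"desired_inactive"} (default): the labelled rows at the code's
#'   inactive bits, so each row converges to a saturated template of its
#'   class — own-class read currents approach 16 x 5.5 = 88 nA, matching the
#'   reported per-neuron input current of about 90 nA, while cross-class
#'   currents stay near 56 nA. \code{"rival_active"}: the labelled rows'
#'   group rivals at the code's active bits (the losers un-learn active
#'   inputs). \code{"both"}: both phases in sequence.
#' @return An object of class \code{learning_config}.
#' @export
learning_config <- function(v_h = 5, v_l = 3, v_cm = 4,
                            pulses_per_phase = 1, epochs = 20,
                            init_g = 3.5, n_pre = 32, n_post = 6,
                            depress_scheme = c("desired_inactive",
                                               "rival_active", "both")) {
  stopifnot(v_h > v_l, pulses_per_phase >= 1, epochs >= 1,
            n_pre >= 1, n_post >= 1)
  depress_scheme <- match.arg(depress_scheme)
  structure(list(v_h = v_h, v_l = v_l, v_cm = v_cm,
                 pulses_per_phase = pulses_per_phase, epochs = epochs,
                 init_g = init_g, n_pre = n_pre, n_post = n_post,
                 depress_scheme = depress_scheme),
            class = "learning_config")
}

check_bias_margins <- function(config, params) {
  if (!(config$v_h - config$v_l > params$v_switch))
    stop("V_H - V_L must exceed the switching threshold")
  if (abs(config$v_h - config$v_cm) > params$v_switch ||
      abs(config$v_cm - config$v_l) > params$v_switch)
    stop("V_CM must be within the switching threshold of both V_H and V_L")
  invisible(TRUE)
}

#' Initialize a cross-point synapse array
#'
#' Builds the crossbar (default 6 rows of post-neurons x 32 columns of
#' pre-neurons = 192 cells) with every cell at \code{init_g}, the mid-value
#' between the minimum and maximum conductance at defaults.
#'
#' @param config a \code{\link{learning_config}}.
#' @param params a \code{\link{device_params}}.
#' @return An object of class \code{crossbar}: a list with the conductance
#'   matrix \code{G} (rows = post-neurons, columns = pre-neurons), the device
#'   \code{params} and the \code{config}.
#' @examples
#' xb <- init_crossbar()
#' length(xb$G)  # 192 cells at defaults
#' @export
init_crossbar <- function(config = learning_config(), params = device_params()) {
  check_bias_margins(config, params)
  if (config$init_g < params$g_min || config$init_g > params$g_max)
    stop("init_g outside the device conductance bounds")
  G <- matrix(config$init_g, nrow = config$n_post, ncol = config$n_pre)
  structure(list(G = G, params = params, config = config), class = "crossbar")
}

as_bits <- function(code) {
  bits <- if (is.list(code) && !is.null(code$bits)) code$bits else code
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("feature code bits must be 0/1")
  bits
}

#' Line-voltage assignment for the potentiation phase
#'
#' Rows whose desired output is 1 have their top electrode (TE) tied to V_L;
#' all other rows sit at V_CM. Columns whose feature bit is 1 have their
#' bottom electrode (BE) at V_H; bit-0 columns at V_CM. A targeted cell
#' (desired row, active column) therefore sees BE - TE = 2 V and potentiates;
#' every other cell sees at most 1 V.
#'
#' @param label desired-output vector (0/1 per post-neuron).
#' @param code a feature code (0/1 vector or \code{\link{feature_code}}).
#' @param config a \code{\link{learning_config}}.
#' @return An object of class \code{bias_pattern}: list with \code{te}
#'   (volts per row), \code{be} (volts per column) and \code{phase}.
#' @export
assign_potentiation_bias <- function(label, code, config = learning_config()) {
  bits <- as_bits(code)
  label <- as.integer(label)
  if (length(label) != config$n_post || length(bits) != config$n_pre)
    stop("label/code length does not match crossbar dimensions")
  te <- ifelse(label == 1L, config$v_l, config$v_cm)
  be <- ifelse(bits == 1L, config$v_h, config$v_cm)
  structure(list(te = te, be = be, phase = "potentiation"),
            class = "bias_pattern")
}

#' Line-voltage assignment for the depression phase
#'
#' Rows targeted for depression get TE = V_H; other rows V_CM. Which cells
#' are depressed depends on the scheme. Under \code{"desired_inactive"}
#' (default) the labelled rows themselves are depressed at the code's
#' inactive bits (BE = V_L at bit-0 columns), sculpting each labelled row
#' into a template of its class. Under \code{"rival_active"} the labelled
#' rows' group rivals are depressed at the code's active bits (BE = V_L at
#' bit-1 columns). Either way a depressed cell sees a 2 V potential
#' difference of depressing polarity and every other cell at most 1 V.
#'
#' @param label desired-output vector (0/1 per post-neuron).
#' @param code a feature code.
#' @param config a \code{\link{learning_config}}.
#' @param rivals 0/1 vector of rival rows (used by the \code{"rival_active"}
#'   scheme); defaults to \code{1 - label}. The training loop passes the
#'   grouping-aware rival set of the code's class.
#' @param scheme overrides \code{config$depress_scheme}
#'   (\code{"desired_inactive"} or \code{"rival_active"}).
#' @return A \code{bias_pattern} (see \code{\link{assign_potentiation_bias}}).
#' @export
assign_depression_bias <- function(label, code, config = learning_config(),
                                   rivals = NULL, scheme = NULL) {
  bits <- as_bits(code)
  label <- as.integer(label)
  if (is.null(scheme)) scheme <- config$depress_scheme
  if (scheme == "both")
    stop("scheme 'both' yields two bias patterns; request each separately")
  if (is.null(rivals)) rivals <- 1L - label
  rivals <- as.integer(rivals)
  if (length(label) != config$n_post || length(bits) != config$n_pre)
    stop("label/code length does not match crossbar dimensions")
  if (scheme == "desired_inactive") {
    rows <- label
    cols <- 1L - bits
  } else {
    if (any(rivals & label)) stop("a row cannot be both desired and depressed")
    rows <- rivals
    cols <- bits
  }
  te <- ifelse(rows == 1L, config$v_h, config$v_cm)
  be <- ifelse(cols == 1L, config$v_l, config$v_cm)
  structure(list(te = te, be = be, phase = "depression"),
            class = "bias_pattern")
}

# Vectorized one-pulse update of the whole conductance matrix; identical
# arithmetic to apply_pulse(), applied cell-wise.
update_matrix <- function(G, V, params) {
  supra <- abs(V) > params$v_switch
  scale <- matrix(0, nrow(G), ncol(G))
  scale[supra] <- 1
  if (params$disturb_enabled) scale[!supra & V != 0] <- params$disturb_fraction
  jit <- if (params$jitter_sd > 0)
    pmax(0, 1 + matrix(stats::rnorm(length(G), 0, params$jitter_sd), nrow(G)))
  else 1
  pot <- V > 0
  dG <- ifelse(pot,
               params$alpha_pot * (params$g_max - G),
               -params$alpha_dep * (G - params$g_min))
  G <- G + scale * jit * dG
  pmin(pmax(G, params$g_min), params$g_max)
}

#' Apply a bias pattern to the crossbar
#'
#' Every cell (r, c) sees \code{v_cell = be[c] - te[r]}; each of the
#' \code{pulses} pulses applies the device update rule to all 192 cells
#' simultaneously.
#'
#' @param xbar a \code{\link{crossbar}} (from \code{\link{init_crossbar}}).
#' @param bias a \code{bias_pattern}.
#' @param pulses number of identical pulses.
#' @return The updated crossbar.
#' @export
apply_bias <- function(xbar, bias, pulses = 1) {
  stopifnot(inherits(bias, "bias_pattern"), pulses >= 0)
  V <- outer(-bias$te, bias$be, `+`)   # be[c] - te[r]
  for (i in seq_len(pulses)) xbar$G <- update_matrix(xbar$G, V, xbar$params)
  xbar
}

#' Row read currents for a feature code
#'
#' During testing every active pre-neuron drives its column at the read
#' voltage and each row's synaptic currents sum on that row's integrator:
#' \code{I_r = sum_c G[r, c] * v_read * bits[c]} (nA).
#'
#' @param xbar a \code{\link{crossbar}}.
#' @param code a feature code.
#' @param v_read read voltage (volts).
#' @return Numeric vector of per-row currents (nA).
#' @export
row_currents <- function(xbar, code, v_read = 1) {
  bits <- as_bits(code)
  if (length(bits) != ncol(xbar$G)) stop("code length does not match crossbar")
  if (abs(v_read) > xbar$params$v_read)
    stop("read voltage exceeds the non-destructive read regime")
  as.numeric(xbar$G %*% bits) * v_read
}

# One training presentation: potentiation phase then depression phase(s).
present_code <- function(xbar, bits, label, rivals, config) {
  bias_p <- assign_potentiation_bias(label, bits, config)
  xbar <- apply_bias(xbar, bias_p, config$pulses_per_phase)
  schemes <- if (config$depress_scheme == "both")
    c("desired_inactive", "rival_active") else config$depress_scheme
  for (sch in schemes) {
    if (sch == "rival_active" && !any(rivals == 1L)) next
    bias_d <- assign_depression_bias(label, bits, config, rivals, scheme = sch)
    xbar <- apply_bias(xbar, bias_d, config$pulses_per_phase)
  }
  xbar
}

#' Train a crossbar on labelled feature codes
#'
#' Supervised half-bias training: for each epoch and each code, the label
#' vector of the code's class selects the rows to potentiate (at active
#' bits) and the depression phase sculpts them per the configured scheme
#' (see \code{\link{learning_config}}).
#' Presentation order is reshuffled each epoch. Training stops as soon as the
#' network is fully trained — every training code classified correctly with
#' exactly its two labelled neurons firing — or at the epoch budget, in which
#' case the crossbar state from the best epoch under that criterion is kept
#' (i.e. training is halted at the point it was most completely trained). Most users call
#' \code{\link{memhnn}} instead, which wraps this loop and returns a fitted
#' model object.
#'
#' @param xbar a \code{\link{crossbar}}.
#' @param codes list of feature codes (each a 0/1 vector or
#'   \code{\link{feature_code}}).
#' @param classes character vector of class labels, one per code.
#' @param grouping a \code{\link{pair_grouping}}.
#' @param neuron a \code{\link{neuron_params}} (used for the early-stop
#'   training-accuracy check).
#' @return List: \code{xbar} (trained), \code{epochs_run}, \code{best_epoch}
#'   (the epoch whose state is returned), \code{train_accuracy} per epoch,
#'   and \code{log} (per-epoch mean conductance per row).
#' @export
train_crossbar <- function(xbar, codes, classes, grouping = pair_grouping(),
                           neuron = neuron_params()) {
  if (length(codes) != length(classes)) stop("codes and classes lengths differ")
  if (any(is.na(classes))) stop("unlabeled feature code in training input")
  config <- xbar$config
  labels <- lapply(classes, label_vector, grouping = grouping)
  rivals <- lapply(classes, rival_vector, grouping = grouping)
  bitlist <- lapply(codes, as_bits)
  acc <- numeric(0)
  log <- NULL
  best <- list(xbar = xbar, score = c(-1, -1), epoch = 0)
  for (ep in seq_len(config$epochs)) {
    # fresh presentation order each epoch, so no class dominates the most
    # recent updates of contested synapses at evaluation time
    ord <- sample.int(length(bitlist))
    for (i in ord)
      xbar <- present_code(xbar, bitlist[[i]], labels[[i]], rivals[[i]], config)
    recs <- lapply(bitlist, function(b) fire_record(xbar, b, neuron))
    pred <- vapply(recs, classify, character(1), grouping = grouping)
    acc <- c(acc, mean(pred == classes))
    log <- rbind(log, rowMeans(xbar$G))
    # a code is fully learned when exactly its two labelled neurons fire
    sig <- mean(vapply(seq_along(recs), function(i)
      identical(as.integer(!is.na(recs[[i]])), labels[[i]]), logical(1)))
    score <- c(acc[ep], sig)
    if (score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2]))
      best <- list(xbar = xbar, score = score, epoch = ep)
    if (acc[ep] == 1 && sig == 1) break
  }
  list(xbar = best$xbar, epochs_run = length(acc), best_epoch = best$epoch,
       train_accuracy = acc, log = log)
}

#' @export
print.crossbar <- function(x, ...) {
  cat(sprintf("memristive crossbar: %d post-neurons x %d pre-neurons (%d cells)\n",
              nrow(x$G), ncol(x$G), length(x$G)))
  cat(sprintf("conductance: mean %.3f nA/V, range [%.3f, %.3f] of [%.3g, %.3g]\n",
              mean(x$G), min(x$G), max(x$G), x$params$g_min, x$params$g_max))
  invisible(x)
}
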