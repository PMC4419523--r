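#' Device parameters for one PCMO memristive synapse
#'
#' Parametric model of a single AlOx/TiNx/PCMO cross-point synapse. The
#' conductance (in nA/V, i.e. the read current per volt of read bias) is
#' bounded in \code{[g_min, g_max]} and only changes when the voltage across
#' the cell exceeds the switching threshold \code{v_switch}. Supra-threshold
#' pulses move the conductance by a state-dependent step that shrinks as the
#' device approaches its bound, reproducing the saturating, symmetric
#' potentiation/depression response of the engineered device: roughly
#' 0.2--0.5 nA/V per pulse in the low-conductance state, falling to
#' 0.02--0.05 nA/V near saturation.
#'
#' @param g_min minimum conductance (nA/V).
#' @param g_max maximum conductance (nA/V).
#' @param v_switch switching threshold V_R (volts); pulses with
#'   \code{|v| <= v_switch} leave the state unchanged.
#' @param v_read maximum read voltage (volts).
#' @param alpha_pot per-pulse potentiation rate coefficient in (0,1);
#'   one pulse closes a fraction \code{alpha_pot} of the gap to \code{g_max}.
#' @param alpha_dep per-pulse depression rate coefficient in (0,1).
#' @param rate_low admissible per-pulse conductance change near
#'   \code{g_min} (nA/V), used by \code{\link{calibrate_rate}}.
#' @param rate_high admissible per-pulse change near \code{g_max} (nA/V).
#' @param disturb_enabled if TRUE, sub-threshold (half-selected) pulses apply
#'   a reduced-magnitude update scaled by \code{disturb_fraction}, for
#'   studying unintended switching; default FALSE reproduces the ideal
#'   half-bias scheme.
#' @param disturb_fraction fraction of the supra-threshold update applied by
#'   a sub-threshold pulse when \code{disturb_enabled}.
#' @param jitter_sd relative standard deviation of optional per-pulse rate
#'   jitter (0 = deterministic updates).
#'
#' @return An object of class \code{device_params}.
#' @examples
#' p <- device_params()
#' s <- synapse_state(p$g_min, p)
#' apply_pulse(s, p, 2)$g - p$g_min   # one potentiating pulse: ~0.35 nA/V
#' @export
device_params <- function(g_min = 1.5, g_max = 5.5,
                          v_switch = 1.0, v_read = 1.0,
                          alpha_pot = 0.0875, alpha_dep = 0.0875,
                          rate_low = c(0.2, 0.5), rate_high = c(0.02, 0.05),
                          disturb_enabled = FALSE, disturb_fraction = 0,
                          jitter_sd = 0) {
  stopifnot(g_min < g_max, v_switch > 0, v_read > 0,
            alpha_pot > 0, alpha_pot < 1, alpha_dep > 0, alpha_dep < 1,
            length(rate_low) == 2, length(rate_high) == 2,
            disturb_fraction >= 0, disturb_fraction <= 1, jitter_sd >= 0)
  structure(list(g_min = g_min, g_max = g_max,
                 v_switch = v_switch, v_read = v_read,
                 alpha_pot = alpha_pot, alpha_dep = alpha_dep,
                 rate_low = rate_low, rate_high = rate_high,
                 disturb_enabled = disturb_enabled,
                 disturb_fraction = disturb_fraction,
                 jitter_sd = jitter_sd),
            class = "device_params")
}

#' Conductance state of one synapse
#'
#' @param g conductance (nA/V); must lie in \code{[g_min, g_max]}.
#' @param params a \code{\link{device_params}} object.
#' @return An object of class \code{synapse_state} with field \code{g}.
#' @export
synapse_state <- function(g, params = device_params()) {
  stopifnot(is.finite(g))
  if (g < params$g_min || g > params$g_max)
    stop("conductance ", g, " outside [", params$g_min, ", ", params$g_max, "]")
  structure(list(g = g), class = "synapse_state")
}

#' Linear read current of a synapse
#'
#' The read regime is linear: at read bias \code{v} the device passes
#' \code{g * v} nA. Reads above \code{v_read} are refused because they would
#' leave the non-destructive regime.
#'
#' @param state a \code{\link{synapse_state}}.
#' @param v read voltage (volts), \code{|v| <= v_read}.
#' @param params a \code{\link{device_params}}.
#' @return Read current in nA.
#' @export
read_current <- function(state, v, params = device_params()) {
  stopifnot(is.finite(v))
  if (abs(v) > params$v_read)
    stop("read voltage ", v, " V exceeds the non-destructive read regime (|v| <= ",
         params$v_read, " V)")
  state$g * v
}

#' Apply one voltage pulse to a synapse
#'
#' Implements the threshold-gated, state-dependent update. With
#' \code{|v_cell| <= v_switch} the state is unchanged (or, with the disturb
#' model enabled, moved by \code{disturb_fraction} of the full update). A
#' supra-threshold pulse of potentiating polarity (cell voltage positive,
#' i.e. bottom electrode above top electrode) closes a fraction
#' \code{alpha_pot} of the remaining gap to \code{g_max}; the opposite
#' polarity closes \code{alpha_dep} of the gap to \code{g_min}. The result is
#' clamped to \code{[g_min, g_max]}.
#'
#' @param state a \code{\link{synapse_state}}.
#' @param params a \code{\link{device_params}}.
#' @param v_cell voltage across the cell, BE minus TE (volts).
#' @return The updated \code{synapse_state}.
#' @export
apply_pulse <- function(state, params, v_cell) {
  if (!is.finite(v_cell)) stop("non-finite pulse voltage")
  g <- state$g
  supra <- abs(v_cell) > params$v_switch
  scale <- if (supra) 1
           else if (params$disturb_enabled) params$disturb_fraction
           else 0
  if (scale > 0 && v_cell != 0) {
    jit <- if (params$jitter_sd > 0) max(0, 1 + stats::rnorm(1, 0, params$jitter_sd)) else 1
    if (v_cell > 0) {
      g <- g + scale * jit * params$alpha_pot * (params$g_max - g)
    } else {
      g <- g - scale * jit * params$alpha_dep * (g - params$g_min)
    }
    g <- min(max(g, params$g_min), params$g_max)
  }
  state$g <- g
  state
}

#' Calibrate the update coefficient from a printed per-pulse rate
#'
#' Converts a target per-pulse conductance change at the minimum-conductance
#' state into the dimensionless rate coefficient:
#' \code{alpha = target / (g_max - g_min)}. The target must lie in the
#' device's low-state rate window (\code{rate_low}, default 0.2--0.5 nA/V).
#' Both coefficients are set identically, matching the symmetric
#' potentiation/depression response of the device.
#'
#' @param params a \code{\link{device_params}}.
#' @param target_rate_at_gmin desired conductance change (nA/V) for one pulse
#'   applied at \code{g_min}.
#' @return \code{params} with \code{alpha_pot = alpha_dep} recalibrated.
#' @examples
#' calibrate_rate(device_params(), 0.35)$alpha_pot  # 0.0875
#' @export
calibrate_rate <- function(params, target_rate_at_gmin) {
  if (target_rate_at_gmin < params$rate_low[1] ||
      target_rate_at_gmin > params$rate_low[2])
    stop("target rate ", target_rate_at_gmin, " nA/V outside the low-state window [",
         params$rate_low[1], ", ", params$rate_low[2], "]")
  a <- target_rate_at_gmin / (params$g_max - params$g_min)
  params$alpha_pot <- a
  params$alpha_dep <- a
  params
}

#' Conductance response to a train of identical pulses
#'
#' Applies \code{n} identical supra-threshold pulses of one polarity and
#' records the conductance after each. The sequence is monotone and converges
#' geometrically to \code{g_max} (potentiation) or \code{g_min} (depression).
#'
#' @param state a \code{\link{synapse_state}} (starting point).
#' @param params a \code{\link{device_params}}.
#' @param n number of pulses (>= 1).
#' @param polarity \code{"potentiation"} or \code{"depression"}.
#' @param v_pulse pulse amplitude (volts); must exceed \code{v_switch}.
#' @return Numeric vector of length \code{n}: conductance after each pulse.
#' @export
pulse_train <- function(state, params, n, polarity = c("potentiation", "depression"),
                        v_pulse = 2) {
  polarity <- match.arg(polarity)
  stopifnot(n >= 1, v_pulse > params$v_switch)
  v <- if (polarity == "potentiation") v_pulse else -v_pulse
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- apply_pulse(state, params, v)
    out[i] <- state$g
  }
  out
}

#' @export
print.device_params <- function(x, ...) {
  cat("PCMO memristive synapse parameters\n")
  cat(sprintf("  conductance range : [%.3g, %.3g] nA/V\n", x$g_min, x$g_max))
  cat(sprintf("  switching threshold V_R: %.3g V (read <= %.3g V)\n",
              x$v_switch, x$v_read))
  cat(sprintf("  rate coefficients : alpha_pot = %.4g, alpha_dep = %.4g\n",
              x$alpha_pot, x$alpha_dep))
  cat(sprintf("  per-pulse rate at g_min: %.3g nA/V (window %.3g-%.3g)\n",
              x$alpha_pot * (x$g_max - x$g_min), x$rate_low[1], x$rate_low[2]))
  if (x$disturb_enabled)
    cat(sprintf("  disturb model ON: sub-threshold fraction %.3g\n", x$disturb_fraction))
  invisible(x)
}
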