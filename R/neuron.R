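#' Leaky integrate-and-fire post-neuron parameters
#'
#' The post-neuron is an inverting leaky integrator followed by a comparator.
#' From the reset level (4 V) the integrator output falls towards a
#' saturation level set by the input current, \code{v_sat = v_reset - gain *
#' i_in}; the neuron fires when the output drops strictly below the threshold
#' \code{v_th} (3 V). After the integration window a refractory phase fully
#' discharges the capacitor, returning every output to the reset level.
#'
#' The RC constant, transimpedance gain and window lengths are free
#' parameters of the simulation. The default gain puts the firing margin
#' \code{v_reset - v_th} (1 V) at 58 nA of row current, between the trained
#' own-class current of a typical code (about 15 active bits x 5.5 nA/V =
#' 83 nA — the roughly 90 nA per-neuron input regime of the hardware) and
#' the cross-class (about 43 nA) and untrained mid-conductance (about 53 nA)
#' currents. A correctly recognized code therefore fires exactly its two
#' labelled neurons, and an untrained uniform crossbar fires none.
#'
#' @param v_reset reset (initial) integrator output (volts).
#' @param v_th comparator threshold (volts); must be below \code{v_reset}.
#' @param tau integrator RC time constant (seconds).
#' @param gain transimpedance scale (volts per nA of row current).
#' @param t_integrate integration-window length (seconds).
#' @param t_refractory refractory-window length (seconds).
#' @param dt simulation step (seconds); must satisfy \code{dt < tau/10}.
#' @return An object of class \code{neuron_params}.
#' @export
neuron_params <- function(v_reset = 4, v_th = 3, tau = 10e-3, gain = 1 / 58,
                          t_integrate = 50e-3, t_refractory = 10e-3,
                          dt = tau / 1000) {
  stopifnot(v_reset > v_th, tau > 0, gain > 0,
            t_integrate > 0, t_refractory >= 0, dt > 0)
  if (dt >= tau / 10) stop("dt must be smaller than tau/10")
  structure(list(v_reset = v_reset, v_th = v_th, tau = tau, gain = gain,
                 t_integrate = t_integrate, t_refractory = t_refractory,
                 dt = dt),
            class = "neuron_params")
}

#' Integrator output at time t (closed form)
#'
#' For a constant input current the first-order leaky integrator gives
#' \code{v(t) = v_sat + (v_reset - v_sat) * exp(-t / tau)} with
#' \code{v_sat = v_reset - gain * i_in}: an almost linear early drop at rate
#' \code{gain * i_in / tau} that saturates at \code{v_sat}.
#'
#' @param params a \code{\link{neuron_params}}.
#' @param i_in input (row) current, nA; must be non-negative.
#' @param t time since reset (seconds); may be a vector.
#' @return Integrator output voltage(s).
#' @export
integrate_output <- function(params, i_in, t) {
  if (any(i_in < 0)) stop("negative input current is not a valid read")
  stopifnot(all(t >= 0))
  v_sat <- params$v_reset - params$gain * i_in
  v_sat + (params$v_reset - v_sat) * exp(-t / params$tau)
}

#' Time for the integrator to cross the firing threshold
#'
#' Solves \code{v(t) = v_th} in closed form:
#' \code{t = tau * log((v_reset - v_sat) / (v_th - v_sat))}. If the
#' saturation level does not lie strictly below the threshold the neuron
#' never fires and \code{NA} is returned; the neuron fires iff
#' \code{gain * i_in > v_reset - v_th} (1 V at defaults). Exact equality of
#' the saturation level with the threshold counts as not firing.
#'
#' @param params a \code{\link{neuron_params}}.
#' @param i_in input current, nA (vectorized).
#' @return Fire time(s) in seconds, or \code{NA} where the neuron never fires.
#' @export
time_to_fire <- function(params, i_in) {
  if (any(i_in < 0)) stop("negative input current is not a valid read")
  v_sat <- params$v_reset - params$gain * i_in
  tf <- rep(NA_real_, length(i_in))
  fires <- v_sat < params$v_th
  tf[fires] <- params$tau *
    log((params$v_reset - v_sat[fires]) / (params$v_th - v_sat[fires]))
  tf
}

#' Fire record of one feature code (closed form, no traces)
#'
#' The per-neuron fire times for a code: closed-form threshold-crossing
#' times of the six integrators, censored at the integration window. Used
#' where the integrator traces themselves are not needed; agrees with
#' \code{\link{run_trial}}'s fire record exactly.
#'
#' @param xbar a trained \code{\link{crossbar}}.
#' @param code a feature code.
#' @param params a \code{\link{neuron_params}}.
#' @param v_read read voltage (volts).
#' @return Numeric vector of fire times (seconds; NA = did not fire).
#' @export
fire_record <- function(xbar, code, params = neuron_params(), v_read = 1) {
  tf <- time_to_fire(params, row_currents(xbar, code, v_read))
  tf[!is.na(tf) & tf > params$t_integrate] <- NA_real_
  tf
}

#' Run one testing trial of the network
#'
#' Computes the six row currents for a feature code, steps all six
#' integrators over the integration window (exact exponential stepping with
#' step \code{dt}), records threshold crossings within the window, then
#' applies the refractory phase in which the capacitor discharges and every
#' trace returns to the reset level, leaving the neurons ready for the next
#' code.
#'
#' @param xbar a trained \code{\link{crossbar}}.
#' @param code a feature code.
#' @param params a \code{\link{neuron_params}}.
#' @param grouping a \code{\link{pair_grouping}} (carried along for
#'   convenience; not used in the dynamics).
#' @param v_read read voltage (volts).
#' @return List: \code{fires} (per-neuron fire time in seconds, \code{NA} if
#'   the neuron did not fire within the window), \code{currents} (nA),
#'   \code{traces} (matrix, one column per neuron) and \code{time} (seconds),
#'   covering integration plus refractory phases.
#' @export
run_trial <- function(xbar, code, params = neuron_params(),
                      grouping = pair_grouping(), v_read = 1) {
  i_in <- row_currents(xbar, code, v_read)
  tt <- seq(0, params$t_integrate, by = params$dt)
  # exact stepping of dv/dt = (v_sat - v)/tau coincides with the closed form
  traces <- vapply(i_in, function(I) integrate_output(params, I, tt),
                   numeric(length(tt)))
  tf <- time_to_fire(params, i_in)
  tf[!is.na(tf) & tf > params$t_integrate] <- NA_real_   # as in fire_record()
  if (params$t_refractory > 0) {
    tr <- seq(params$dt, params$t_refractory, by = params$dt)
    v_end <- traces[nrow(traces), ]
    # leaky-path discharge back to the reset rail, complete by end of phase
    tau_r <- params$t_refractory / 10
    rec <- vapply(v_end, function(v0)
      params$v_reset + (v0 - params$v_reset) * exp(-tr / tau_r),
      numeric(length(tr)))
    rec[length(tr), ] <- params$v_reset
    traces <- rbind(traces, rec)
    tt <- c(tt, params$t_integrate + tr)
  }
  list(fires = tf, currents = i_in, traces = traces, time = tt)
}
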