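#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter set for the LIF membrane equation
#' \eqn{\tau_m \, du/dt = -(u - u_{rest}) + R\,I(t)}, integrated by explicit
#' Euler at step `dt`. A neuron fires when its potential reaches `u_th` and
#' is then reset to `u_reset`.
#'
#' Defaults are the standard constants used throughout the package:
#' `u_rest = u_reset = 0` mV, `u_th = 60` mV, `tau_m = 30` ms, `dt = 1` ms.
#'
#' @param u_rest Resting membrane potential (mV).
#' @param u_reset Post-spike reset potential (mV).
#' @param u_th Firing threshold (mV).
#' @param tau_m Membrane time constant (ms); must be positive.
#' @param R Membrane resistance (dimensionless scale on the input current).
#' @param dt Integration step (ms); must satisfy `0 < dt < tau_m`.
#' @return An object of class `lif_params`.
#' @examples
#' p <- lif_params()
#' p$u_th
#' @export
lif_params <- function(u_rest = 0, u_reset = 0, u_th = 60,
                       tau_m = 30, R = 1, dt = 1) {
  stopifnot(is.numeric(u_rest), is.numeric(u_reset), is.numeric(u_th),
            is.numeric(tau_m), is.numeric(R), is.numeric(dt))
  if (!(u_th > u_rest)) stop("u_th must exceed u_rest")
  if (!(tau_m > 0)) stop("tau_m must be positive")
  if (!(dt > 0 && dt < tau_m)) stop("dt must satisfy 0 < dt < tau_m")
  structure(list(u_rest = u_rest, u_reset = u_reset, u_th = u_th,
                 tau_m = tau_m, R = R, dt = dt),
            class = "lif_params")
}

#' Create a population of LIF neurons at rest
#'
#' @param size Number of neurons.
#' @param params A [lif_params()] object.
#' @return An object of class `neuron_population` with fields `size`,
#'   `potentials` (mV), `last_spike_times` (ms; `NA` = never fired) and the
#'   current simulation time `t` (ms).
#' @export
neuron_population <- function(size, params = lif_params()) {
  stopifnot(is.numeric(size), length(size) == 1L, size >= 1)
  size <- as.integer(size)
  structure(list(size = size,
                 potentials = rep(params$u_rest, size),
                 last_spike_times = rep(NA_real_, size),
                 t = 0),
            class = "neuron_population")
}

#' Advance a LIF population by one integration step
#'
#' Explicit-Euler update of every membrane potential under the supplied input
#' current, followed by threshold detection. Neurons whose potential reaches
#' `u_th` are reported as fired, their `last_spike_times` set to the new
#' simulation time, and their potential reset to `u_reset`.
#'
#' @param pop A [neuron_population()].
#' @param input_current Numeric vector of input currents, one per neuron.
#' @param params A [lif_params()] object.
#' @return A list with elements `pop` (the advanced population) and `fired`
#'   (integer indices of neurons that fired on this step).
#' @examples
#' pop <- neuron_population(1)
#' lif_step(pop, 120, lif_params())$pop$potentials  # one Euler step from rest
#' @export
lif_step <- function(pop, input_current, params = lif_params()) {
  if (!inherits(pop, "neuron_population")) stop("pop must be a neuron_population")
  if (length(input_current) != pop$size)
    stop("input_current length (", length(input_current),
         ") does not match population size (", pop$size, ")")
  if (!all(is.finite(input_current))) stop("input_current must be finite")
  u <- pop$potentials
  u <- u + (params$dt / params$tau_m) *
    (-(u - params$u_rest) + params$R * input_current)
  t_new <- pop$t + params$dt
  fired <- which(u >= params$u_th)
  if (length(fired)) {
    u[fired] <- params$u_reset
    pop$last_spike_times[fired] <- t_new
  }
  pop$potentials <- u
  pop$t <- t_new
  list(pop = pop, fired = fired)
}

# Number of Euler steps from rest to threshold under a constant drive RI,
# i.e. the discrete analogue of t = tau_m * ln(RI / (RI - u_th)). Inf if the
# drive can never reach threshold.
lif_latency_steps <- function(params, RI) {
  reach <- params$u_rest + RI  # asymptotic potential
  if (reach <= params$u_th) return(Inf)
  frac <- 1 - (params$u_th - params$u_rest) / RI
  ceiling(log(frac) / log(1 - params$dt / params$tau_m))
}
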