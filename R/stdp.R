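#' Spike-timing-dependent plasticity parameters
#'
#' Exponential pair-based STDP: a presynaptic spike preceding a postsynaptic
#' spike by \eqn{|\Delta t|} potentiates the synapse by
#' \eqn{A_+ e^{\Delta t/\tau_+}} (with \eqn{\Delta t = t_{pre} - t_{post} < 0}),
#' and the reverse order depresses it by \eqn{A_- e^{-\Delta t/\tau_-}}.
#' Pairs further apart than `window` are ignored; the default window of
#' 5 time constants truncates the exponential below 1% of its peak.
#'
#' Defaults: `A_plus = 0.25`, `A_minus = 0.01`,
#' `tau_plus = tau_minus = 10` ms, weights bounded in `[0, 1]`.
#'
#' @param A_plus Potentiation learning rate (> 0).
#' @param A_minus Depression learning rate (> 0).
#' @param tau_plus,tau_minus STDP time constants (ms, > 0).
#' @param window Maximum `|delta t|` considered (ms).
#' @param w_min,w_max Weight bounds, `w_min < w_max`.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A_plus = 0.25, A_minus = 0.01,
                        tau_plus = 10, tau_minus = 10,
                        window = 5 * max(tau_plus, tau_minus),
                        w_min = 0, w_max = 1) {
  stopifnot(A_plus > 0, A_minus > 0, tau_plus > 0, tau_minus > 0, window > 0)
  if (!(w_min < w_max)) stop("w_min must be below w_max")
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 window = window, w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' STDP weight change for one spike pair
#'
#' @param t_pre Presynaptic spike time (ms); may be a vector.
#' @param t_post Postsynaptic spike time (ms); recycled against `t_pre`.
#' @param params An [stdp_params()] object.
#' @return Weight change(s): positive for pre-before-post, negative for
#'   post-before-pre, zero for coincident spikes or pairs outside the window.
#' @examples
#' stdp_delta(100, 110)  # pre leads by 10 ms: 0.25 * exp(-1)
#' stdp_delta(110, 100)  # pre lags by 10 ms: -0.01 * exp(-1)
#' @export
stdp_delta <- function(t_pre, t_post, params = stdp_params()) {
  if (!all(is.finite(t_pre)) || !all(is.finite(t_post)))
    stop("spike times must be finite")
  dt <- t_pre - t_post
  dw <- numeric(length(dt))
  pot <- dt < 0
  dep <- dt > 0
  dw[pot] <- params$A_plus * exp(dt[pot] / params$tau_plus)
  dw[dep] <- -params$A_minus * exp(-dt[dep] / params$tau_minus)
  dw[abs(dt) > params$window] <- 0
  dw
}

#' Construct a synapse matrix
#'
#' A (pre x post) weight matrix with a polarity, a plasticity flag, and an
#' optional structural mask. Weights are stored as non-negative magnitudes;
#' an inhibitory matrix contributes non-positive current downstream. Masked
#' entries (mask 0) are structurally absent: their weight is pinned at zero
#' and plasticity never touches them.
#'
#' @param weights Numeric matrix of non-negative weight magnitudes.
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @param plastic Logical; may the matrix be updated by [apply_stdp()]?
#' @param mask Optional 0/1 matrix of the same shape marking which synapses
#'   exist structurally. Default: all present.
#' @param params An [stdp_params()] object supplying the weight bounds.
#' @return An object of class `synapse_matrix`.
#' @export
synapse_matrix <- function(weights, polarity = c("excitatory", "inhibitory"),
                           plastic = FALSE, mask = NULL,
                           params = stdp_params()) {
  polarity <- match.arg(polarity)
  weights <- as.matrix(weights)
  if (is.null(mask)) mask <- matrix(1, nrow(weights), ncol(weights))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(weights))) stop("mask shape must match weights")
  weights <- weights * mask
  if (any(weights < params$w_min - 1e-12) || any(weights > params$w_max + 1e-12))
    stop("weights outside [w_min, w_max]")
  structure(list(weights = weights, polarity = polarity, plastic = plastic,
                 mask = mask, w_min = params$w_min, w_max = params$w_max),
            class = "synapse_matrix")
}

#' Apply STDP to a plastic synapse matrix
#'
#' Accumulates [stdp_delta()] over every (pre spike, post spike) pair within
#' the STDP window and clamps the result to `[w_min, w_max]`. Weights are
#' magnitudes: for an inhibitory matrix, potentiation (pre-before-post)
#' increases the magnitude of the negative-effect weight. Structurally absent
#' synapses are never modified.
#'
#' @param syn A plastic [synapse_matrix()].
#' @param pre_raster,post_raster Spike rasters ([record_raster()]) for the
#'   pre- and postsynaptic populations; `neuron_index` addresses rows
#'   (pre) and columns (post) of the weight matrix.
#' @param params An [stdp_params()] object.
#' @return The updated `synapse_matrix`.
#' @export
apply_stdp <- function(syn, pre_raster, post_raster, params = stdp_params()) {
  if (!inherits(syn, "synapse_matrix")) stop("syn must be a synapse_matrix")
  if (!syn$plastic) stop("apply_stdp called on a non-plastic synapse matrix")
  pre <- as.data.frame(pre_raster)
  post <- as.data.frame(post_raster)
  if (nrow(pre) == 0L || nrow(post) == 0L) return(syn)
  if (max(pre$neuron_index) > nrow(syn$weights) ||
      max(post$neuron_index) > ncol(syn$weights))
    stop("raster neuron_index outside synapse matrix dimensions")
  # all-pairs time differences, truncated to the STDP window
  dt <- outer(pre$time_ms, post$time_ms, "-")
  keep <- which(abs(dt) <= params$window & dt != 0)
  if (length(keep)) {
    d <- dt[keep]
    dw <- ifelse(d < 0,
                 params$A_plus * exp(d / params$tau_plus),
                 -params$A_minus * exp(-d / params$tau_minus))
    ij <- arrayInd(keep, dim(dt))
    flat <- (post$neuron_index[ij[, 2L]] - 1L) * nrow(syn$weights) +
      pre$neuron_index[ij[, 1L]]
    acc <- rowsum(dw, group = flat)
    idx <- as.integer(rownames(acc))
    w <- syn$weights
    w[idx] <- w[idx] + acc[, 1L]
    w <- pmin(pmax(w, params$w_min), params$w_max)
    syn$weights <- w * syn$mask
  }
  syn
}
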