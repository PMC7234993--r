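# Relaxed mean-field neural-mass dynamics on a structural connectome.
#
# Each region carries one average synaptic gating variable S_i in [0,1]:
#   dS_i = [-S_i/tau_s + r*(1 - S_i)*H(x_i)] dt + sigma dW_i
#   H(x)  = (a*x - b) / (1 - exp(-d*(a*x - b)))         (population rate, Hz)
#   x_i   = w_i*J*S_i + G*J*sum_{j!=i} C_ij*S_j + I_i   (input current, nA)
# w_i is the region's recurrent excitation-inhibition, I_i its excitatory
# subcortical input; G scales inter-regional signal flow over C.

#' Global mean-field model parameters
#'
#' Synaptic constants follow the reduced Wong-Wang lineage: J = 0.2609 nA,
#' a = 270 Hz/nA, b = 108 Hz, d = 0.154 s, with kinetic parameters
#' tau_s = 0.1 s and r = 0.641. `G` scales inter-regional coupling and
#' `sigma` the per-region Gaussian noise; both are estimated by the model
#' inversion. `dt` is the Euler-Maruyama step (must satisfy dt <= tau_s/10).
#'
#' @param G global coupling (dimensionless).
#' @param sigma noise amplitude of the gating SDE (dimensionless).
#' @param J synaptic coupling, nA.
#' @param a transfer-function gain, Hz/nA.
#' @param b transfer-function threshold, Hz.
#' @param d transfer-function slope constant, s.
#' @param tau_s synaptic gating time constant, s.
#' @param r_kin kinetic rate constant (dimensionless).
#' @param dt integration step, s.
#' @return `mfm_global_params` list.
#' @export
mfm_global_params <- function(G = 0.115, sigma = 0.05, J = 0.2609, a = 270,
                              b = 108, d = 0.154, tau_s = 0.1, r_kin = 0.641,
                              dt = 0.001) {
  p <- list(G = G, sigma = sigma, J = J, a = a, b = b, d = d, tau_s = tau_s,
            r_kin = r_kin, dt = dt)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals[names(vals) != "G"] <= 0) || G < 0) {
    stop("global parameters must be finite and positive", call. = FALSE)
  }
  if (dt > tau_s / 10 + 1e-12) {
    stop("dt must be at most tau_s/10 for a stable Euler-Maruyama step",
         call. = FALSE)
  }
  structure(p, class = "mfm_global_params")
}

#' Regional mean-field model parameters
#'
#' @param w length-N vector of recurrent excitation-inhibition strengths
#'   (dimensionless, non-negative).
#' @param I length-N vector of excitatory subcortical inputs, nA.
#' @return `mfm_regional_params` list.
#' @export
mfm_regional_params <- function(w, I) {
  w <- as.numeric(w); I <- as.numeric(I)
  if (length(w) != length(I)) stop("w and I must have equal length",
                                   call. = FALSE)
  if (any(!is.finite(w)) || any(!is.finite(I)) || any(w < 0) || any(I < 0)) {
    stop("regional parameters must be finite and non-negative", call. = FALSE)
  }
  structure(list(w = w, I = I), class = "mfm_regional_params")
}

#' Population firing-rate transfer function
#'
#' H(x) = (a*x - b)/(1 - exp(-d*(a*x - b))). The singularity at a*x = b is
#' removable with limit 1/d; a series expansion is used near it so the
#' function is smooth and monotone throughout.
#'
#' @param x input current(s), nA.
#' @param a gain, Hz/nA. @param b threshold, Hz. @param d slope constant, s.
#' @return Firing rate(s), Hz (non-negative).
#' @export
firing_rate <- function(x, a = 270, b = 108, d = 0.154) {
  if (any(!is.finite(x))) stop("non-finite input current", call. = FALSE)
  cpp_firing_rate(as.numeric(x), a, b, d)
}

#' Total input current per region
#'
#' x_i = w_i*J*S_i + G*J*sum_j C_ij*S_j + I_i, with the inter-regional sum
#' running over j != i (the diagonal of C is zero by contract; recurrent
#' self-input is carried exclusively by the w_i term).
#'
#' @param S length-N gating vector, entries in [0,1].
#' @param regional [mfm_regional_params].
#' @param global [mfm_global_params].
#' @param sc normalised `structural_connectome`.
#' @return length-N current vector, nA.
#' @export
input_current <- function(S, regional, global, sc) {
  N <- nrow(sc$weights)
  if (length(S) != N || length(regional$w) != N) {
    stop("dimension mismatch between S, parameters, and connectome",
         call. = FALSE)
  }
  cpp_input_current(sc$weights, as.numeric(S), regional$w, regional$I,
                    global$G, global$J)
}

#' Simulate neural gating dynamics
#'
#' Euler-Maruyama integration of the gating SDE with iid standard-normal
#' increments per region per step; S is clamped to [0,1] after every step.
#' The trajectory is a deterministic function of (inputs, seed).
#'
#' @param sc normalised `structural_connectome`.
#' @param global [mfm_global_params].
#' @param regional [mfm_regional_params].
#' @param duration_s simulated time, s.
#' @param seed RNG seed.
#' @param init_S initial gating value(s), default 0.1 everywhere.
#' @param thin store every `thin`-th step (1 = full rate).
#' @return `neural_trajectory`: list with `S` (T x N), `dt`, `thin`.
#' @export
simulate_neural <- function(sc, global, regional, duration_s, seed,
                            init_S = 0.1, thin = 1L) {
  N <- nrow(sc$weights)
  if (length(regional$w) != N) stop("regional parameter length != N",
                                    call. = FALSE)
  S0 <- rep_len(as.numeric(init_S), N)
  if (any(S0 < 0 | S0 > 1)) stop("init_S must lie in [0,1]", call. = FALSE)
  n_steps <- as.integer(round(duration_s / global$dt))
  set.seed(seed)
  S <- cpp_simulate_neural(sc$weights, regional$w, regional$I, global$G,
                           global$sigma, global$J, global$a, global$b,
                           global$d, global$tau_s, global$r_kin, global$dt,
                           n_steps, S0, as.integer(thin))
  structure(list(S = S, dt = global$dt * thin, thin = as.integer(thin)),
            class = "neural_trajectory")
}

#' Deterministic fixed point of the gating dynamics
#'
#' Damped self-consistent iteration for the noise-free equilibrium
#' S*/tau_s = r*(1 - S*)*H(x(S*)), used as an independent oracle for the
#' integrator. Non-convergence is flagged, not thrown.
#'
#' @param sc normalised `structural_connectome`.
#' @param global [mfm_global_params] (sigma ignored).
#' @param regional [mfm_regional_params].
#' @param init initial gating vector in [0,1]^N.
#' @param damping step fraction per iteration.
#' @param tol residual tolerance on dS/dt.
#' @param max_iter iteration cap.
#' @return list(S, residual, converged).
#' @export
find_fixed_point <- function(sc, global, regional, init = 0.1,
                             damping = 0.2, tol = 1e-10, max_iter = 20000L) {
  N <- nrow(sc$weights)
  S <- rep_len(as.numeric(init), N)
  if (any(S < 0 | S > 1)) stop("init must lie in [0,1]", call. = FALSE)
  resid <- Inf
  for (k in seq_len(max_iter)) {
    x <- input_current(S, regional, global, sc)
    # fixed point of S = tau_s * r * (1-S) * H(x(S))
    target <- global$tau_s * global$r_kin * (1 - S) * firing_rate(x, global$a,
                                                                  global$b,
                                                                  global$d)
    target <- pmin(pmax(target, 0), 1)
    S_new <- (1 - damping) * S + damping * target
    S <- S_new
    x <- input_current(S, regional, global, sc)
    resid <- max(abs(-S / global$tau_s +
                       global$r_kin * (1 - S) *
                         firing_rate(x, global$a, global$b, global$d)))
    if (resid < tol) break
  }
  list(S = S, residual = resid, converged = resid < tol)
}
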