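# Balloon-Windkessel hemodynamic forward model: per region, neural drive
# z(t) = S_i(t) feeds a four-state ODE (vasodilatory signal s, inflow f,
# venous volume v, deoxyhemoglobin q):
#   ds/dt = z - kappa*s - gamma_f*(f - 1)
#   df/dt = s
#   tau_v dv/dt = f - v^(1/alpha)
#   tau_v dq/dt = f*(1 - (1-rho)^(1/f))/rho - v^(1/alpha) * q/v
# with resting state (0,1,1,1) and BOLD readout
#   y = V0 * (k1*(1-q) + k2*(1 - q/v) + k3*(1-v)).

#' Hemodynamic model parameters
#'
#' Canonical Balloon-Windkessel constants: signal decay kappa = 0.65/s,
#' flow-dependent elimination gamma_f = 0.41/s, transit time tau_v = 0.98 s,
#' stiffness exponent alpha = 0.32, resting oxygen extraction rho = 0.34,
#' resting venous volume fraction V0 = 0.02, and BOLD coefficients
#' k1 = 7*rho, k2 = 2, k3 = 2*rho - 0.2. `tr` is the output sampling
#' interval emulating the scanner repetition time (2 s). The default burn-in
#' (50 s) covers the hemodynamic transient from the (0,1,1,1) start, whose
#' slowest mode decays at ~0.33/s; shorter burn-ins leave a residual
#' transient shared across regions that contaminates FC. `stride` updates
#' the (slow, >1 s time-constant) hemodynamic states every stride-th neural
#' step, i.e. with step stride*dt.
#'
#' @param kappa 1/s. @param gamma_f 1/s. @param tau_v s. @param alpha in (0,1).
#' @param rho in (0,1). @param V0 dimensionless. @param k1,k2,k3 BOLD
#'   coefficients. @param tr output sampling interval, s. @param burn_in_s
#'   initial transient discarded before analysis, s. @param stride
#'   hemodynamic update stride in neural steps.
#' @return `hemodynamic_params` list.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma_f = 0.41, tau_v = 0.98,
                               alpha = 0.32, rho = 0.34, V0 = 0.02,
                               k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2,
                               tr = 2, burn_in_s = 50, stride = 5L) {
  if (alpha <= 0 || alpha >= 1 || rho <= 0 || rho >= 1 ||
      any(c(kappa, gamma_f, tau_v, V0, tr) <= 0) || burn_in_s < 0 ||
      stride < 1) {
    stop("invalid hemodynamic parameters", call. = FALSE)
  }
  structure(list(kappa = kappa, gamma_f = gamma_f, tau_v = tau_v,
                 alpha = alpha, rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3,
                 tr = tr, burn_in_s = burn_in_s, stride = as.integer(stride)),
            class = "hemodynamic_params")
}

#' Simulate BOLD from a neural trajectory
#'
#' Integrates the Balloon-Windkessel system region-wise with explicit Euler
#' at the trajectory's own step, starting from the resting state (0,1,1,1).
#' Fully deterministic.
#'
#' @param traj `neural_trajectory` from [simulate_neural()] (thin = 1).
#' @param h [hemodynamic_params].
#' @return `bold_series`: list with `y` (T x N BOLD at the neural step),
#'   `dt`, `burn_in_steps`.
#' @export
simulate_bold <- function(traj, h = hemodynamic_params()) {
  stopifnot(inherits(traj, "neural_trajectory"))
  y <- cpp_simulate_bold(traj$S, traj$dt, h$kappa, h$gamma_f, h$tau_v,
                         h$alpha, h$rho, h$V0, h$k1, h$k2, h$k3, h$stride)
  burn <- as.integer(round(h$burn_in_s / traj$dt))
  structure(list(y = y, dt = traj$dt, burn_in_steps = burn),
            class = "bold_series")
}

#' Downsample BOLD to scan resolution
#'
#' Drops the burn-in transient, then keeps every (tr/dt)-th sample; tr must
#' be an integer multiple of the series step.
#'
#' @param bold `bold_series` at step `dt`.
#' @param tr target sampling interval, s.
#' @return `bold_series` at step `tr` with `burn_in_steps = 0`.
#' @export
downsample_to_tr <- function(bold, tr) {
  stopifnot(inherits(bold, "bold_series"))
  ratio <- tr / bold$dt
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("tr must be an integer multiple of the series step", call. = FALSE)
  }
  m <- as.integer(round(ratio))
  burn <- bold$burn_in_steps
  total <- nrow(bold$y)
  n_keep <- (total - burn) %/% m
  if (n_keep < 1) stop("series shorter than burn-in + one TR", call. = FALSE)
  idx <- burn + m * seq_len(n_keep)
  structure(list(y = bold$y[idx, , drop = FALSE], dt = tr,
                 burn_in_steps = 0L),
            class = "bold_series")
}

#' Closed-form Balloon-Windkessel steady state for constant drive
#'
#' For constant z the vasodilatory signal settles at 0, so f = 1 + z/gamma_f,
#' v = f^alpha, and q = f^alpha * (1 - (1-rho)^(1/f)) / rho. Used as an
#' independent oracle for the integrator.
#'
#' @param z constant neural drive.
#' @param h [hemodynamic_params].
#' @return list(s, f, v, q, y).
#' @export
bw_steady_state <- function(z, h = hemodynamic_params()) {
  f <- 1 + z / h$gamma_f
  v <- f^h$alpha
  q <- v * (1 - (1 - h$rho)^(1 / f)) / h$rho
  y <- h$V0 * (h$k1 * (1 - q) + h$k2 * (1 - q / v) + h$k3 * (1 - v))
  list(s = 0, f = f, v = v, q = q, y = y)
}
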