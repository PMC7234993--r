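# Model inversion: estimate the global coupling G, global noise amplitude
# sigma, and the regional recurrent excitation-inhibition w_i and subcortical
# input I_i by maximising the Pearson similarity between simulated and
# empirical functional connectivity.
#
# The scheme alternates an E-like step (simulate FC at the current
# parameters with fixed noise seeds) with an M-like step (a damped
# Gauss-Newton update on the upper-triangle FC residual, with a
# finite-difference Jacobian over all parameters). Common random numbers --
# the same noise seeds for every objective evaluation -- make the stochastic
# objective deterministic, so the accepted-objective trace is non-decreasing
# by construction.

#' Default parameter bounds for the inversion
#'
#' Brackets the scale set by the synaptic coupling J = 0.2609 nA:
#' w in [0, 2], I in [0, 0.5] nA, G in [0, 5], sigma in [0.001, 0.1].
#'
#' @return Named list of (low, high) pairs.
#' @export
default_bounds <- function() {
  list(G = c(0, 5), sigma = c(0.001, 0.1), w = c(0, 2), I = c(0, 0.5))
}

#' Inversion configuration
#'
#' The objective is evaluated on simulations of `sim_duration_s` seconds
#' (averaging `noise_realizations` fixed-seed runs in Fisher-z space), while
#' the finite-difference Jacobian uses shorter `jac_duration_s` simulations
#' -- a two-stage schedule that keeps the search cheap without touching the
#' recorded objective. `dt` may be coarser than the simulator default; it
#' must still satisfy dt <= tau_s / 10.
#'
#' @param n_outer_iterations outer Gauss-Newton iterations.
#' @param n_random_inits restarts (first starts at `init`, later ones are
#'   jittered).
#' @param sim_duration_s seconds per official objective evaluation
#'   (including burn-in).
#' @param jac_duration_s seconds per Jacobian-column simulation.
#' @param base_seed seed anchoring all noise realizations.
#' @param bounds per-parameter (low, high), as [default_bounds()].
#' @param fd_steps named list of absolute finite-difference perturbations
#'   for G, sigma, w, and I, each small relative to the parameter's
#'   physiological scale (a bound-range fraction would step G across the
#'   network's bifurcation and destroy the linearisation).
#' @param damping initial Levenberg-style damping factor.
#' @param tol absolute objective-improvement tolerance for convergence.
#' @param noise_realizations simulations averaged per objective evaluation.
#' @param dt integration step used during fitting, s.
#' @param init named list with starting w and I levels (scalars recycled);
#'   G and sigma are initialised by a coarse grid search (see `init_grid`).
#' @param init_grid named list with candidate G, sigma, and baseline-I
#'   values scanned (with short simulations) before the Gauss-Newton stage;
#'   geometric grids spanning the bounds by default. The whole-network
#'   dynamics bifurcate from a fluctuating to a saturated regime as G grows
#'   and as the operating point set by the baseline subcortical input
#'   rises, so the scan must bracket both.
#' @param max_tries damping increases attempted per iteration.
#' @return `fit_config` list.
#' @export
fit_config <- function(n_outer_iterations = 12, n_random_inits = 1,
                       sim_duration_s = 250, jac_duration_s = 70,
                       base_seed = 42, bounds = default_bounds(),
                       fd_steps = list(G = 0.01, sigma = 0.004, w = 0.05,
                                       I = 0.015),
                       damping = 1, tol = 1e-4,
                       noise_realizations = 2, dt = 0.002,
                       init = list(w = 0.9, I = 0.3),
                       init_grid = list(
                         G = exp(seq(log(0.02), log(4.5), length.out = 12)),
                         sigma = exp(seq(log(0.002), log(0.08),
                                         length.out = 4)),
                         I = c(0.25, 0.30, 0.35)),
                       max_tries = 6) {
  stopifnot(n_outer_iterations >= 1, tol > 0, n_random_inits >= 1,
            all(vapply(bounds, function(b) b[1] < b[2], logical(1))))
  structure(list(n_outer_iterations = n_outer_iterations,
                 n_random_inits = n_random_inits,
                 sim_duration_s = sim_duration_s,
                 jac_duration_s = jac_duration_s, base_seed = base_seed,
                 bounds = bounds, fd_steps = fd_steps, damping = damping,
                 tol = tol, noise_realizations = noise_realizations,
                 dt = dt, init = init, init_grid = init_grid,
                 max_tries = max_tries),
            class = "fit_config")
}

theta_pack <- function(G, sigma, w, I) c(G, sigma, w, I)
theta_unpack <- function(theta, N) {
  list(G = theta[1], sigma = theta[2], w = theta[3:(N + 2)],
       I = theta[(N + 3):(2 * N + 2)])
}

theta_clip <- function(theta, N, bounds) {
  lo <- c(bounds$G[1], bounds$sigma[1], rep(bounds$w[1], N),
          rep(bounds$I[1], N))
  hi <- c(bounds$G[2], bounds$sigma[2], rep(bounds$w[2], N),
          rep(bounds$I[2], N))
  pmin(pmax(theta, lo), hi)
}

sim_fc_at <- function(theta, sc, cfg, global_template, h, duration_s,
                      realizations) {
  N <- nrow(sc$weights)
  p <- theta_unpack(theta, N)
  g <- global_template
  g$G <- p$G; g$sigma <- p$sigma; g$dt <- cfg$dt
  reg <- mfm_regional_params(pmax(p$w, 0), pmax(p$I, 0))
  zacc <- NULL
  for (k in seq_len(realizations)) {
    y <- simulate_bold_tr(sc, g, reg, duration_s = duration_s,
                          seed = cfg$base_seed + 1000L * k, h = h)
    if (nrow(y) < 3) {
      stop("simulation shorter than burn-in + three volumes", call. = FALSE)
    }
    sds <- apply(y, 2, stats::sd)
    if (any(!is.finite(y)) || any(sds == 0)) return(NULL)
    z <- fisher_z(stats::cor(y))
    zacc <- if (is.null(zacc)) z else zacc + z
  }
  r <- fisher_z_inv(zacc / realizations)
  diag(r) <- 1
  functional_connectome((r + t(r)) / 2, sc$parcellation, "r")
}

#' Objective: similarity of simulated to empirical FC at candidate parameters
#'
#' Simulates neural -> BOLD -> TR downsampling -> Pearson FC (averaged over
#' `noise_realizations` fixed-seed runs in z-space) and correlates the
#' upper triangle with the empirical FC. Deterministic given the config's
#' base seed. A degenerate simulation returns -1 with attribute
#' `failed = TRUE` and is treated as a rejected step.
#'
#' @param theta parameter vector c(G, sigma, w, I).
#' @param sc normalised `structural_connectome`.
#' @param emp_fc empirical `functional_connectome` in r-space.
#' @param cfg [fit_config].
#' @param global_template [mfm_global_params] carrying the fixed constants.
#' @param h [hemodynamic_params].
#' @param duration_s override of cfg$sim_duration_s (optional).
#' @return Similarity r (scalar).
#' @export
objective <- function(theta, sc, emp_fc, cfg,
                      global_template = mfm_global_params(dt = cfg$dt),
                      h = hemodynamic_params(),
                      duration_s = cfg$sim_duration_s) {
  fc <- sim_fc_at(theta, sc, cfg, global_template, h, duration_s,
                  cfg$noise_realizations)
  if (is.null(fc)) return(structure(-1, failed = TRUE))
  fc_similarity(fc, emp_fc)
}

#' Invert the relaxed mean-field model against an empirical FC
#'
#' Damped Gauss-Newton on the upper-triangle FC residual with a
#' finite-difference Jacobian over (G, sigma, w, I); a step is accepted only
#' if it improves the (common-random-number, hence deterministic) similarity
#' objective, otherwise the damping grows. Returns the best of
#' `n_random_inits` restarts together with the SC-FC baseline correlation.
#'
#' @param sc normalised `structural_connectome`.
#' @param emp_fc empirical `functional_connectome` in r-space.
#' @param cfg [fit_config].
#' @param global_template [mfm_global_params] for the fixed constants.
#' @param h [hemodynamic_params].
#' @param verbose print one line per outer iteration?
#' @return `fit_result`: list with `params` (fitted G, sigma, w, I),
#'   `objective_trace`, `best_similarity`, `baseline`, `converged`,
#'   `seed_used`, `parcellation`.
#' @export
fit_rmfm <- function(sc, emp_fc, cfg = fit_config(),
                     global_template = mfm_global_params(dt = cfg$dt),
                     h = hemodynamic_params(), verbose = FALSE) {
  N <- nrow(sc$weights)
  if (stats::sd(upper_tri_vec(emp_fc$values)) == 0) {
    stop("degenerate empirical FC: zero variance", call. = FALSE)
  }
  baseline <- sc_fc_baseline(sc, emp_fc)
  emp_ut <- upper_tri_vec(emp_fc$values)
  bounds <- cfg$bounds
  range_vec <- c(diff(bounds$G), diff(bounds$sigma), rep(diff(bounds$w), N),
                 rep(diff(bounds$I), N))
  # stage 0: coarse scan of the two global parameters at the baseline
  # regional levels, using short single-realization simulations. The
  # objective surface over (G, sigma) is multimodal -- distinct dynamical
  # regimes can mimic each other's FC -- so restarts are seeded from the
  # best cells of *distinct* regions of the scan rather than from jitter
  # around one point, and the search stops once a restart clearly beats
  # the raw SC-FC baseline.
  w0 <- rep_len(cfg$init$w, N)
  I0 <- rep_len(cfg$init$I, N)
  if (!is.null(cfg$init$G) && !is.null(cfg$init$sigma)) {
    # explicit global init: skip the scan, single start
    starts <- list(list(G = cfg$init$G, sigma = cfg$init$sigma,
                        I0 = cfg$init$I))
  } else {
    grid_I <- if (is.null(cfg$init_grid$I)) cfg$init$I else cfg$init_grid$I
    grid <- expand.grid(G = cfg$init_grid$G, sigma = cfg$init_grid$sigma,
                        I = grid_I)
    grid_obj <- apply(grid, 1, function(gs) {
      fc <- sim_fc_at(theta_pack(gs[["G"]], gs[["sigma"]], w0,
                                 rep(gs[["I"]], N)),
                      sc, cfg, global_template, h, cfg$jac_duration_s, 1L)
      if (is.null(fc)) -1 else fc_similarity(fc, emp_fc)
    })
    ord <- order(grid_obj, decreasing = TRUE)
    starts <- list()
    for (k in ord) {
      cand <- list(G = grid$G[k], sigma = grid$sigma[k], I0 = grid$I[k])
      # G and the baseline input level jointly position the network
      # relative to its bifurcation; restarts must differ in one of them
      distinct <- all(vapply(starts, function(s) {
        abs(log(cand$G / s$G)) > 0.4 || abs(cand$I0 - s$I0) > 0.04
      }, logical(1)))
      if (distinct) starts[[length(starts) + 1L]] <- cand
      if (length(starts) >= cfg$n_random_inits) break
    }
  }

  best <- NULL
  for (restart in seq_along(starts)) {
    theta <- theta_pack(starts[[restart]]$G, starts[[restart]]$sigma, w0,
                        rep_len(starts[[restart]]$I0, N))
    theta <- theta_clip(theta, N, bounds)
    fc_cur <- sim_fc_at(theta, sc, cfg, global_template, h,
                        cfg$sim_duration_s, cfg$noise_realizations)
    if (is.null(fc_cur)) stop("simulation failed at the initial parameters",
                              call. = FALSE)
    obj <- fc_similarity(fc_cur, emp_fc)
    trace <- obj
    lambda <- cfg$damping
    stalls <- 0L
    converged <- FALSE
    hi_vec <- c(bounds$G[2], bounds$sigma[2], rep(bounds$w[2], N),
                rep(bounds$I[2], N))
    hstep <- c(cfg$fd_steps$G, cfg$fd_steps$sigma, rep(cfg$fd_steps$w, N),
               rep(cfg$fd_steps$I, N))
    for (iter in seq_len(cfg$n_outer_iterations)) {
      # E-like step: linearise the simulated-FC map at the current
      # parameters with short common-random-number simulations
      fc0 <- sim_fc_at(theta, sc, cfg, global_template, h,
                       cfg$jac_duration_s, 1L)
      if (is.null(fc0)) break
      base_ut <- upper_tri_vec(fc0$values)
      P <- length(theta)
      J <- matrix(0, length(base_ut), P)
      for (p in seq_len(P)) {
        tp <- theta
        # step towards the interior when near the upper bound
        dir <- if (theta[p] + hstep[p] <= hi_vec[p]) 1 else -1
        tp[p] <- theta[p] + dir * hstep[p]
        fcp <- sim_fc_at(tp, sc, cfg, global_template, h,
                         cfg$jac_duration_s, 1L)
        if (is.null(fcp)) next
        J[, p] <- dir * (upper_tri_vec(fcp$values) - base_ut) / hstep[p]
      }
      # residual against the official (long, averaged) simulated FC, so the
      # proposed step corrects real mismatch rather than short-run noise
      resid <- emp_ut - upper_tri_vec(fc_cur$values)
      JtJ <- crossprod(J)
      Jtr <- crossprod(J, resid)
      accepted <- FALSE
      lam <- lambda
      for (try in seq_len(cfg$max_tries)) {
        A <- JtJ + lam * diag(diag(JtJ) + 1e-8)
        delta <- tryCatch(solve(A, Jtr), error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- theta_clip(theta + as.numeric(delta), N, bounds)
          fc_cand <- sim_fc_at(cand, sc, cfg, global_template, h,
                               cfg$sim_duration_s, cfg$noise_realizations)
          cobj <- if (is.null(fc_cand)) -1 else fc_similarity(fc_cand, emp_fc)
          if (!is.null(fc_cand) && cobj > obj) {
            gain <- cobj - obj
            theta <- cand
            obj <- as.numeric(cobj)
            fc_cur <- fc_cand
            lambda <- max(lam / 3, 1e-4)
            accepted <- TRUE
            if (gain < cfg$tol) converged <- TRUE
            break
          }
        }
        lam <- lam * 5
      }
      if (!accepted) {
        lambda <- lam
        stalls <- stalls + 1L
      } else {
        stalls <- 0L
      }
      trace <- c(trace, obj)
      if (verbose) {
        message(sprintf("  iter %2d  objective %.4f  damping %.3g%s", iter,
                        obj, lambda, if (accepted) "" else "  (no step)"))
      }
      if (converged || stalls >= 2L) break
    }
    fit <- list(params = theta_unpack(theta, N), objective_trace = trace,
                best_similarity = max(trace), baseline = baseline,
                converged = converged, seed_used = cfg$base_seed,
                restart = restart, parcellation = sc$parcellation,
                config = cfg)
    if (is.null(best) || fit$best_similarity > best$best_similarity) {
      best <- fit
    }
    # a fit that clearly explains FC beyond the anatomical baseline is
    # good enough to stop exploring other regimes
    if (best$best_similarity > baseline + 0.02) break
  }
  class(best) <- "fit_result"
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("rmfm fit: similarity %.3f (SC-FC baseline %.3f), ",
                     "G = %.3f, sigma = %.4f, %d iterations%s\n"),
              x$best_similarity, x$baseline, x$params$G, x$params$sigma,
              length(x$objective_trace) - 1,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Align two cohort fits for a regional parameter contrast
#'
#' @param fit_a,fit_b `fit_result` objects on the same parcellation.
#' @return data.frame with region_id, network, w_a, w_b, I_a, I_b.
#' @export
contrast_ready_params <- function(fit_a, fit_b) {
  pa <- fit_a$parcellation; pb <- fit_b$parcellation
  if (nrow(pa) != nrow(pb) || !identical(pa$network, pb$network)) {
    stop("fits are on different parcellations", call. = FALSE)
  }
  data.frame(region_id = pa$region_id, network = pa$network,
             w_a = fit_a$params$w, w_b = fit_b$params$w,
             I_a = fit_a$params$I, I_b = fit_b$params$I)
}
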