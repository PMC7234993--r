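# Synthetic study generator: modular structural connectomes with mirrored
# hemispheres, ground-truth regional parameters for HC / GE / TLE cohorts
# (network-targeted shifts in the directions reported for the two epilepsy
# syndromes), cohort BOLD/FC simulation, and subject x region feature tables
# with planted, network-localised group effects. Everything is a pure
# function of (arguments, seed).

#' Cohort specification for ground-truth parameter generation
#'
#' Encodes a cohort as per-network additive shifts on the regional model
#' parameters relative to a common baseline. Default presets:
#' \describe{
#'   \item{HC}{no shifts.}
#'   \item{TLE}{subcortical input reduced (-0.06 nA) and recurrent
#'     excitation-inhibition increased (+0.15) in limbic and somatomotor
#'     networks.}
#'   \item{GE}{subcortical input increased (+0.04 nA) in every network;
#'     recurrent excitation-inhibition unchanged.}
#' }
#'
#' @param name "HC", "GE", or "TLE".
#' @param w_shift named numeric: per-network additive shift to w.
#' @param i_shift named numeric: per-network additive shift to I, nA.
#' @param n_subjects cohort size (>= 3).
#' @param subject_noise_sd SD of subject-level multiplicative-free jitter
#'   added to both w and I (on I it is scaled by 0.3 to respect its smaller
#'   magnitude).
#' @param side_fraction fraction of patients labelled right-sided (TLE only;
#'   drives hemisphere flipping in the statistics stage).
#' @return `cohort_spec` list.
#' @export
cohort_spec <- function(name = c("HC", "GE", "TLE"), w_shift = numeric(),
                        i_shift = numeric(), n_subjects = 20,
                        subject_noise_sd = 0.02, side_fraction = 0) {
  name <- match.arg(name)
  if (n_subjects < 3) stop("n_subjects must be >= 3", call. = FALSE)
  if (any(!is.finite(c(w_shift, i_shift, 0)))) {
    stop("shifts must be finite", call. = FALSE)
  }
  structure(list(name = name, w_shift = w_shift, i_shift = i_shift,
                 n_subjects = as.integer(n_subjects),
                 subject_noise_sd = subject_noise_sd,
                 side_fraction = side_fraction),
            class = "cohort_spec")
}

#' Default cohort presets
#'
#' @param n_subjects subjects per cohort.
#' @return Named list of [cohort_spec] objects for HC, GE, and TLE.
#' @export
default_cohorts <- function(n_subjects = 20) {
  list(
    HC = cohort_spec("HC", n_subjects = n_subjects),
    GE = cohort_spec("GE",
                     i_shift = c(limbic = 0.04, somatomotor = 0.04,
                                 default = 0.04, control = 0.04),
                     n_subjects = n_subjects),
    TLE = cohort_spec("TLE",
                      w_shift = c(limbic = 0.15, somatomotor = 0.15),
                      i_shift = c(limbic = -0.06, somatomotor = -0.06),
                      n_subjects = n_subjects, side_fraction = 0.5)
  )
}

#' Generate a modular structural connectome with mirrored hemispheres
#'
#' Regions split into left (ids 0..N/2-1) and right (N/2..N-1) hemispheres
#' with homologue pairing i <-> i + N/2. Network labels are contiguous
#' blocks, mirrored across hemispheres. Edges are Bernoulli draws (denser
#' within networks) with log-normal weights (stronger within networks);
#' homotopic pairs always connect. The draw is repeated up to 10 times until
#' the graph is connected.
#'
#' @param n_regions even integer.
#' @param n_networks number of intrinsic networks; must divide n_regions.
#' @param p_within,p_between edge probabilities within / between networks.
#' @param weight_scale multiplier on within-network weights (> 1 makes
#'   within-network edges stronger).
#' @param networks network names (recycled to n_networks).
#' @param seed RNG seed.
#' @return list(sc = `structural_connectome`, parcellation).
#' @export
make_synthetic_sc <- function(n_regions = 40, n_networks = 4,
                              p_within = 0.6, p_between = 0.15,
                              weight_scale = 2,
                              networks = c("limbic", "somatomotor",
                                           "default", "control"),
                              seed = 1) {
  if (n_regions %% 2 != 0) stop("n_regions must be even", call. = FALSE)
  if (n_networks < 2 || n_regions %% n_networks != 0 ||
      (n_regions / 2) %% (n_networks) != 0) {
    stop("n_networks must be >= 2 and divide each hemisphere", call. = FALSE)
  }
  if (p_within < p_between) {
    stop("p_within must be >= p_between", call. = FALSE)
  }
  networks <- rep_len(networks, n_networks)
  half <- n_regions / 2L
  per_net <- half / n_networks
  net_half <- rep(networks, each = per_net)
  parc <- parcellation(
    region_id = 0:(n_regions - 1L),
    name = c(paste0("L_", net_half, "_", seq_len(half)),
             paste0("R_", net_half, "_", seq_len(half))),
    hemisphere = rep(c("left", "right"), each = half),
    network = c(net_half, net_half),
    homologue_id = c(half:(n_regions - 1L), 0:(half - 1L))
  )
  set.seed(seed)
  for (attempt in 1:10) {
    same_net <- outer(parc$network, parc$network, `==`)
    p <- ifelse(same_net, p_within, p_between)
    ut <- upper.tri(p)
    adj <- matrix(0, n_regions, n_regions)
    adj[ut] <- stats::rbinom(sum(ut), 1, p[ut])
    wts <- matrix(0, n_regions, n_regions)
    wts[ut] <- adj[ut] * exp(stats::rnorm(sum(ut), 0, 0.5)) *
      ifelse(same_net[ut], weight_scale, 1)
    # homotopic edges: every region connects to its contralateral homologue
    for (i in seq_len(half)) {
      wts[i, i + half] <- exp(stats::rnorm(1, 0, 0.5)) * weight_scale
    }
    wts <- wts + t(wts)
    g <- igraph::graph_from_adjacency_matrix(wts > 0, mode = "undirected")
    if (igraph::is_connected(g)) {
      return(list(sc = normalize_sc(structural_connectome(wts, parc)),
                  parcellation = parc))
    }
  }
  stop("failed to draw a connected connectome in 10 attempts", call. = FALSE)
}

#' Ground-truth regional parameters for a cohort
#'
#' w_i = base_w + w_shift(network(i)) and I_i = base_I + i_shift(network(i)),
#' plus seeded region-level Gaussian jitter, clipped to the inversion bounds.
#' Errors if the shifts push more than 10 percent of regions onto a bound.
#'
#' @param parc [parcellation].
#' @param spec [cohort_spec] carrying the per-network shifts.
#' @param base_w,base_I baseline parameter levels.
#' @param w_jitter_sd,i_jitter_sd SD of region-level heterogeneity.
#' @param bounds list with `w` and `I` (low, high) pairs.
#' @param seed RNG seed.
#' @return [mfm_regional_params].
#' @export
make_ground_truth <- function(parc, spec, base_w = 0.9, base_I = 0.3,
                              w_jitter_sd = 0.10, i_jitter_sd = 0.02,
                              bounds = default_bounds(), seed = 1) {
  bad <- setdiff(names(spec$w_shift), unique(parc$network))
  bad <- c(bad, setdiff(names(spec$i_shift), unique(parc$network)))
  if (length(bad)) {
    stop("shift names unknown network(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  shift_of <- function(shifts, nets) {
    s <- shifts[nets]
    s[is.na(s)] <- 0
    unname(s)
  }
  set.seed(seed)
  n <- nrow(parc)
  w <- base_w + shift_of(spec$w_shift, parc$network) +
    stats::rnorm(n, 0, w_jitter_sd)
  I <- base_I + shift_of(spec$i_shift, parc$network) +
    stats::rnorm(n, 0, i_jitter_sd)
  w_cl <- pmin(pmax(w, bounds$w[1]), bounds$w[2])
  I_cl <- pmin(pmax(I, bounds$I[1]), bounds$I[2])
  n_clip <- sum(w_cl != w) + sum(I_cl != I)
  if (n_clip > 0.1 * 2 * n) {
    stop("shifts drive > 10% of regional parameters outside bounds",
         call. = FALSE)
  }
  mfm_regional_params(w_cl, I_cl)
}

#' Simulate per-subject functional connectomes for a cohort
#'
#' Each subject gets seeded Gaussian jitter on (w, I) around the cohort's
#' regional parameters, then neural -> BOLD -> TR downsampling -> Pearson FC.
#'
#' @param sc normalised `structural_connectome`.
#' @param global [mfm_global_params].
#' @param regional cohort-level [mfm_regional_params].
#' @param n_subjects number of subjects.
#' @param subject_noise_sd SD of subject-level jitter on w (0.3x on I).
#' @param seed base seed; subject s uses seed + s for jitter and noise.
#' @param h [hemodynamic_params].
#' @param duration_s simulated seconds per subject (including burn-in);
#'   the default gives 500 s of usable signal, i.e. 250 volumes at TR = 2 s.
#' @return list of `functional_connectome` objects (one per subject).
#' @export
generate_cohort_fc <- function(sc, global, regional, n_subjects,
                               subject_noise_sd = 0.02, seed = 100,
                               h = hemodynamic_params(), duration_s = 550) {
  parc <- sc$parcellation
  n <- nrow(parc)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- seed + s
    set.seed(sseed)
    w_s <- pmax(regional$w + stats::rnorm(n, 0, subject_noise_sd), 0)
    I_s <- pmax(regional$I + stats::rnorm(n, 0, 0.3 * subject_noise_sd), 0)
    y <- simulate_bold_tr(sc, global,
                          mfm_regional_params(w_s, I_s),
                          duration_s = duration_s, seed = sseed + 10000L,
                          h = h)
    compute_fc(y, parc)
  })
}

#' Fused neural + hemodynamic simulation at scan resolution
#'
#' Runs the gating SDE and the Balloon-Windkessel system in one pass and
#' returns BOLD sampled every TR after the burn-in. Produces exactly the
#' same numbers as [simulate_neural()] + [simulate_bold()] +
#' [downsample_to_tr()] with the same seed, without storing the full-rate
#' trajectories.
#'
#' @param sc normalised `structural_connectome`.
#' @param global [mfm_global_params].
#' @param regional [mfm_regional_params].
#' @param duration_s simulated seconds (including burn-in).
#' @param seed RNG seed.
#' @param h [hemodynamic_params] (carries tr and burn_in_s).
#' @param init_S initial gating value.
#' @return T' x N matrix of BOLD at TR.
#' @export
simulate_bold_tr <- function(sc, global, regional, duration_s, seed,
                             h = hemodynamic_params(), init_S = 0.1) {
  N <- nrow(sc$weights)
  n_steps <- as.integer(round(duration_s / global$dt))
  burn <- as.integer(round(h$burn_in_s / global$dt))
  keep <- h$tr / global$dt
  if (abs(keep - round(keep)) > 1e-9) {
    stop("tr must be an integer multiple of dt", call. = FALSE)
  }
  set.seed(seed)
  cpp_simulate_bold_tr(sc$weights, regional$w, regional$I, global$G,
                       global$sigma, global$J, global$a, global$b, global$d,
                       global$tau_s, global$r_kin, global$dt, n_steps,
                       rep_len(init_S, N), burn, as.integer(round(keep)),
                       h$kappa, h$gamma_f, h$tau_v, h$alpha, h$rho, h$V0,
                       h$k1, h$k2, h$k3, h$stride)
}

#' Generate subject x region feature tables with planted effects
#'
#' Controls are Normal(0, 1) per region; patient groups add network-targeted
#' shifts expressed in control-SD units. Age and sex covariates are drawn
#' with the same seed discipline and a shared age slope can be added so
#' covariate adjustment matters.
#'
#' @param parc [parcellation].
#' @param effects named list: for each patient group, a named numeric of
#'   per-network shifts in SD units.
#' @param n_per_group named integer vector (names = group labels, must
#'   include "HC").
#' @param seed RNG seed.
#' @param age_slope common linear age effect (SD units per year).
#' @param side_fraction named numeric: fraction of each patient group
#'   labelled right-sided.
#' @return A [feature_table].
#' @export
generate_feature_tables <- function(parc, effects = list(),
                                    n_per_group = c(HC = 20, GE = 20,
                                                    TLE = 20),
                                    seed = 1, age_slope = 0,
                                    side_fraction = c(TLE = 0.5)) {
  stopifnot("HC" %in% names(n_per_group))
  set.seed(seed)
  n_regions <- nrow(parc)
  groups <- rep(names(n_per_group), n_per_group)
  n_sub <- length(groups)
  age <- round(stats::runif(n_sub, 18, 60), 1)
  sex <- stats::rbinom(n_sub, 1, 0.5)
  side <- rep("none", n_sub)
  for (g in names(side_fraction)) {
    idx <- which(groups == g)
    n_right <- round(side_fraction[[g]] * length(idx))
    if (n_right > 0) side[idx[seq_len(n_right)]] <- "right"
    side[idx[-seq_len(max(n_right, 0))]] <- "left"
    if (n_right == 0) side[idx] <- "left"
  }
  values <- matrix(stats::rnorm(n_sub * n_regions), n_sub, n_regions)
  values <- values + age_slope * (age - mean(age))
  for (g in names(effects)) {
    shift <- effects[[g]]
    delta <- shift[parc$network]
    delta[is.na(delta)] <- 0
    values[groups == g, ] <- sweep(values[groups == g, , drop = FALSE], 2,
                                   unname(delta), `+`)
  }
  covars <- data.frame(subject_id = sprintf("sub%03d", seq_len(n_sub)),
                       group = groups, age = age, sex = sex, side = side,
                       stringsAsFactors = FALSE)
  feature_table(values, covars, parc)
}

#' The standard synthetic study
#'
#' Builds the package's reference fixture in one call: a 40-region,
#' 4-network modular connectome, ground-truth regional parameters for the
#' HC / GE / TLE cohorts, and the three group-average functional
#' connectomes simulated at the study's generating conditions. All stage
#' seeds are derived from `seed` by fixed offsets.
#'
#' @param seed base seed.
#' @param n_subjects subjects per cohort.
#' @param n_regions,n_networks connectome geometry.
#' @return list(sc, parcellation, global, truths, group_fc, subject_fc).
#' @export
standard_study <- function(seed = 1, n_subjects = 20, n_regions = 40,
                           n_networks = 4) {
  syn <- make_synthetic_sc(n_regions = n_regions, n_networks = n_networks,
                           seed = seed)
  specs <- default_cohorts(n_subjects = n_subjects)
  global <- standard_global_params()
  truths <- lapply(specs, function(sp) {
    make_ground_truth(syn$parcellation, sp, seed = seed + 10)
  })
  subject_fc <- group_fc <- list()
  for (k in seq_along(specs)) {
    grp <- names(specs)[k]
    subject_fc[[grp]] <- generate_cohort_fc(
      syn$sc, global, truths[[grp]], n_subjects = n_subjects,
      subject_noise_sd = specs[[grp]]$subject_noise_sd,
      seed = seed + 100 * k)
    group_fc[[grp]] <- group_average_fc(subject_fc[[grp]])
  }
  list(sc = syn$sc, parcellation = syn$parcellation, global = global,
       truths = truths, group_fc = group_fc, subject_fc = subject_fc)
}

#' Generating global parameters of the standard study
#'
#' The study simulates cohorts in the stable noise-driven regime below the
#' network's saturation bifurcation, with the coupling and noise level
#' calibrated once against the study's design targets.
#'
#' @return [mfm_global_params].
#' @export
standard_global_params <- function() {
  mfm_global_params(G = 0.115, sigma = 0.05, dt = 0.002)
}

#' Standard inversion protocol for the 40-region fixture
#'
#' @param base_seed seed anchoring the fit's common random numbers.
#' @return [fit_config].
#' @export
standard_fit_config <- function(base_seed = 42) {
  fit_config(n_outer_iterations = 10, n_random_inits = 2,
             sim_duration_s = 500, jac_duration_s = 100,
             noise_realizations = 3, dt = 0.002, max_tries = 8,
             fd_steps = list(G = 0.01, sigma = 0.004, w = 0.05, I = 0.002),
             base_seed = base_seed)
}
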