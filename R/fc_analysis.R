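# Functional-connectivity utilities: Pearson FC from time series, Fisher
# r-to-z averaging across subjects, structure-function similarity measures,
# and seed-based connectivity with optional global-signal regression.

#' Pearson functional connectivity from a time-series matrix
#'
#' @param ts T x N matrix (or `bold_series`) of regional time series, T >= 3.
#' @param parc matching [parcellation].
#' @return `functional_connectome` in r-space with unit diagonal.
#' @export
compute_fc <- function(ts, parc) {
  if (inherits(ts, "bold_series")) ts <- ts$y
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series in region(s) ",
         paste(which(sds == 0) - 1L, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  functional_connectome(r, parc, space = "r")
}

#' Fisher r-to-z transform
#'
#' z = atanh(r) with r clipped to +/-(1 - 1e-7) first, so degenerate perfect
#' correlations map to a large finite value instead of infinity.
#'
#' @param r correlations, |r| <= 1.
#' @return z values; invert with [fisher_z_inv()].
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("|r| > 1 passed to fisher_z", call. = FALSE)
  }
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Inverse Fisher transform
#' @param z Fisher-z values.
#' @return correlations tanh(z).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Group-average functional connectome
#'
#' Averages subject FC matrices in Fisher-z space and back-transforms to
#' r-space; the diagonal is reset to 1.
#'
#' @param fcs list of `functional_connectome` objects in r-space sharing one
#'   parcellation.
#' @return Group-level `functional_connectome` in r-space.
#' @export
group_average_fc <- function(fcs) {
  stopifnot(length(fcs) >= 1)
  parc <- fcs[[1]]$parcellation
  for (fc in fcs) {
    if (!inherits(fc, "functional_connectome") || fc$space != "r") {
      stop("all inputs must be r-space functional connectomes", call. = FALSE)
    }
    if (!identical(dim(fc$values), dim(fcs[[1]]$values)) ||
        !identical(fc$parcellation$network, parc$network)) {
      stop("mixed parcellations in group_average_fc", call. = FALSE)
    }
  }
  zsum <- Reduce(`+`, lapply(fcs, function(fc) fisher_z(fc$values)))
  r <- fisher_z_inv(zsum / length(fcs))
  diag(r) <- 1
  functional_connectome(r, parc, space = "r")
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' Similarity between simulated and empirical FC
#'
#' Pearson correlation over the strictly-upper-triangle entries (diagonal
#' excluded); the objective maximised by the model inversion.
#'
#' @param sim,emp `functional_connectome` objects on one parcellation, N >= 3.
#' @return Pearson r (scalar).
#' @export
fc_similarity <- function(sim, emp) {
  a <- upper_tri_vec(sim$values); b <- upper_tri_vec(emp$values)
  if (length(a) != length(b)) stop("parcellation mismatch", call. = FALSE)
  if (nrow(sim$values) < 3) stop("need N >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in upper triangle", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Baseline structure-function correlation
#'
#' Pearson correlation between upper-triangle structural weights and
#' functional connectivity values: the reference a fitted model's similarity
#' is expected to exceed.
#'
#' @param sc `structural_connectome`. @param emp `functional_connectome`.
#' @return Pearson r (scalar).
#' @export
sc_fc_baseline <- function(sc, emp) {
  a <- upper_tri_vec(sc$weights); b <- upper_tri_vec(emp$values)
  if (length(a) != length(b)) stop("parcellation mismatch", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in upper triangle", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Seed-based connectivity profile
#'
#' Correlates a seed time series (e.g. a thalamic mask average) with every
#' parcel series and returns the Fisher-z profile. With `gsr = TRUE` the
#' mean-across-parcels signal is regressed out of the seed and every parcel
#' series (OLS residuals, intercept included) before correlating.
#'
#' @param seed_ts length-T seed series.
#' @param parcel_ts T x N matrix of parcel series.
#' @param gsr apply global-signal regression first?
#' @param seed_label label stored with the profile.
#' @return `seed_profile`: list(z, seed_label, gsr).
#' @export
seed_fc <- function(seed_ts, parcel_ts, gsr = FALSE, seed_label = "seed") {
  parcel_ts <- as.matrix(parcel_ts)
  seed_ts <- as.numeric(seed_ts)
  if (length(seed_ts) != nrow(parcel_ts)) stop("length mismatch",
                                               call. = FALSE)
  if (length(seed_ts) < 3) stop("need at least 3 time points", call. = FALSE)
  if (stats::sd(seed_ts) == 0) stop("constant seed series", call. = FALSE)
  if (any(apply(parcel_ts, 2, stats::sd) == 0)) {
    stop("constant parcel series", call. = FALSE)
  }
  if (gsr) {
    g <- rowMeans(parcel_ts)
    resid_on <- function(y) stats::lsfit(g, y)$residuals
    seed_ts <- resid_on(seed_ts)
    parcel_ts <- apply(parcel_ts, 2, resid_on)
  }
  r <- as.numeric(stats::cor(seed_ts, parcel_ts))
  structure(list(z = fisher_z(r), seed_label = seed_label, gsr = gsr),
            class = "seed_profile")
}
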