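# Parcel-level group statistics: hemisphere pooling by homologue flipping,
# z-scoring against controls, covariate-adjusted GLM contrasts with
# max-statistic permutation FWE control, Mahalanobis / Hotelling T2
# multivariate tests, and network-SD-normalised parameter contrasts.

#' Subject x region feature table
#'
#' One imaging-derived modality (thickness-like, FA-like, MD-like, seed-z,
#' ...) for all subjects, with per-subject covariates.
#'
#' @param values n_subjects x N numeric matrix, no missing cells.
#' @param covariates data.frame with one row per subject: `subject_id`,
#'   `group` (HC/GE/TLE), `age`, `sex` (0/1), `side`
#'   (left/right/none), and any optional clinical columns
#'   (`drug_response`, `onset`, `duration`, `hippocampal_volume`).
#' @param parc matching [parcellation].
#' @return `feature_table` object.
#' @export
feature_table <- function(values, covariates, parc) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells in feature table", call. = FALSE)
  if (ncol(values) != nrow(parc)) {
    stop("value columns must match parcellation size", call. = FALSE)
  }
  if (nrow(values) != nrow(covariates)) {
    stop("one covariate row per subject required", call. = FALSE)
  }
  need <- c("subject_id", "group", "age", "sex", "side")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariates missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(covariates$group %in% c("HC", "GE", "TLE"))) {
    stop("group labels must be HC, GE, or TLE", call. = FALSE)
  }
  structure(list(values = values, covariates = covariates,
                 parcellation = parc),
            class = "feature_table")
}

#' Pool lesion sides by flipping right-sided patients onto the left
#'
#' For each subject labelled `side = "right"`, every region's value is
#' swapped with its contralateral homologue's, so lesions line up on the
#' left hemisphere across the cohort. Subjects with side "left" or "none"
#' are untouched. Applying the operation twice is the identity.
#'
#' @param ft a [feature_table] whose parcellation has complete homologue
#'   pairing.
#' @return Flipped [feature_table].
#' @export
flip_to_ipsilateral <- function(ft) {
  parc <- ft$parcellation
  hom <- parc$homologue_id
  if (anyNA(hom)) stop("parcellation has regions without homologues",
                       call. = FALSE)
  perm <- match(hom, parc$region_id)
  values <- ft$values
  flip <- which(ft$covariates$side == "right")
  values[flip, ] <- values[flip, perm, drop = FALSE]
  feature_table(values, ft$covariates, parc)
}

#' Z-score features against the control group
#'
#' Per region, z = (x - mean_HC) / SD_HC (sample SD, divisor n-1), applied
#' to every subject including the controls themselves.
#'
#' @param ft a [feature_table].
#' @param control_group label of the reference group (default "HC").
#' @return Z-scored [feature_table].
#' @export
zscore_vs_controls <- function(ft, control_group = "HC") {
  ctl <- ft$values[ft$covariates$group == control_group, , drop = FALSE]
  if (nrow(ctl) < 3) stop("need at least 3 controls", call. = FALSE)
  mu <- colMeans(ctl)
  sdv <- apply(ctl, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero control SD in region(s) ",
         paste(which(sdv == 0) - 1L, collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(ft$values, 2, mu), 2, sdv, `/`)
  feature_table(z, ft$covariates, ft$parcellation)
}

# Build the design matrix [intercept | covariate terms | group indicator]
# for a two-group contrast; the group column is 1 for contrast[1].
build_design <- function(ft, terms, contrast) {
  cov <- ft$covariates
  keep <- cov$group %in% contrast
  cov <- cov[keep, , drop = FALSE]
  Y <- ft$values[keep, , drop = FALSE]
  X <- cbind(intercept = rep(1, nrow(cov)))
  for (tm in terms) {
    if (!tm %in% names(cov)) stop("unknown covariate term: ", tm,
                                  call. = FALSE)
    X <- cbind(X, as.numeric(cov[[tm]]))
    colnames(X)[ncol(X)] <- tm
  }
  X <- cbind(X, group = as.numeric(cov$group == contrast[1]))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; collinear terms among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  list(X = X, Y = Y)
}

#' Covariate-adjusted group contrast per region
#'
#' Ordinary least squares of each region's values on an intercept, the named
#' covariate terms, and a two-level group indicator (coded 1 for the first
#' group of `contrast`, so t > 0 means that group is higher). Two-sided p
#' from the t distribution with residual degrees of freedom. With no
#' covariates this reduces exactly to the pooled-variance two-sample t test.
#'
#' @param ft a [feature_table].
#' @param terms character vector of covariate column names (may be empty).
#' @param contrast length-2 character vector of group labels, e.g.
#'   c("TLE", "GE").
#' @return `contrast_result`: data.frame with region_id, t, p_uncorrected,
#'   plus attributes `df` and `model_terms`.
#' @export
glm_contrast <- function(ft, terms = c("sex", "age"),
                         contrast = c("TLE", "GE")) {
  d <- build_design(ft, terms, contrast)
  X <- d$X; Y <- d$Y
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[p, p])
  tstat <- coefs[p, ] / se
  out <- data.frame(region_id = ft$parcellation$region_id, t = tstat,
                    p_uncorrected = 2 * stats::pt(-abs(tstat), df))
  rownames(out) <- NULL
  attr(out, "df") <- df
  attr(out, "model_terms") <- colnames(X)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Permutation-based family-wise error control for a group contrast
#'
#' Freedman-Lane-style max-statistic permutation: the group indicator and
#' the data are residualised on the nuisance covariates, the residualised
#' indicator is permuted, and the maximum |t| across regions forms the null
#' distribution. p_fwe_i = (1 + #\{perm max >= |t_i|\}) / (n_perm + 1),
#' floored at the parametric uncorrected p so corrected values never fall
#' below uncorrected ones.
#'
#' @param ft a [feature_table].
#' @param terms nuisance covariate names.
#' @param contrast length-2 group pair.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return `contrast_result` data.frame with region_id, t, p_uncorrected,
#'   p_fwe.
#' @export
permutation_fwe <- function(ft, terms = c("sex", "age"),
                            contrast = c("TLE", "GE"), n_perm = 1000,
                            seed = 7) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- glm_contrast(ft, terms, contrast)
  d <- build_design(ft, terms, contrast)
  X <- d$X; Y <- d$Y
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  Z <- X[, -p, drop = FALSE]
  g <- X[, p]
  qz <- qr(Z)
  g_res <- qr.resid(qz, g)
  Y_res <- qr.resid(qz, Y)
  yy <- colSums(Y_res^2)
  gg <- sum(g_res^2)
  set.seed(seed)
  Gp <- vapply(seq_len(n_perm), function(k) g_res[sample.int(n)],
               numeric(n))
  Gy <- crossprod(Gp, Y_res)                      # n_perm x N
  rss <- sweep(-Gy^2 / gg, 2, yy, `+`)
  tperm <- (Gy / sqrt(gg)) / sqrt(rss / df)
  max_t <- apply(abs(tperm), 1, max)
  p_fwe <- vapply(abs(obs$t),
                  function(ti) (1 + sum(max_t >= ti)) / (n_perm + 1),
                  numeric(1))
  obs$p_fwe <- pmax(p_fwe, obs$p_uncorrected)
  obs
}

#' Mahalanobis distance of a subject from the control distribution
#'
#' sqrt((x - mu)' Sigma^{-1} (x - mu)) with mean and covariance estimated
#' from the control matrix. A singular covariance errors unless
#' `pseudo_inverse = TRUE`, in which case the Moore-Penrose inverse is used
#' and the result is flagged.
#'
#' @param x length-M feature vector for one subject.
#' @param controls n_HC x M control matrix, n_HC > M.
#' @param pseudo_inverse fall back to a pseudo-inverse if Sigma is singular?
#' @return Distance (scalar); attribute `pseudo` marks pseudo-inverse use.
#' @export
mahalanobis_d <- function(x, controls, pseudo_inverse = FALSE) {
  controls <- as.matrix(controls)
  M <- ncol(controls)
  if (nrow(controls) <= M) stop("need more controls than features",
                                call. = FALSE)
  mu <- colMeans(controls)
  Sigma <- stats::cov(controls)
  inv <- tryCatch(solve(Sigma), error = function(e) NULL)
  pseudo <- FALSE
  if (is.null(inv)) {
    if (!pseudo_inverse) stop("singular control covariance", call. = FALSE)
    inv <- MASS::ginv(Sigma)
    pseudo <- TRUE
  }
  dvec <- x - mu
  structure(sqrt(drop(t(dvec) %*% inv %*% dvec)), pseudo = pseudo)
}

#' Two-sample Hotelling's T-squared test
#'
#' T2 = (n_a n_b)/(n_a + n_b) (xbar_a - xbar_b)' S_pooled^{-1}
#' (xbar_a - xbar_b), converted to F = T2 (n_a + n_b - M - 1) /
#' (M (n_a + n_b - 2)) with p from F(M, n_a + n_b - M - 1). At M = 1 this is
#' the square of the two-sample pooled-variance t statistic.
#'
#' @param group_a n_a x M matrix. @param group_b n_b x M matrix.
#' @return list(T2, F, p, df1, df2).
#' @export
hotelling_t2 <- function(group_a, group_b) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  M <- ncol(A)
  if (ncol(B) != M) stop("feature-count mismatch", call. = FALSE)
  na <- nrow(A); nb <- nrow(B)
  if (na + nb - 2 <= M) stop("too few subjects for M features",
                             call. = FALSE)
  Sp <- ((na - 1) * stats::cov(A) + (nb - 1) * stats::cov(B)) / (na + nb - 2)
  inv <- tryCatch(solve(Sp), error = function(e) {
    stop("singular pooled covariance", call. = FALSE)
  })
  dbar <- colMeans(A) - colMeans(B)
  T2 <- (na * nb) / (na + nb) * drop(t(dbar) %*% inv %*% dbar)
  Fstat <- T2 * (na + nb - M - 1) / (M * (na + nb - 2))
  df1 <- M; df2 <- na + nb - M - 1
  list(T2 = T2, F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Network-SD-normalised regional parameter contrast
#'
#' For cohort-level fitted parameters, the between-group difference for
#' region i is divided by the SD (sample, n-1) of the differences across the
#' regions of i's intrinsic network: Delta_i = (pa_i - pb_i) /
#' SD(\{pa_j - pb_j : network(j) = network(i)\}).
#'
#' @param pa,pb length-N regional parameter vectors (group A and B).
#' @param networks length-N network labels; every network needs >= 2
#'   regions.
#' @return length-N normalised differences; networks whose differences have
#'   zero SD yield 0 when all differences are 0 (flagged via the
#'   `degenerate_networks` attribute) and NaN otherwise.
#' @export
parameter_contrast <- function(pa, pb, networks) {
  if (length(pa) != length(pb) || length(pa) != length(networks)) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(table(networks) < 2)) {
    stop("every network needs at least 2 regions", call. = FALSE)
  }
  d <- pa - pb
  out <- numeric(length(d))
  degen <- character(0)
  for (nw in unique(networks)) {
    idx <- networks == nw
    s <- stats::sd(d[idx])
    if (s == 0) {
      degen <- c(degen, nw)
      out[idx] <- if (all(d[idx] == 0)) 0 else NaN
    } else {
      out[idx] <- d[idx] / s
    }
  }
  structure(out, degenerate_networks = degen)
}
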