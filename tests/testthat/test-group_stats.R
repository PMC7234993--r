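make_ft <- function(n_hc = 10, n_tle = 10, n_regions = 4, seed = 1,
                    tle_shift = 0, sides = NULL) {
  set.seed(seed)
  n <- n_hc + n_tle
  vals <- matrix(rnorm(n * n_regions), n, n_regions)
  vals[(n_hc + 1):n, ] <- vals[(n_hc + 1):n, ] + tle_shift
  grp <- c(rep("HC", n_hc), rep("TLE", n_tle))
  if (is.null(sides)) sides <- ifelse(grp == "HC", "none", "left")
  covars <- data.frame(subject_id = sprintf("s%02d", 1:n), group = grp,
                       age = round(runif(n, 20, 60)), sex = rbinom(n, 1, 0.5),
                       side = sides, stringsAsFactors = FALSE)
  feature_table(vals, covars, toy_parcellation(n_regions))
}

test_that("hemisphere flipping swaps homologues and is an involution", {
  ft <- make_ft(n_hc = 2, n_tle = 2, sides = c("none", "none", "right",
                                               "left"))
  flipped <- flip_to_ipsilateral(ft)
  # pairing in toy_parcellation(4) is (0<->2, 1<->3)
  expect_equal(flipped$values[3, ], ft$values[3, c(3, 4, 1, 2)])
  expect_equal(flipped$values[c(1, 2, 4), ], ft$values[c(1, 2, 4), ])
  # per-subject value multisets survive
  expect_equal(sort(flipped$values[3, ]), sort(ft$values[3, ]))
  twice <- flip_to_ipsilateral(flipped)
  expect_equal(twice$values, ft$values)

  bad_parc <- toy_parcellation2(4)
  ftb <- feature_table(ft$values, ft$covariates, bad_parc)
  expect_error(flip_to_ipsilateral(ftb), "homologue")
})

test_that("z-scoring against controls gives controls mean 0 / SD 1", {
  ft <- make_ft(n_hc = 8, n_tle = 5, seed = 3)
  z <- zscore_vs_controls(ft)
  hc <- z$values[z$covariates$group == "HC", ]
  expect_equal(colMeans(hc), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(hc, 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a patient sitting exactly at the control mean scores zero everywhere
  ft2 <- ft
  ft2$values[13, ] <- colMeans(ft$values[1:8, ])
  z2 <- zscore_vs_controls(ft2)
  expect_equal(z2$values[13, ], rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  # hand-computed 3-control fixture
  vals <- rbind(c(1, 2), c(3, 4), c(5, 9), c(7, 1))
  cov3 <- data.frame(subject_id = paste0("s", 1:4),
                     group = c("HC", "HC", "HC", "TLE"),
                     age = c(30, 40, 50, 35), sex = c(0, 1, 0, 1),
                     side = c("none", "none", "none", "left"))
  ft3 <- feature_table(vals, cov3, toy_parcellation(2))
  z3 <- zscore_vs_controls(ft3)
  expect_equal(z3$values[4, 1], (7 - 3) / 2)
  expect_equal(z3$values[4, 2], (1 - 5) / sqrt(13))
})

test_that("glm_contrast reduces to the pooled two-sample t without terms", {
  for (seed in 1:5) {
    ft <- make_ft(seed = seed, tle_shift = 0.5)
    res <- glm_contrast(ft, terms = character(0), contrast = c("TLE", "HC"))
    for (j in 1:4) {
      tt <- t.test(ft$values[ft$covariates$group == "TLE", j],
                   ft$values[ft$covariates$group == "HC", j],
                   var.equal = TRUE)
      expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p_uncorrected[j], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("glm_contrast with covariates matches a normal-equations oracle", {
  ft <- make_ft(n_hc = 6, n_tle = 6, seed = 11)
  res <- glm_contrast(ft, terms = c("sex", "age"), contrast = c("TLE", "HC"))
  cov <- ft$covariates
  for (j in 1:4) {
    X <- cbind(1, cov$sex, cov$age, as.numeric(cov$group == "TLE"))
    y <- ft$values[, j]
    beta <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (nrow(X) - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[4, 4])
    expect_equal(res$t[j], drop(beta[4] / se), tolerance = 1e-10)
  }
  expect_equal(attr(res, "df"), 12 - 4)
})

test_that("confounded designs raise a rank error", {
  ft <- make_ft(n_hc = 6, n_tle = 6, seed = 2)
  ft$covariates$sex <- as.numeric(ft$covariates$group == "TLE")
  expect_error(glm_contrast(ft, terms = "sex", contrast = c("TLE", "HC")),
               "rank")
})

test_that("permutation p_fwe dominates uncorrected p and flags effects", {
  ft <- make_ft(n_hc = 20, n_tle = 20, seed = 5, tle_shift = 0)
  ft$values[ft$covariates$group == "TLE", 2] <-
    ft$values[ft$covariates$group == "TLE", 2] + 2
  res <- permutation_fwe(ft, terms = c("sex", "age"),
                         contrast = c("TLE", "HC"), n_perm = 500, seed = 3)
  expect_true(all(res$p_fwe >= res$p_uncorrected))
  expect_true(all(res$p_fwe >= 0 & res$p_fwe <= 1))
  expect_lt(res$p_fwe[2], 0.05)
  expect_error(permutation_fwe(ft, n_perm = 50), ">= 100")
  # determinism
  res2 <- permutation_fwe(ft, terms = c("sex", "age"),
                          contrast = c("TLE", "HC"), n_perm = 500, seed = 3)
  expect_identical(res$p_fwe, res2$p_fwe)
})

test_that("mahalanobis distance matches closed forms", {
  set.seed(9)
  ctl <- matrix(rnorm(60), 30, 2)
  mu <- colMeans(ctl)
  expect_equal(as.numeric(mahalanobis_d(mu, ctl)), 0)

  # identity-covariance fixture: equals Euclidean distance
  n <- 500
  set.seed(10)
  z <- matrix(rnorm(2 * n), n, 2)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(cov(z)))   # exact identity sample covariance
  x <- c(1.3, -0.7)
  expect_equal(as.numeric(mahalanobis_d(x, z)),
               sqrt(sum((x - colMeans(z))^2)), tolerance = 1e-12)

  # correlated 2x2 fixture vs explicit inverse oracle
  S <- cov(ctl); d <- c(2, 1) - mu
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) /
    (S[1, 1] * S[2, 2] - S[1, 2]^2)
  expect_equal(as.numeric(mahalanobis_d(c(2, 1), ctl)),
               sqrt(drop(t(d) %*% inv %*% d)), tolerance = 1e-12)

  expect_error(mahalanobis_d(c(1, 1), ctl[1:2, ]), "more controls")
  sing <- cbind(ctl[, 1], ctl[, 1])
  expect_error(mahalanobis_d(c(1, 1), sing), "singular")
  expect_true(is.finite(mahalanobis_d(c(1, 1), sing, pseudo_inverse = TRUE)))
})

test_that("hotelling T2 equals t^2 at M = 1 and vanishes for equal groups", {
  set.seed(12)
  a <- matrix(rnorm(15), 15, 1); b <- matrix(rnorm(12) + 0.8, 12, 1)
  ht <- hotelling_t2(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(ht$T2, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht$p, tt$p.value, tolerance = 1e-10)

  g <- matrix(rnorm(40), 20, 2)
  same <- hotelling_t2(g, g)
  expect_equal(same$T2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(hotelling_t2(g[1:2, ], g[1:2, ]), "too few")
})

test_that("parameter contrast normalises by within-network SD", {
  nets <- c("limbic", "limbic", "somatomotor", "somatomotor")
  pa <- c(1, 3, 2, 2); pb <- c(0, 0, 1, 1)
  d <- parameter_contrast(pa, pb, nets)
  # limbic differences (1, 3): sample SD sqrt(2)
  expect_equal(d[1:2], c(1, 3) / sqrt(2), ignore_attr = TRUE)
  # somatomotor differences are equal -> zero SD, nonzero -> NaN flagged
  expect_true(all(is.nan(d[3:4])))
  expect_true("somatomotor" %in% attr(d, "degenerate_networks"))

  # identical groups: all zeros, flagged but defined as 0
  z <- parameter_contrast(pa, pa, nets)
  expect_equal(as.numeric(z), rep(0, 4))

  # invariances: common scaling and common additive offset
  expect_equal(as.numeric(parameter_contrast(10 * pa, 10 * pb, nets)[1:2]),
               as.numeric(d[1:2]))
  expect_equal(as.numeric(parameter_contrast(pa + 5, pb + 5, nets)[1:2]),
               as.numeric(d[1:2]))
  expect_error(parameter_contrast(c(1, 2, 3), c(0, 0, 0),
                                  c("a", "a", "b")),
               "at least 2")
})
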