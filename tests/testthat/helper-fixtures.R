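# Small fixtures shared across test files; everything is built in code.

toy_parcellation <- function(n = 4) {
  half <- n / 2
  parcellation(
    region_id = 0:(n - 1),
    name = paste0("p", 0:(n - 1)),
    hemisphere = rep(c("left", "right"), each = half),
    network = rep_len(c("limbic", "somatomotor"), n),
    homologue_id = c(half:(n - 1), 0:(half - 1))
  )
}

# deterministic small symmetric SC with zero diagonal
toy_sc <- function(n = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structural_connectome(m, toy_parcellation2(n))
}

# random valid correlation matrix from seeded time series
toy_fc <- function(n = 5, seed = 1, t_len = 50) {
  set.seed(seed)
  ts <- matrix(rnorm(t_len * n), t_len, n)
  compute_fc(ts, toy_parcellation2(n))
}

# parcellation without homologue pairing, arbitrary n
toy_parcellation2 <- function(n) {
  parcellation(
    region_id = 0:(n - 1),
    name = paste0("p", 0:(n - 1)),
    hemisphere = rep_len(c("left", "right"), n),
    network = rep_len(c("limbic", "somatomotor", "default"), n),
    homologue_id = NA
  )
}
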