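# shared fixtures: all generated in code, nothing on disk

small_regions <- function() region_table(48)

small_spec <- function(seed = 1, n = 40, ...) {
  cohort_spec(n_subjects = n, regions = small_regions(), seed = seed, ...)
}

noiseless_noise <- function() {
  list(modality_frac = 0, lesion_sd = 0, extent_sd = 0,
       outside_rate = 0, i3m_blur = 0)
}

# deterministic small regression problem
toy_xy <- function(n = 12, p = 5, k = 2, seed = 99, noise = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  B <- matrix(rnorm(p * k), p, k)
  Y <- X %*% B + noise * matrix(rnorm(n * k), n, k)
  colnames(Y) <- paste0("y", 1:k)
  list(X = X, Y = Y, B = B)
}

# independent direct evaluation of the Wold VIP formula from W and SSY
vip_oracle <- function(model, a) {
  W <- model$W[, 1:a, drop = FALSE]
  ssy <- model$ssy[1:a]
  p <- nrow(W)
  sapply(seq_len(p), function(j) {
    num <- sum(ssy * (W[j, ]^2 / colSums(W^2)))
    sqrt(p * num / sum(ssy))
  })
}
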