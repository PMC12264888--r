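#' Generate calibrated WAB-R subtest scores
#'
#' Draws subtest scores from a clipped (censored) Gaussian copula whose
#' latent parameters are calibrated so that the *post-clipping* sample
#' means, SDs and pairwise Pearson correlations match the cohort targets
#' in expectation. Clipping to `[0, max]` reproduces the ceiling/floor
#' effects of bounded clinical scales (auditory comprehension reaches its
#' 10-point ceiling), and the calibration pre-compensates the moment
#' bias that clipping introduces:
#'
#' * per margin, the latent mean/SD are solved by fixed-point iteration
#'   against the closed-form moments of the doubly censored normal;
#' * per pair, the latent correlation is solved with [stats::uniroot()]
#'   against the post-clipping correlation evaluated by two-dimensional
#'   Gauss-Hermite quadrature;
#' * the assembled latent correlation matrix is repaired to the nearest
#'   positive-definite matrix ([Matrix::nearPD()]) if needed; a target
#'   that cannot be repaired is an error reporting the eigenvalues.
#'
#' A single latent severity factor (the first principal component of the
#' latent correlation, sign-flipped so that higher severity means lower
#' scores) is returned alongside the scores; the lesion generator uses it
#' to couple anatomical damage to overall impairment.
#'
#' @param spec a [cohort_spec()].
#' @param n number of subjects (defaults to `spec$n_subjects`).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return object of class `behaviour_matrix`: list with `scores`
#'   (n x 4 matrix, subject rownames), `max_scores`, and `severity`
#'   (standardized latent severity, higher = more impaired).
#' @export
generate_behaviour <- function(spec, n = spec$n_subjects, seed = spec$seed) {
  cal <- calibrate_behaviour(spec)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(spec$subtest_targets)
  Z <- matrix(rnorm(n * k), n, k) %*% chol(cal$R_latent)
  scores <- vapply(seq_len(k), function(j)
    clamp(cal$mu[j] + cal$sigma[j] * Z[, j], 0, spec$subtest_targets$max[j]),
    numeric(n))
  colnames(scores) <- spec$subtest_targets$subtest
  rownames(scores) <- sprintf("sub-%03d", seq_len(n))
  ev <- eigen(cal$R_latent, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1                 # loadings positive on scores
  severity <- as.numeric(-(Z %*% v1) / sqrt(ev$values[1]))
  structure(list(scores = scores,
                 max_scores = setNames(spec$subtest_targets$max,
                                       spec$subtest_targets$subtest),
                 severity = severity,
                 calibration = cal),
            class = "behaviour_matrix")
}

#' @export
print.behaviour_matrix <- function(x, ...) {
  cat(sprintf("<behaviour_matrix> %d subjects x %d subtests\n",
              nrow(x$scores), ncol(x$scores)))
  print(round(rbind(mean = colMeans(x$scores), sd = apply(x$scores, 2, sd)), 2))
  invisible(x)
}

# Mean and SD of clamp(N(mu, sigma^2), 0, M): closed-form censored moments.
censored_moments <- function(mu, sigma, upper) {
  a <- (0 - mu) / sigma; b <- (upper - mu) / sigma
  Fa <- pnorm(a); Fb <- pnorm(b); fa <- dnorm(a); fb <- dnorm(b)
  ez_mid  <- fa - fb                       # E[z; a < z < b]
  ez2_mid <- (Fb - Fa) + a * fa - b * fb   # E[z^2; a < z < b]
  m1 <- upper * (1 - Fb) + mu * (Fb - Fa) + sigma * ez_mid
  m2 <- upper^2 * (1 - Fb) + mu^2 * (Fb - Fa) +
    2 * mu * sigma * ez_mid + sigma^2 * ez2_mid
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Latent (mu, sigma) whose censored moments hit the targets.
calibrate_margin <- function(target_mean, target_sd, upper,
                             tol = 1e-3, max_iter = 25) {
  mu <- target_mean; sigma <- target_sd
  for (i in seq_len(max_iter)) {
    mm <- censored_moments(mu, sigma, upper)
    if (abs(mm[1] - target_mean) < tol && abs(mm[2] - target_sd) < tol) break
    mu <- mu + (target_mean - mm[1])
    sigma <- sigma * target_sd / mm[2]
  }
  c(mu = unname(mu), sigma = unname(sigma))
}

# Post-clipping correlation of a censored bivariate normal with latent
# correlation rho, by tensorized Gauss-Hermite quadrature.
censored_corr <- function(rho, p1, p2, gh) {
  z1 <- sqrt(2) * gh$x; w <- gh$w / sqrt(pi)
  g1 <- clamp(p1[1] + p1[2] * z1, 0, p1[3])
  s <- sqrt(max(1 - rho^2, 0))
  exy <- 0
  for (i in seq_along(z1)) {
    z2 <- rho * z1[i] + s * sqrt(2) * gh$x
    exy <- exy + w[i] * g1[i] * sum(w * clamp(p2[1] + p2[2] * z2, 0, p2[3]))
  }
  m1 <- censored_moments(p1[1], p1[2], p1[3])
  m2 <- censored_moments(p2[1], p2[2], p2[3])
  (exy - m1[1] * m2[1]) / (m1[2] * m2[2])
}

#' Calibrate the latent copula parameters for a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @param gh_nodes number of Gauss-Hermite nodes per axis (default 80).
#' @return list with latent `mu`, `sigma`, `R_latent` (positive-definite
#'   latent correlation) and `repaired` flag.
#' @export
calibrate_behaviour <- function(spec, gh_nodes = 80) {
  tg <- spec$subtest_targets
  k <- nrow(tg)
  marg <- t(vapply(seq_len(k), function(j)
    calibrate_margin(tg$mean[j], tg$sd[j], tg$max[j]), numeric(2)))
  gh <- pracma::gaussHermite(gh_nodes)
  Rt <- spec$subtest_correlations
  Rl <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    target <- Rt[i, j]
    if (abs(target) < 1e-12) { Rl[i, j] <- Rl[j, i] <- 0; next }
    p1 <- c(marg[i, ], tg$max[i]); p2 <- c(marg[j, ], tg$max[j])
    f <- function(r) censored_corr(r, p1, p2, gh) - target
    lo <- max(-0.999, target - 0.2); hi <- min(0.999, target + 0.2)
    while (f(lo) > 0 && lo > -0.999) lo <- max(-0.999, lo - 0.2)
    while (f(hi) < 0 && hi < 0.999) hi <- min(0.999, hi + 0.2)
    r <- if (f(lo) > 0 || f(hi) < 0) target else uniroot(f, c(lo, hi), tol = 1e-5)$root
    Rl[i, j] <- Rl[j, i] <- r
  }
  repaired <- FALSE
  ev <- eigen(Rl, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    Rl <- as.matrix(Matrix::nearPD(Rl, corr = TRUE)$mat)
    repaired <- TRUE
    ev <- eigen(Rl, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stopf("correlation target not repairable to positive definite; eigenvalues: %s",
            paste(signif(ev, 4), collapse = ", "))
  }
  dimnames(Rl) <- list(tg$subtest, tg$subtest)
  list(mu = marg[, 1], sigma = marg[, 2], R_latent = Rl, repaired = repaired)
}
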