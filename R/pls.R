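#' Partial least squares regression (PLS2) via cross-covariance SVD
#'
#' Fits a latent-variable regression of a response block `Y` (here the
#' four WAB-R subtests) on a predictor block `X` (region or edge
#' features). Columns of both blocks are centered and unit-variance
#' scaled (constant columns are centered only and flagged); each
#' component's X-weight vector is the leading left singular vector of
#' the current (deflated) cross-covariance `X'Y`, scores are extracted
#' and `X` is deflated by score regression. This is the classical
#' NIPALS/`plsregress`-family algorithm in regression mode; the
#' implementation updates the `p x k` cross-covariance instead of
#' copying the deflated `n x p` block, which is algebraically identical
#' and keeps wide connectome matrices cheap.
#'
#' Each weight vector's sign is fixed so its largest-magnitude entry is
#' positive, making loadings deterministic (predictions and VIP scores
#' are invariant to these sign choices).
#'
#' @param X numeric matrix, subjects x features.
#' @param Y numeric matrix (or vector), subjects x responses.
#' @param n_components number of latent variables A,
#'   `A <= min(n - 1, p)`.
#' @param scale. logical; unit-variance scale the columns (default TRUE).
#' @return an object of class `plsr_model` with weights `W` (p x A),
#'   X-loadings `P`, Y-loadings `Q` (k x A), scores `T` (orthogonal
#'   columns), centering/scaling vectors, per-component explained Y
#'   sum-of-squares `ssy` on the standardized scale, squared singular
#'   values `sv2` of the deflated cross-covariances, and totals needed
#'   for explained-variance accounting.
#' @export
fit_plsr <- function(X, Y, n_components, scale. = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)
  if (nrow(Y) != n) stopf("X and Y must have the same number of subjects")
  if (n < 3) stopf("need at least 3 subjects, got %d", n)
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(colSums(!is.finite(X)) > 0)
    stopf("non-finite values in X columns: %s",
          paste(head(bad, 10), collapse = ", "))
  }
  if (anyNA(Y) || any(!is.finite(Y))) {
    bad <- which(colSums(!is.finite(Y)) > 0)
    stopf("non-finite values in Y columns: %s", paste(bad, collapse = ", "))
  }
  A <- as.integer(n_components)
  if (A < 1 || A > min(n - 1, p))
    stopf("n_components must lie in [1, min(n-1, p)] = [1, %d]", min(n - 1, p))

  xc <- colMeans(X); yc <- colMeans(Y)
  col_sd <- function(M, mu) sqrt(pmax(colSums(M^2) - nrow(M) * mu^2, 0) /
                                   (nrow(M) - 1))
  xs <- if (scale.) col_sd(X, xc) else rep(1, p)
  ys <- if (scale.) col_sd(Y, yc) else rep(1, k)
  const_x <- xs <= .Machine$double.eps^0.5
  xs[const_x] <- 1
  const_y <- ys <= .Machine$double.eps^0.5
  ys[const_y] <- 1
  X0 <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Y0 <- sweep(sweep(Y, 2, yc), 2, ys, "/")

  S <- crossprod(X0, Y0)
  ssx_total <- sum(X0^2); ssy_total <- sum(Y0^2)
  cov_total <- sum(S^2)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, k, A); Tm <- matrix(0, n, A)
  ssy <- ssx <- sv2 <- numeric(A)
  for (a in seq_len(A)) {
    sv <- svd(S, nu = 1, nv = 0)
    w <- sv$u[, 1]
    sv2[a] <- sv$d[1]^2
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    t <- X0 %*% w
    if (a > 1) {
      J <- seq_len(a - 1)
      t <- t - Tm[, J, drop = FALSE] %*% crossprod(P[, J, drop = FALSE], w)
    }
    tt <- sum(t^2)
    if (tt < 1e-12) {               # X exhausted before A components
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      Q <- Q[, seq_len(A), drop = FALSE]; Tm <- Tm[, seq_len(A), drop = FALSE]
      ssy <- ssy[seq_len(A)]; ssx <- ssx[seq_len(A)]; sv2 <- sv2[seq_len(A)]
      break
    }
    pl <- crossprod(X0, t)
    if (a > 1) {
      J <- seq_len(a - 1)
      pl <- pl - P[, J, drop = FALSE] %*% crossprod(Tm[, J, drop = FALSE], t)
    }
    pl <- pl / tt
    q <- crossprod(Y0, t) / tt
    S <- S - pl %*% t(q) * tt       # deflation of X'Y by score regression
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- t
    ssy[a] <- tt * sum(q^2)
    ssx[a] <- tt * sum(pl^2)
  }
  if (A < 1) stopf("X has no variance to decompose")
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Q) <- colnames(Y)
  structure(list(
    n_components = A, W = W, P = P, Q = Q, T = Tm,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    const_x = const_x, const_y = const_y,
    ssy = ssy, ssx = ssx, sv2 = sv2,
    ssx_total = ssx_total, ssy_total = ssy_total, cov_total = cov_total,
    feature_labels = colnames(X), response_names = colnames(Y),
    n = n, p = p, k = k, scaled = scale.
  ), class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  ec <- explained_covariance(x)
  cat(sprintf("<plsr_model> %d subjects, %d features, %d responses, %d LVs\n",
              x$n, x$p, x$k, x$n_components))
  cat(sprintf("  cumulative explained: X %.1f%%, Y %.1f%%, X-Y covariance %.1f%%\n",
              100 * ec$cum_x_var[x$n_components],
              100 * ec$cum_y_var[x$n_components],
              100 * ec$cum_xy_cov[x$n_components]))
  invisible(x)
}

#' Regression coefficients of a fitted PLS model
#'
#' @param object a `plsr_model`.
#' @param n_components number of components to use (default: all fitted).
#' @param standardized if TRUE, return the coefficients on the
#'   centered/scaled scale; otherwise back-transformed to original units
#'   (with an `intercept` attribute).
#' @param ... unused.
#' @return p x k coefficient matrix.
#' @export
coef.plsr_model <- function(object, n_components = object$n_components,
                            standardized = FALSE, ...) {
  a <- seq_len(n_components)
  W <- object$W[, a, drop = FALSE]
  P <- object$P[, a, drop = FALSE]
  Q <- object$Q[, a, drop = FALSE]
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(Q)
  dimnames(B) <- list(object$feature_labels, object$response_names)
  if (standardized) return(B)
  Bo <- (B / object$x_scale) %*% diag(object$y_scale, object$k)
  dimnames(Bo) <- dimnames(B)
  attr(Bo, "intercept") <- object$y_center - drop(crossprod(Bo, object$x_center))
  Bo
}

#' Predict responses for new subjects
#'
#' Applies the stored centering/scaling and the component-restricted
#' beta matrix; returns predictions in original response units.
#'
#' @param object a `plsr_model`.
#' @param newdata matrix of new subjects (same feature count/order).
#' @param n_components components to use (default: all fitted).
#' @param ... unused.
#' @return matrix of predicted responses.
#' @export
predict.plsr_model <- function(object, newdata,
                               n_components = object$n_components, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != object$p)
    stopf("newdata has %d features, model expects %d", ncol(Xn), object$p)
  B <- coef(object, n_components = n_components, standardized = TRUE)
  X0 <- sweep(sweep(Xn, 2, object$x_center), 2, object$x_scale, "/")
  Yh <- X0 %*% B
  Yh <- sweep(Yh %*% diag(object$y_scale, object$k), 2, object$y_center, "+")
  colnames(Yh) <- object$response_names
  Yh
}

#' Explained variance and covariance per component
#'
#' Per-component and cumulative fractions of (standardized) X variance,
#' Y variance, and X-Y covariance. The covariance fraction is the
#' squared singular value of the deflated cross-covariance normalized
#' over the computed components (the usual convention; the deflated
#' cross-covariances are not an orthogonal decomposition of the initial
#' one, so a Frobenius-norm denominator could exceed 1 cumulatively).
#' Cumulative Y variance is non-decreasing and reaches 1 at full rank
#' on a noiseless linear system.
#'
#' @param model a `plsr_model`.
#' @return data.frame with one row per component.
#' @export
explained_covariance <- function(model) {
  A <- model$n_components
  x_var <- model$ssx / model$ssx_total
  y_var <- model$ssy / model$ssy_total
  xy <- model$sv2 / max(sum(model$sv2), 1e-300)
  data.frame(
    component = seq_len(A),
    x_var = x_var, y_var = y_var, xy_cov = xy,
    cum_x_var = cumsum(x_var), cum_y_var = cumsum(y_var),
    cum_xy_cov = cumsum(xy)
  )
}

#' Smallest number of components explaining half the brain-behaviour covariance
#' @param model a `plsr_model`.
#' @param threshold cumulative covariance fraction (default 0.5).
#' @return integer component count, or `NA` if never reached.
#' @export
components_to_half_cov <- function(model, threshold = 0.5) {
  cum <- explained_covariance(model)$cum_xy_cov
  idx <- which(cum >= threshold)
  if (length(idx)) idx[1] else NA_integer_
}

#' Variable importance in projection (VIP)
#'
#' Standard Wold VIP: each feature's squared normalized weights are
#' averaged over components, weighted by the Y sum-of-squares `SSY_a`
#' each component explains, and scaled so the squared scores average 1:
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)`.
#' Consequently `sum_j VIP_j^2 = p` exactly.
#'
#' @param model a `plsr_model`.
#' @param n_components components to summarize over (default: all
#'   fitted; the pipeline uses the retained count, conventionally 5).
#' @return object of class `vip_vector`: named numeric vector with
#'   attribute `n_components`.
#' @export
vip_scores <- function(model, n_components = model$n_components) {
  a <- seq_len(n_components)
  ssy <- model$ssy[a]
  if (sum(ssy) <= 1e-12)
    stopf("total explained Y sum-of-squares is zero (constant Y?)")
  W <- model$W[, a, drop = FALSE]
  Wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(model$p * drop(Wn2 %*% ssy) / sum(ssy))
  names(v) <- model$feature_labels
  structure(v, n_components = n_components, class = c("vip_vector", "numeric"))
}

#' Relative Y-loading profile across retained components
#'
#' For each response, the SSY-weighted average of its absolute Y
#' loadings across components, normalized to sum to 1 across responses.
#' Ranks the responses by how dominantly they shape the latent
#' decomposition (in aphasia cohorts spontaneous speech typically
#' dominates).
#'
#' @param model a `plsr_model`.
#' @param n_components components to summarize over (default: all).
#' @return named numeric vector summing to 1.
#' @export
y_loading_profile <- function(model, n_components = model$n_components) {
  a <- seq_len(n_components)
  ssy <- model$ssy[a]
  wts <- if (sum(ssy) > 0) ssy / sum(ssy) else rep(1 / length(a), length(a))
  raw <- drop(abs(model$Q[, a, drop = FALSE]) %*% wts)
  out <- raw / sum(raw)
  names(out) <- model$response_names
  out
}
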