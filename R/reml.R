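#' Single-random-effect linear mixed model by REML
#'
#' Fits \eqn{y = X\beta + Zu + e} with \eqn{u \sim N(0, K\sigma^2_u)} and
#' \eqn{e \sim N(0, R\sigma^2_e)}, \eqn{R = \mathrm{diag}(w)}, by restricted
#' maximum likelihood. The restricted log-likelihood is profiled down to the
#' one-dimensional variance ratio \eqn{\delta = \sigma^2_e/\sigma^2_u} and
#' maximised by Brent search on \eqn{\log\delta} after a spectral
#' decomposition of the projected kernel, the same strategy used by spectral
#' ridge-regression BLUP solvers. This one solver powers marker-effect
#' ridge regression (Z = dosages, K = I), pedigree BLUP (K = A) and genomic
#' BLUP (K = G).
#'
#' When `ncol(Z)` is smaller than the residual degrees of freedom the
#' eigendecomposition is taken on the q-by-q projected kernel rather than the
#' n-by-n covariance, so marker models with few markers and line models with
#' few lines are both cheap.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix; defaults to an intercept column.
#' @param Z Random-effect design matrix; defaults to the identity.
#' @param K Covariance kernel for `u` (symmetric PSD); defaults to identity.
#' @param weights Positive residual variance multipliers, one per
#'   observation (`Var(e_i) = sigma2_e * weights[i]`). Default all 1.
#' @param lambda If supplied, the ratio \eqn{\sigma^2_e/\sigma^2_u} is fixed
#'   at this value instead of estimated (the scale \eqn{\sigma^2_u} is still
#'   profiled). Used for conditional fits.
#' @param method `"REML"` (default) or `"ML"`.
#' @param compute_pev `"diag"` (default), `"full"` or `"none"`: how much of
#'   the prediction-error (co)variance of `u` to return.
#' @param bounds Search bounds for \eqn{\log\delta} (natural log).
#'
#' @return An object of class `reml_fit`: a list with `sigma2_u`, `sigma2_e`,
#'   `lambda` (= sigma2_e/sigma2_u), `beta`, `beta_se`, `u`, `pev` (vector,
#'   matrix or NULL), `loglik` (restricted, orthonormal-contrast convention,
#'   on the weight-transformed scale), `boundary` flag and bookkeeping.
#' @export
reml_solve <- function(y, X = NULL, Z = NULL, K = NULL, weights = NULL,
                       lambda = NULL, method = c("REML", "ML"),
                       compute_pev = c("diag", "full", "none"),
                       bounds = c(-10, 10)) {
  method <- match.arg(method)
  compute_pev <- match.arg(compute_pev)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(Z)) Z <- diag(n)
  Z <- as.matrix(Z)
  q <- ncol(Z)
  if (nrow(X) != n || nrow(Z) != n) {
    abort("Dimension error: X and Z must have one row per observation.")
  }
  identity_K <- is.null(K)
  if (!identity_K) {
    K <- as.matrix(K)
    if (nrow(K) != q || ncol(K) != q) {
      abort("Dimension error: K must be square with one row per column of Z.")
    }
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
      abort("Kernel error: K must be symmetric.")
    }
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort("`weights` must be positive and finite.")
  }

  # Transform to unit residual variance.
  sw <- sqrt(weights)
  yt <- y / sw
  Xt <- X / sw
  Zt <- Z / sw

  qrX <- qr(Xt)
  p <- qrX$rank
  if (p < ncol(Xt)) {
    abort(sprintf("Rank-deficiency error: X has %d columns but rank %d.",
                  ncol(Xt), p))
  }
  m <- n - p
  if (m <= 0) abort("Need more observations than fixed-effect parameters.")
  # Projector onto the orthocomplement of the X column space, applied via
  # the thin Q factor so the n x (n-p) contrast basis is never formed when
  # the cheap q x q route below is taken.
  Q1 <- qr.Q(qrX)
  proj <- function(A) A - Q1 %*% crossprod(Q1, A)

  # Square root of K with eigenvalue clipping for near-PSD kernels.
  clipped <- FALSE
  if (identity_K) {
    Ksqrt <- NULL
  } else {
    eK <- eigen(K, symmetric = TRUE)
    tol <- 1e-10 * max(eK$values, 1e-12)
    if (min(eK$values) < -1e-6 * max(abs(eK$values), 1)) {
      abort("Kernel error: K has large negative eigenvalues (not PSD).")
    }
    if (any(eK$values < tol)) clipped <- TRUE
    ev <- pmax(eK$values, tol)
    Ksqrt <- eK$vectors %*% (sqrt(ev) * t(eK$vectors))
  }
  B <- if (identity_K) Zt else Zt %*% Ksqrt   # n x q, V0 = B B' + delta I

  # Spectral pieces for the profiled restricted likelihood.
  Sy <- proj(yt)
  if (q < m) {
    # nonzero eigenvalues of the projected kernel come from the q x q
    # cross-product B'SB; the (m - q)-dimensional null part only needs the
    # residual squared norm
    SB <- proj(B)
    eE <- eigen(crossprod(SB), symmetric = TRUE)
    theta <- pmax(eE$values, 0)
    v <- crossprod(SB, yt)                    # q x 1 (= B'S y)
    pos <- theta > max(theta, 1) * 1e-12
    eta2_pos <- as.numeric(crossprod(eE$vectors[, pos, drop = FALSE], v))^2 /
      theta[pos]
    theta_pos <- theta[pos]
    eta2_zero <- max(sum(yt * Sy) - sum(eta2_pos), 0)
    n_zero <- m - sum(pos)
  } else {
    Tb <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
    Tty <- crossprod(Tb, yt)
    H <- tcrossprod(B)                        # n x n
    Mt <- crossprod(Tb, H %*% Tb)
    eM <- eigen((Mt + t(Mt)) / 2, symmetric = TRUE)
    theta_pos <- pmax(eM$values, 0)
    eta2_pos <- as.numeric(crossprod(eM$vectors, Tty))^2
    eta2_zero <- 0
    n_zero <- 0L
  }

  ss_fun <- function(delta) {
    sum(eta2_pos / (theta_pos + delta)) + eta2_zero / delta
  }
  ld_fun <- function(delta) {
    sum(log(theta_pos + delta)) + n_zero * log(delta)
  }
  rll <- function(logd) {
    delta <- exp(logd)
    s2 <- ss_fun(delta) / m
    -0.5 * (m * log(2 * pi * max(s2, 1e-300)) + ld_fun(delta) + m)
  }

  boundary <- FALSE
  if (!is.null(lambda)) {
    check_range(lambda, "lambda", lo = 0)
    delta <- max(lambda, 1e-12)
    loglik <- rll(log(delta))
  } else if (method == "REML") {
    opt <- optimize(rll, interval = bounds, maximum = TRUE, tol = 1e-9)
    delta <- exp(opt$maximum)
    loglik <- opt$objective
    boundary <- min(abs(opt$maximum - bounds)) < 1e-4
  } else {
    # Full (unrestricted) likelihood, profiled over beta and sigma2_u.
    mll <- function(logd) {
      delta <- exp(logd)
      fit <- gls_pieces(yt, Xt, B, delta)
      s2 <- fit$rss / n
      -0.5 * (n * log(2 * pi * max(s2, 1e-300)) + fit$ldet + n)
    }
    opt <- optimize(mll, interval = bounds, maximum = TRUE, tol = 1e-9)
    delta <- exp(opt$maximum)
    loglik <- opt$objective
    boundary <- min(abs(opt$maximum - bounds)) < 1e-4
  }

  fit <- gls_pieces(yt, Xt, B, delta)
  sigma2_u <- if (method == "ML" && is.null(lambda)) {
    fit$rss / n
  } else {
    ss_fun(delta) / m
  }
  sigma2_e <- delta * sigma2_u

  beta <- drop(fit$beta)
  names(beta) <- colnames(X) %||% paste0("b", seq_len(ncol(X)))
  beta_se <- sqrt(pmax(diag(fit$XtVinvX_inv), 0) * sigma2_u)
  names(beta_se) <- names(beta)

  # BLUP of u: K Z' V0^{-1} (y - X beta), all on the transformed scale.
  resid0 <- yt - Xt %*% fit$beta
  Bt_r <- crossprod(B, fit$v0inv(resid0))     # q x 1
  u <- if (identity_K) drop(Bt_r) else drop(Ksqrt %*% Bt_r)
  names(u) <- colnames(Z) %||% paste0("u", seq_len(q))

  pev <- NULL
  if (compute_pev != "none") {
    D <- if (identity_K) B else B %*% Ksqrt   # Zt K, n x q
    ViD <- fit$v0inv(D)
    M2 <- crossprod(Xt, ViD)                  # p x q
    Kfull <- if (identity_K) diag(q) else K
    PEV <- sigma2_u * (Kfull - crossprod(D, ViD) +
                         t(M2) %*% fit$XtVinvX_inv %*% M2)
    if (compute_pev == "diag") {
      pev <- pmax(diag(PEV), 0)
      names(pev) <- names(u)
    } else {
      dimnames(PEV) <- list(names(u), names(u))
      pev <- PEV
    }
  }

  structure(list(
    sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = delta,
    beta = beta, beta_se = beta_se, u = u, pev = pev,
    loglik = loglik, method = method, boundary = boundary,
    kernel_clipped = clipped, n = n, rank_x = p, q = q
  ), class = "reml_fit")
}

# GLS quantities at a fixed ratio delta: V0 = B B' + delta I on the
# transformed scale. Uses the Woodbury identity when q < n, dense Cholesky
# otherwise. Returns beta, (X'V0^-1 X)^-1, the weighted RSS r'V0^-1 r,
# log|V0| + log|X'V0^-1 X| - log|X'X| (ML path reuses ldet of V0 only), and
# a closure applying V0^{-1}.
gls_pieces <- function(yt, Xt, B, delta) {
  n <- nrow(B); q <- ncol(B)
  if (q < n) {
    inner <- crossprod(B) + delta * diag(q)
    ch <- chol(inner)
    v0inv <- function(A) {
      (A - B %*% backsolve(ch, backsolve(ch, crossprod(B, A),
                                         transpose = TRUE))) / delta
    }
    ldet <- 2 * sum(log(diag(ch))) + (n - q) * log(delta)
  } else {
    V0 <- tcrossprod(B) + delta * diag(n)
    ch <- chol(V0)
    v0inv <- function(A) backsolve(ch, backsolve(ch, A, transpose = TRUE))
    ldet <- 2 * sum(log(diag(ch)))
  }
  ViX <- v0inv(Xt)
  XtViX <- crossprod(Xt, ViX)
  XtViX_inv <- solve(XtViX)
  beta <- XtViX_inv %*% crossprod(ViX, yt)
  r <- yt - Xt %*% beta
  rss <- sum(r * v0inv(r))
  list(beta = beta, XtVinvX_inv = XtViX_inv, rss = rss, ldet = ldet,
       v0inv = v0inv)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> %s | n = %d, q = %d\n  sigma2_u = %.6g, sigma2_e = %.6g (lambda = %.4g)\n  loglik = %.4f%s\n",
    x$method, x$n, x$q, x$sigma2_u, x$sigma2_e, x$lambda, x$loglik,
    if (x$boundary) "  [ratio at search boundary]" else ""))
  invisible(x)
}

#' @rdname reml_solve
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @export
tidy.reml_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = names(x$beta), type = "fixed", estimate = unname(x$beta),
           std_error = unname(x$beta_se)),
    tibble(term = names(x$u), type = "random", estimate = unname(x$u),
           std_error = if (!is.null(x$pev) && is.null(dim(x$pev)))
             sqrt(unname(x$pev)) else NA_real_))
}

#' @rdname reml_solve
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e, lambda = x$lambda,
         loglik = x$loglik, n = x$n, q = x$q, method = x$method,
         boundary = x$boundary)
}
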