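#' Stage-2 analysis: across-trial BLUPs
#'
#' Fits the across-environment mixed model on stage-1 BLUEs: environment
#' (year-by-location) as fixed effects, line as a random effect with a
#' chosen covariance kernel — pedigree A for performance BLUPs, genomic G
#' for genomic BLUPs, or identity — and residuals weighted per record. The
#' default residual weights are the squared stage-1 standard errors, making
#' the residual covariance proportional to the stage-1 error covariance;
#' identity weights are available for sensitivity analysis.
#'
#' @param blues Stage-1 output tibble (columns `line`, `env`, `blue`, and
#'   `se` unless `weights = "identity"`).
#' @param kernel Optional covariance matrix for lines (A or G, with line
#'   dimnames covering every line); `NULL` uses the identity.
#' @param dosage Alternative to a genomic `kernel`: a `dosage_matrix`
#'   covering every line. The model is then fitted in its marker
#'   parameterisation (random marker effects, identity kernel), which gives
#'   the *same* genomic BLUPs as the corresponding G-kernel fit but scales
#'   with the number of markers instead of the number of lines. `H2` is not
#'   computed on this route.
#' @param weights `"se"` (default; residual weight = stage-1 SE^2) or
#'   `"identity"`.
#' @param lambda Optional fixed variance ratio passed to [reml_solve()]
#'   (conditional fit; otherwise REML-estimated).
#' @param compute_pev Passed to [reml_solve()] (`"diag"` default).
#'
#' @return An object of class `stage_two_fit`: `blup` (tibble: line, blup,
#'   pev), `env_effects` (tibble: env, estimate, se), `mu`, `vc` (sigma2_g,
#'   sigma2_e, lambda), `H2` (Cullis generalised heritability of the
#'   analysis), `fit` (the underlying `reml_fit`).
#' @export
fit_stage_two <- function(blues, kernel = NULL, dosage = NULL,
                          weights = c("se", "identity"), lambda = NULL,
                          compute_pev = "diag") {
  weights <- match.arg(weights)
  blues <- as_tibble(blues)
  need <- c("line", "env", "blue")
  if (!all(need %in% names(blues))) {
    abort("`blues` needs columns line, env, blue (and se for SE weights).")
  }
  if (!is.null(kernel) && !is.null(dosage)) {
    abort("Supply `kernel` or `dosage`, not both.")
  }
  if (sd(blues$blue) < 1e-12) {
    warn("All BLUEs identical; degenerate response, BLUPs set to 0.")
  }
  lines <- unique(blues$line)
  if (!is.null(dosage)) {
    missing_lines <- setdiff(lines, rownames(dosage))
    if (length(missing_lines) > 0) {
      abort(sprintf("Coverage error: %d line(s) absent from dosage: %s",
                    length(missing_lines),
                    paste(head(missing_lines, 5), collapse = ", ")))
    }
  }
  if (!is.null(kernel)) {
    missing_lines <- setdiff(lines, rownames(kernel))
    if (length(missing_lines) > 0) {
      abort(sprintf("Coverage error: %d line(s) absent from kernel: %s",
                    length(missing_lines),
                    paste(head(missing_lines, 5), collapse = ", ")))
    }
    kernel <- kernel[lines, lines]
  }
  w <- if (weights == "se") {
    if (!"se" %in% names(blues) || any(!is.finite(blues$se)) ||
        any(blues$se <= 0)) {
      abort("SE weights need a positive finite `se` column.")
    }
    blues$se^2
  } else rep(1, nrow(blues))

  env <- factor(blues$env)
  X <- if (nlevels(env) > 1) {
    model.matrix(~ env, contrasts.arg = list(env = "contr.sum"))
  } else matrix(1, nrow(blues), 1, dimnames = list(NULL, "(Intercept)"))

  if (!is.null(dosage)) {
    # marker parameterisation: Z row = the record's centred line dosages
    # (column-centring matches the G construction, so the two routes give
    # identical BLUPs; the centring constant is absorbed by the intercept)
    M <- as.matrix(dosage)[lines, , drop = FALSE]
    M <- sweep(M, 2, colMeans(M))
    Zm <- M[match(blues$line, lines), , drop = FALSE]
    fit <- reml_solve(blues$blue, X = X, Z = Zm, weights = w,
                      lambda = lambda, compute_pev = compute_pev)
    u_line <- as.numeric(M %*% fit$u)
    pev_line <- if (!is.null(fit$pev)) {
      PU <- if (is.matrix(fit$pev)) fit$pev else diag(fit$pev)
      if (compute_pev == "full") M %*% PU %*% t(M)
      else rowSums((M %*% PU) * M)
    } else NULL
    fit$u <- setNames(u_line, lines)
    fit$pev <- pev_line
    fit$q <- length(lines)
  } else {
    Z <- model.matrix(~ 0 + factor(blues$line, levels = lines))
    colnames(Z) <- lines
    fit <- reml_solve(blues$blue, X = X, Z = Z, K = kernel, weights = w,
                      lambda = lambda, compute_pev = compute_pev)
  }

  mu <- unname(fit$beta[1])
  env_eff <- if (nlevels(env) > 1) {
    # sum-contrast coefficients: last level is minus the sum of the others
    coefs <- fit$beta[-1]
    ses <- fit$beta_se[-1]
    tibble(env = levels(env),
           estimate = c(coefs, -sum(coefs)),
           se = c(ses, NA_real_))
  } else tibble(env = levels(env), estimate = 0, se = NA_real_)

  pev_d <- if (!is.null(fit$pev)) {
    if (is.matrix(fit$pev)) diag(fit$pev) else fit$pev
  } else rep(NA_real_, length(lines))
  H2 <- if (!is.null(dosage)) {
    NA_real_  # marker route: line-level sigma2_g is not a single scalar
  } else if (fit$sigma2_u > 1e-10 && !is.null(fit$pev) && is.matrix(fit$pev)) {
    q <- length(lines)
    dbar <- 2 * sum(diag(fit$pev)) / q -
      2 * (sum(fit$pev) - sum(diag(fit$pev))) / (q * (q - 1))
    min(max(1 - dbar / (2 * fit$sigma2_u), 0), 1)
  } else if (fit$sigma2_u > 1e-10 && !is.null(fit$pev)) {
    # diagonal-only approximation (PEV correlations ignored)
    min(max(1 - mean(pev_d) / fit$sigma2_u, 0), 1)
  } else NA_real_

  structure(list(
    blup = tibble(line = lines, blup = unname(fit$u),
                  pev = unname(pev_d)),
    env_effects = env_eff, mu = mu,
    vc = tibble(sigma2_g = fit$sigma2_u, sigma2_e = fit$sigma2_e,
                lambda = fit$lambda),
    H2 = H2, weights = weights,
    kernel = if (!is.null(dosage)) "markers"
    else if (is.null(kernel)) "identity" else "custom",
    fit = fit), class = "stage_two_fit")
}

#' @export
print.stage_two_fit <- function(x, ...) {
  cat(sprintf(
    "<stage_two_fit> %d lines, %d environments | kernel: %s, weights: %s\n  sigma2_g = %.4g, sigma2_e = %.4g, H2 = %s\n",
    nrow(x$blup), nrow(x$env_effects), x$kernel, x$weights,
    x$vc$sigma2_g, x$vc$sigma2_e,
    if (is.na(x$H2)) "NA" else sprintf("%.3f", x$H2)))
  invisible(x)
}

#' @rdname fit_stage_two
#' @param x A `stage_two_fit`.
#' @param ... Unused.
#' @export
tidy.stage_two_fit <- function(x, ...) x$blup

#' @rdname fit_stage_two
#' @export
glance.stage_two_fit <- function(x, ...) {
  dplyr::mutate(x$vc, H2 = x$H2, mu = x$mu, n_lines = nrow(x$blup),
                n_env = nrow(x$env_effects))
}
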