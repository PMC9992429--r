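#' Genomic estimated breeding values by ridge-regression BLUP
#'
#' Fits \eqn{y = 1\mu + Mu + e} with marker effects
#' \eqn{u \sim N(0, I\sigma^2_u)} on the phenotyped lines via [reml_solve()],
#' then scores every genotyped line (phenotyped or not) as
#' \eqn{GEBV_i = M_i \hat u}. With an intercept-only fixed part and centred
#' dosages the GEBVs of the training set are centred near zero.
#'
#' @param dosage A `dosage_matrix` from [encode_dosage()] covering all lines
#'   to score.
#' @param pheno Tibble with columns `line` and `value` (typically stage-1
#'   BLUEs, or their per-line means). Phenotyped lines must be a subset of
#'   the genotyped lines.
#' @param compute_pev Passed to [reml_solve()]; default `"none"` (marker
#'   PEVs are rarely needed and cost q^2 work).
#' @return An object of class `gebv_fit`: `gebv` (tibble line/gebv),
#'   `marker_effects` (tibble marker/effect), `vc`, `degenerate` flag,
#'   `fit` (the `reml_fit`).
#' @export
compute_gebv <- function(dosage, pheno, compute_pev = "none") {
  pheno <- as_tibble(pheno)
  if (!all(c("line", "value") %in% names(pheno))) {
    abort("`pheno` needs columns line, value.")
  }
  missing_geno <- setdiff(pheno$line, rownames(dosage))
  if (length(missing_geno) > 0) {
    abort(sprintf("Dimension error: %d phenotyped line(s) not genotyped: %s",
                  length(missing_geno),
                  paste(head(missing_geno, 5), collapse = ", ")))
  }
  M_all <- as.matrix(dosage)
  poly <- apply(M_all, 2, function(x) max(x) - min(x) > 1e-12)
  if (sum(poly) < 2) abort("Need at least 2 polymorphic markers.")
  M <- M_all[pheno$line, , drop = FALSE]

  if (sd(pheno$value) < 1e-12) {
    warn("Constant phenotype: degenerate fit, GEBVs all 0.")
    return(structure(list(
      gebv = tibble(line = rownames(M_all), gebv = 0),
      marker_effects = tibble(marker = colnames(M_all), effect = 0),
      vc = tibble(sigma2_u = 0, sigma2_e = 0, lambda = NA_real_),
      degenerate = TRUE, fit = NULL), class = "gebv_fit"))
  }
  fit <- reml_solve(pheno$value, Z = M, compute_pev = compute_pev)
  gebv <- as.numeric(M_all %*% fit$u)
  structure(list(
    gebv = tibble(line = rownames(M_all), gebv = gebv),
    marker_effects = tibble(marker = colnames(M_all),
                            effect = unname(fit$u)),
    vc = tibble(sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e,
                lambda = fit$lambda),
    degenerate = FALSE, fit = fit), class = "gebv_fit")
}

#' @export
print.gebv_fit <- function(x, ...) {
  cat(sprintf("<gebv_fit> %d lines scored, %d markers%s\n",
              nrow(x$gebv), nrow(x$marker_effects),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @rdname compute_gebv
#' @param x A `gebv_fit`.
#' @param ... Unused.
#' @export
tidy.gebv_fit <- function(x, ...) x$gebv

#' @rdname compute_gebv
#' @export
glance.gebv_fit <- function(x, ...) {
  dplyr::mutate(x$vc, n_lines = nrow(x$gebv),
                n_markers = nrow(x$marker_effects),
                degenerate = x$degenerate)
}

#' Predict unphenotyped lines from a trained marker model
#'
#' Estimates marker effects from the training lines only (e.g. yield-tested
#' parents) and scores a target set that has genotypes but no phenotypes
#' (e.g. their early-generation progeny). Marker sets are intersected; the
#' call refuses to predict when the overlap falls below `min_overlap`.
#'
#' @param train_dosage,target_dosage `dosage_matrix` objects.
#' @param train_pheno Tibble `line`/`value` for the training lines.
#' @param min_overlap Minimum shared-marker count (default 100).
#' @return A tibble `line`/`gebv` for the target lines, with attribute
#'   `marker_overlap`.
#' @export
predict_unphenotyped <- function(train_dosage, train_pheno, target_dosage,
                                 min_overlap = 100) {
  shared <- intersect(colnames(train_dosage), colnames(target_dosage))
  if (length(shared) < min_overlap) {
    abort(sprintf(
      "Marker overlap too small: %d shared markers (floor %d). Training has %d, target %d.",
      length(shared), min_overlap, ncol(train_dosage), ncol(target_dosage)))
  }
  fit <- compute_gebv(train_dosage[, shared, drop = FALSE], train_pheno)
  eff <- setNames(fit$marker_effects$effect, fit$marker_effects$marker)
  out <- tibble(line = rownames(target_dosage),
                gebv = as.numeric(as.matrix(target_dosage)[, shared,
                                                           drop = FALSE] %*%
                                    eff[shared]))
  attr(out, "marker_overlap") <- length(shared)
  out
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBVs and observed values over the lines
#' present in both tables — the accuracy definition used throughout genomic
#' selection. Constant vectors raise an error rather than returning a
#' silent 0.
#'
#' @param gebv Tibble `line`/`gebv` (or a `gebv_fit`).
#' @param observed Tibble `line`/`value`.
#' @return A single correlation in \[-1, 1\].
#' @export
prediction_accuracy <- function(gebv, observed) {
  if (inherits(gebv, "gebv_fit")) gebv <- gebv$gebv
  merged <- dplyr::inner_join(as_tibble(gebv), as_tibble(observed),
                              by = "line")
  if (nrow(merged) < 3) abort("Need at least 3 shared lines.")
  safe_cor(merged$gebv, merged$value, "GEBV/observed vectors")
}

#' Relative efficiency of genomic selection
#'
#' Scales GS accuracy by trial heritability to compare genomic with
#' phenotypic selection. Two conventions are supported — `r/H2` (the
#' default) and `r/sqrt(H2)` — and the one used is recorded in the result,
#' since the literature prints both.
#'
#' @param r GS accuracy in (-1, 1\].
#' @param H2 Estimated heritability in (0, 1\].
#' @param convention `"h2"` for r/H2 (default) or `"sqrt_h2"` for r/sqrt(H2).
#' @return A tibble: `accuracy`, `H2`, `convention`, `rec`.
#' @export
relative_efficiency <- function(r, H2, convention = c("h2", "sqrt_h2")) {
  convention <- match.arg(convention)
  if (!is.numeric(H2) || H2 <= 0 || H2 > 1) {
    abort("Parameter error: `H2` must lie in (0, 1].")
  }
  if (!is.numeric(r) || r <= -1 || r > 1) {
    abort("Parameter error: `r` must lie in (-1, 1].")
  }
  rec <- if (convention == "h2") r / H2 else r / sqrt(H2)
  tibble(accuracy = r, H2 = H2, convention = convention, rec = rec)
}

#' Select parents on GEBV
#'
#' Top-k lines by GEBV, descending; ties broken by line id so the ranking is
#' deterministic.
#'
#' @param gebv A `gebv_fit` or a tibble `line`/`gebv`.
#' @param k Number of parents to select.
#' @return A tibble `rank`/`line`/`gebv`.
#' @export
select_parents <- function(gebv, k) {
  if (inherits(gebv, "gebv_fit")) gebv <- gebv$gebv
  gebv <- as_tibble(gebv)
  check_range(k, "k", 1, Inf, integer = TRUE)
  if (k > nrow(gebv)) abort("Parameter error: `k` exceeds the number of lines.")
  gebv |>
    dplyr::arrange(dplyr::desc(.data$gebv), .data$line) |>
    head(k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
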