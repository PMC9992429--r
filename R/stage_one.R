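#' Choose the blocking model for one trial by BIC
#'
#' Fits every admissible fixed-effects blocking structure for the trial's
#' design — \{none, replicate\} for RCBD and augmented designs, \{none, row,
#' column, row+column\} for row-column designs — always with genotype
#' effects, by least squares, and returns the structure with the lowest BIC
#' (maximum-likelihood BIC, since candidates differ in their fixed effects).
#' Ties go to the model with fewer parameters. Candidates whose blocking
#' columns are aliased with genotypes, or that leave no residual degrees of
#' freedom, are skipped with a log entry.
#'
#' @param trial A plot-record tibble for a single trial (columns `line`,
#'   `design`, and the design factors `rep`/`row`/`col`/`block`,
#'   `yield_t_ha`).
#' @return A list: `blocking` (character vector of chosen blocking terms,
#'   possibly empty), `bic` (tibble of candidates), `skipped` (character).
#' @export
select_blocking_model <- function(trial) {
  trial <- as_tibble(trial)
  if (length(unique(trial$trial %||% "t")) > 1) {
    abort("`trial` must contain a single trial.")
  }
  design <- unique(trial$design)
  if (length(design) != 1) abort("A trial must have exactly one design.")
  candidates <- switch(
    design,
    "RCBD" = list(character(0), "block"),
    "augmented" = list(character(0), "block"),
    "row-column" = list(character(0), "row", "col", c("row", "col")),
    abort(sprintf("Unknown design '%s'.", design)))

  rows <- list(); skipped <- character(0)
  for (cand in candidates) {
    dat <- dplyr::mutate(trial, line = factor(.data$line),
                         dplyr::across(dplyr::any_of(c("block", "row", "col")),
                                       factor))
    rhs <- paste(c("line", cand), collapse = " + ")
    fit <- try(lm(stats::as.formula(paste("yield_t_ha ~ 0 +", rhs)),
                  data = dat), silent = TRUE)
    label <- if (length(cand) == 0) "none" else paste(cand, collapse = "+")
    if (inherits(fit, "try-error")) {
      skipped <- c(skipped, label); next
    }
    npar <- sum(!is.na(coef(fit)))
    aliased_blocks <- length(cand) > 0 && any(is.na(coef(fit)))
    if (fit$df.residual <= 0 || aliased_blocks) {
      skipped <- c(skipped, label); next
    }
    rows[[length(rows) + 1]] <- tibble(
      blocking = label, n_par = npar, bic = BIC(fit))
  }
  if (length(rows) == 0) {
    # only the genotype-means model is admissible
    return(list(blocking = character(0),
                bic = tibble(blocking = "none", n_par = NA_real_,
                             bic = NA_real_),
                skipped = skipped))
  }
  bic_tbl <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$bic, .data$n_par)
  chosen <- bic_tbl$blocking[1]
  list(blocking = if (chosen == "none") character(0)
       else strsplit(chosen, "+", fixed = TRUE)[[1]],
       bic = bic_tbl, skipped = skipped)
}

#' Stage-1 analysis: per-trial BLUEs
#'
#' Fits the chosen fixed-effects model (genotype effects plus any blocking
#' factors, blocking factors in sum-to-zero contrasts so genotype
#' coefficients are adjusted means at the average block) and returns the
#' best linear unbiased estimate and standard error per line. In augmented
#' designs the replicated checks estimate the block effects that adjust the
#' unreplicated entries.
#'
#' @param trial Plot records of one trial.
#' @param blocking Character vector of blocking terms (e.g. `"block"` or
#'   `c("row", "col")`). `NULL` (default) triggers [select_blocking_model()].
#' @return A tibble: `line`, `trial`, `year`, `location`, `env`, `blue`,
#'   `se`, `n_plots`.
#' @export
fit_stage_one <- function(trial, blocking = NULL) {
  trial <- as_tibble(trial)
  if (nrow(trial) == 0) abort("Empty trial.")
  if (dplyr::n_distinct(trial$line) < 2) {
    abort("A trial needs at least 2 distinct lines.")
  }
  if (is.null(blocking)) blocking <- select_blocking_model(trial)$blocking
  dat <- dplyr::mutate(trial, line = factor(.data$line),
                       dplyr::across(dplyr::any_of(c("block", "row", "col")),
                                     factor))
  rhs <- paste(c("line", blocking), collapse = " + ")
  ctr <- lapply(setNames(nm = blocking), function(x) "contr.sum")
  fit <- lm(stats::as.formula(paste("yield_t_ha ~ 0 +", rhs)), data = dat,
            contrasts = if (length(blocking)) ctr else NULL)
  if (fit$df.residual <= 0) {
    abort("Residual degrees of freedom <= 0; cannot estimate BLUE SEs.")
  }
  cf <- coef(fit)
  keep <- grep("^line", names(cf))
  est <- cf[keep]
  ses <- sqrt(diag(vcov(fit))[keep])
  ids <- sub("^line", "", names(est))
  meta <- dat |>
    dplyr::group_by(line = as.character(.data$line)) |>
    dplyr::summarise(trial = .data$trial[1], year = .data$year[1],
                     location = .data$location[1], n_plots = dplyr::n(),
                     .groups = "drop")
  tibble(line = ids, blue = unname(est), se = unname(ses)) |>
    dplyr::left_join(meta, by = "line") |>
    dplyr::mutate(env = paste(.data$year, .data$location, sep = ":")) |>
    dplyr::select("line", "trial", "year", "location", "env", "blue", "se",
                  "n_plots")
}

#' Run stage 1 across every trial in a table
#'
#' Splits plot records by trial, chooses each trial's blocking model by BIC,
#' extracts BLUEs, and estimates each trial's generalised heritability.
#'
#' @param trials Plot-record tibble covering one or more trials.
#' @param heritability Whether to compute per-trial Cullis H2 (needs a
#'   genotype-random refit; modestly more work).
#' @return A list: `blues` (stacked stage-1 output), `models` (tibble:
#'   trial, blocking, H2).
#' @export
fit_trials <- function(trials, heritability = FALSE) {
  trials <- as_tibble(trials)
  parts <- split(trials, trials$trial)
  blues <- list(); models <- list()
  for (tr in names(parts)) {
    sel <- select_blocking_model(parts[[tr]])
    blues[[tr]] <- fit_stage_one(parts[[tr]], blocking = sel$blocking)
    models[[tr]] <- tibble(
      trial = tr,
      blocking = if (length(sel$blocking) == 0) "none"
      else paste(sel$blocking, collapse = "+"),
      H2 = if (heritability) estimate_trial_heritability(parts[[tr]])
      else NA_real_)
  }
  list(blues = dplyr::bind_rows(blues), models = dplyr::bind_rows(models))
}

#' Generalised (Cullis) trial heritability
#'
#' Refits the trial with genotype as a random effect (identity kernel,
#' blocking factors fixed) and computes
#' \eqn{H^2 = 1 - \bar v_\Delta / (2\hat\sigma^2_g)}, where
#' \eqn{\bar v_\Delta} is the mean prediction-error variance of a difference
#' between two genotype BLUPs. This definition stays meaningful under
#' unbalance (e.g. augmented designs); the result is clipped to \[0, 1\].
#'
#' @param trial Plot records of one trial.
#' @param blocking Blocking terms; `NULL` chooses by BIC.
#' @return H2 in \[0, 1\]; 0 (with a `zero_vg` attribute) when the genetic
#'   variance estimate is zero.
#' @export
estimate_trial_heritability <- function(trial, blocking = NULL) {
  trial <- as_tibble(trial)
  if (is.null(blocking)) blocking <- select_blocking_model(trial)$blocking
  dat <- dplyr::mutate(trial, line = factor(.data$line),
                       dplyr::across(dplyr::any_of(c("block", "row", "col")),
                                     factor))
  X <- if (length(blocking) == 0) {
    matrix(1, nrow(dat), 1)
  } else {
    ctr <- lapply(setNames(nm = blocking), function(x) "contr.sum")
    model.matrix(stats::as.formula(paste("~", paste(blocking, collapse = "+"))),
                 data = dat, contrasts.arg = ctr)
  }
  Z <- model.matrix(~ 0 + line, data = dat)
  fit <- reml_solve(dat$yield_t_ha, X = X, Z = Z, compute_pev = "full")
  if (fit$sigma2_u < 1e-10 * max(fit$sigma2_e, 1e-12)) {
    return(structure(0, zero_vg = TRUE))
  }
  pev <- fit$pev
  q <- ncol(Z)
  # mean PEV of a difference over all line pairs
  dbar <- (2 * sum(diag(pev)) / q) - 2 * (sum(pev) - sum(diag(pev))) /
    (q * (q - 1))
  h2 <- 1 - dbar / (2 * fit$sigma2_u)
  min(max(h2, 0), 1)
}
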