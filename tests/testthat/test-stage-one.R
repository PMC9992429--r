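# Build a single-trial plot table by hand.
toy_trial <- function(lines, reps, yields, design = "RCBD",
                      year = 2020, loc = "A") {
  tibble::tibble(line = lines, trial = paste(year, loc, sep = "_"),
                 year = year, location = loc, design = design,
                 rep = reps, row = NA_integer_, col = NA_integer_,
                 block = paste0("rep", reps), yield_t_ha = yields)
}

rcbd_sim <- function(seed, n_lines = 20, reps = 3, block_sd = 0,
                     err_sd = 0.3, gvals = NULL) {
  withr::with_seed(seed, {
    g <- gvals %||% rnorm(n_lines, 5, 0.5)
    b <- rnorm(reps, 0, block_sd)
    df <- expand.grid(line = sprintf("L%02d", seq_len(n_lines)),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
    toy_trial(df$line, df$rep,
              g[match(df$line, sprintf("L%02d", seq_len(n_lines)))] +
                b[df$rep] + rnorm(nrow(df), 0, err_sd))
  })
}

test_that("BIC picks replicate blocking when block effects are strong", {
  picks <- vapply(1:100, function(s) {
    tr <- rcbd_sim(s, n_lines = 15, reps = 3, block_sd = 0.9, err_sd = 0.3)
    sel <- select_blocking_model(tr)
    length(sel$blocking) > 0
  }, logical(1))
  expect_gte(mean(picks), 0.95)
})

test_that("BIC prefers no blocking when block effects are absent", {
  picks <- vapply(1:100, function(s) {
    tr <- rcbd_sim(s + 500, n_lines = 20, reps = 3, block_sd = 0,
                   err_sd = 0.3)
    sel <- select_blocking_model(tr)
    length(sel$blocking) == 0
  }, logical(1))
  expect_gt(mean(picks), 0.5)
})

test_that("single-rep unblocked trials fall back to the genotype-means model", {
  tr <- rcbd_sim(1, n_lines = 10, reps = 1)
  sel <- select_blocking_model(tr)
  expect_length(sel$blocking, 0)
  expect_true("none" %in% c(sel$bic$blocking, sel$skipped))
})

test_that("row-column trials consider row, column and both", {
  pop <- sim_population(20, n_cross = 4, per_cross = 9, n_markers = 60)
  cfg <- sim_config(n_markers = 60, design = "row-column", reps = 2,
                    locations = "A", block_sd = 0.6, seed = 20)
  truth <- assign_effects_and_tbv(pop$geno, cfg)
  tr <- simulate_trials(truth, cfg, year = 2020, seed = 21)
  sel <- select_blocking_model(tr)
  expect_true(all(sel$bic$blocking %in%
                    c("none", "row", "col", "row+col")))
  expect_gte(nrow(sel$bic), 2)
})

test_that("balanced RCBD with additive blocks returns plain line means", {
  # orthogonality: blocks cannot bias genotype BLUEs in a complete design
  tr <- rcbd_sim(3, n_lines = 12, reps = 3, block_sd = 0.8, err_sd = 0.4)
  blues <- fit_stage_one(tr, blocking = "block")
  means <- tapply(tr$yield_t_ha, tr$line, mean)
  expect_equal(blues$blue, as.numeric(means[blues$line]), tolerance = 1e-10)

  # noise-free: BLUE equals the genetic value exactly
  g <- seq(4, 6, length.out = 8)
  tr0 <- rcbd_sim(4, n_lines = 8, reps = 2, block_sd = 0, err_sd = 0,
                  gvals = g)
  blues0 <- suppressWarnings(fit_stage_one(tr0, blocking = character(0)))
  expect_equal(sort(blues0$blue), sort(g), tolerance = 1e-12)
})

test_that("3-line x 2-rep toy matches the hand least-squares solution", {
  # y_ij = mu_i + b_j + e; contr.sum blocks. Hand normal equations for
  # lines A,B,C with reps 1,2:
  y <- c(5.0, 5.6, 4.8, 5.4, 6.0, 5.0)   # A1 B1 C1 A2 B2 C2
  tr <- toy_trial(rep(c("A", "B", "C"), 2), rep(1:2, each = 3), y)
  blues <- fit_stage_one(tr, blocking = "block")
  # balanced: adjusted mean = line mean; block effect +/- 0.1666...
  expect_equal(blues$blue[blues$line == "A"], mean(y[c(1, 4)]),
               tolerance = 1e-12)
  expect_equal(blues$blue[blues$line == "B"], mean(y[c(2, 5)]),
               tolerance = 1e-12)
  # SE from hand-computed residual MS: fit has df = 6 - 4 = 2
  fitlm <- lm(y ~ 0 + line + block, data = dplyr::mutate(
    tr, line = factor(line), block = factor(block)),
    contrasts = list(block = "contr.sum"))
  expect_equal(blues$se[blues$line == "A"],
               sqrt(diag(vcov(fitlm))[["lineA"]]), tolerance = 1e-12)
})

test_that("BLUE standard errors shrink as 1/sqrt(reps)", {
  ses <- vapply(c(2, 4, 8), function(r) {
    tr <- rcbd_sim(6, n_lines = 10, reps = r, block_sd = 0, err_sd = 0.5)
    mean(fit_stage_one(tr, blocking = character(0))$se)
  }, numeric(1))
  expect_equal(ses[1] / ses[2], sqrt(2), tolerance = 0.25)
  expect_equal(ses[2] / ses[3], sqrt(2), tolerance = 0.25)
})

test_that("augmented designs adjust unreplicated entries via check-borne blocks", {
  # two blocks with a known offset; checks reveal it, tests get corrected
  withr::with_seed(9, {
    checks <- c("CHK1", "CHK2")
    tests <- sprintf("T%02d", 1:10)
    gc <- c(CHK1 = 5, CHK2 = 5.5)
    gt <- setNames(rnorm(10, 5.2, 0.4), tests)
    blk_eff <- c(blk1 = 0.8, blk2 = -0.8)
    rows <- dplyr::bind_rows(
      tibble::tibble(line = rep(checks, 2),
                     block = rep(names(blk_eff), each = 2)),
      tibble::tibble(line = tests,
                     block = rep(names(blk_eff), each = 5)))
    g_all <- c(gc, gt)
    rows$yield_t_ha <- g_all[rows$line] + blk_eff[rows$block]
    tr <- tibble::tibble(line = rows$line, trial = "t", year = 2020,
                         location = "A", design = "augmented",
                         rep = NA_integer_, row = NA_integer_,
                         col = NA_integer_, block = rows$block,
                         yield_t_ha = rows$yield_t_ha)
    blues <- suppressWarnings(fit_stage_one(tr, blocking = "block"))
    expect_equal(blues$blue[match(tests, blues$line)], unname(gt),
                 tolerance = 1e-10)
  })
})

test_that("Cullis heritability hits its limits and the balanced expectation", {
  pop <- sim_population(22, n_cross = 8, per_cross = 10, n_markers = 200)

  # noise-free limit
  cfg1 <- sim_config(n_markers = 200, heritability_plot = 1 - 1e-9,
                     gxe_ratio = 0, loc_sd = 0, block_sd = 0,
                     locations = "A", reps = 2, seed = 22)
  truth1 <- assign_effects_and_tbv(pop$geno, cfg1)
  tr1 <- simulate_trials(truth1, cfg1, year = 2020, seed = 1)
  expect_gte(estimate_trial_heritability(tr1, blocking = character(0)), 0.99)

  # no genetic signal
  cfg0 <- sim_config(n_markers = 200, heritability_plot = 0,
                     gxe_ratio = 0, loc_sd = 0, block_sd = 0,
                     locations = "A", reps = 2, seed = 22)
  truth0 <- assign_effects_and_tbv(pop$geno, cfg0)
  tr0 <- simulate_trials(truth0, cfg0, year = 2020, seed = 2)
  h0 <- estimate_trial_heritability(tr0, blocking = character(0))
  expect_lte(h0, 0.2)

  # plot h2 = 0.5 with 3 reps: line-mean expectation 3*0.5/(1+2*0.5) = 0.75
  cfg5 <- sim_config(n_markers = 200, heritability_plot = 0.5,
                     gxe_ratio = 0, loc_sd = 0, block_sd = 0,
                     locations = "A", reps = 3, seed = 22)
  truth5 <- assign_effects_and_tbv(pop$geno, cfg5)
  h2s <- vapply(1:20, function(s) {
    tr <- simulate_trials(truth5, cfg5, year = 2020, seed = s)
    estimate_trial_heritability(tr, blocking = character(0))
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.75), 0.1)
})

test_that("fit_trials runs per trial and reports model choices", {
  pop <- sim_population(23, n_cross = 5, per_cross = 8, n_markers = 80)
  cfg <- sim_config(n_markers = 80, locations = c("A", "B"), reps = 2,
                    seed = 23)
  truth <- assign_effects_and_tbv(pop$geno, cfg)
  tr <- simulate_trials(truth, cfg, year = 2020, seed = 3)
  out <- fit_trials(tr, heritability = TRUE)
  expect_equal(sort(unique(out$blues$trial)), sort(unique(tr$trial)))
  expect_equal(nrow(out$models), 2)
  expect_true(all(out$models$H2 >= 0 & out$models$H2 <= 1))
  expect_true(all(out$blues$se > 0))
})
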