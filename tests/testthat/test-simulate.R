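test_that("founder simulation honours dimensions, seed determinism and MAF", {
  cfg <- sim_config(n_founders = 20, n_markers = 200, seed = 1)
  f1 <- simulate_founders(cfg)
  expect_equal(dim(f1), c(20, 200))
  f2 <- simulate_founders(cfg)
  expect_identical(unclass(f1), unclass(f2))
  # degenerate maf_range: frequencies pile up at 0.5 within binomial error
  freqs <- vapply(1:50, function(s) {
    cfg5 <- sim_config(n_founders = 20, n_markers = 200,
                       maf_range = c(0.5, 0.5), seed = s)
    mean(simulate_founders(cfg5)) / 2
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 0.5), 0.02)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_config(heritability_plot = 1.2), "heritability_plot")
  expect_error(sim_config(n_qtl = 900, n_markers = 800), "n_qtl")
  expect_error(sim_config(design = "latin-square"), "design")
  expect_error(sim_config(n_parents_recycled = 1), "n_parents_recycled")
})

test_that("selfing decays heterozygosity as (1/2)^g from a fully het F1", {
  cfg <- sim_config(n_markers = 200, n_chromosomes = 4, seed = 2)
  f <- simulate_founders(cfg)
  # force opposite homozygotes so the F1 is heterozygous everywhere
  calls <- unclass(f)
  calls["F001", ] <- 0L
  calls["F002", ] <- 2L
  f <- marker_matrix(calls, map = attr(f, "map"))

  fam0 <- derive_inbred_family(f, "F001", "F002", n_lines = 30,
                               selfing_generations = 0, seed = 3)
  expect_true(all(fam0$genotypes == 1L))

  fam6 <- derive_inbred_family(f, "F001", "F002", n_lines = 500,
                               selfing_generations = 6, seed = 4)
  het <- mean(fam6$genotypes == 1L)
  p <- 0.5^6
  se3 <- 3 * sqrt(p * (1 - p) / length(fam6$genotypes))
  # loci on one chromosome are linked, so allow a generous multiple of the
  # independent-binomial SE
  expect_lt(abs(het - p), 10 * se3)
  expect_equal(fam6$pedigree$parent1[1], "F001")
})

test_that("monomorphic parental loci stay monomorphic in offspring", {
  cfg <- sim_config(n_markers = 100, seed = 5)
  f <- simulate_founders(cfg)
  fam <- derive_inbred_family(f, "F001", "F002", n_lines = 50, seed = 6)
  same <- which(f["F001", ] == f["F002", ])
  for (j in head(same, 10)) {
    expect_true(all(fam$genotypes[, j] == f["F001", j]))
  }
  expect_error(derive_inbred_family(f, "F001", "NOPE", 5), "parents")
})

test_that("true breeding values satisfy the dosage-times-effect identity", {
  pop <- sim_population(7, n_cross = 5, per_cross = 10, n_markers = 200)
  truth <- assign_effects_and_tbv(pop$geno, pop$config)
  eff <- truth$effects$effect
  recomputed <- as.numeric(unclass(pop$geno) %*% eff)
  expect_equal(truth$tbv$tbv, recomputed, tolerance = 1e-12)
  # effects are rescaled so the sample variance of TBV is exactly var_g
  expect_equal(stats::var(truth$tbv$tbv), pop$config$var_g,
               tolerance = 1e-10)
})

test_that("zero heritability gives flat truth; n_qtl = 0 with h2 > 0 errors", {
  pop <- sim_population(8, n_cross = 3, per_cross = 5, n_markers = 100)
  cfg0 <- sim_config(n_markers = 100, heritability_plot = 0, seed = 8)
  truth <- assign_effects_and_tbv(pop$geno, cfg0)
  expect_true(all(truth$tbv$tbv == 0))
  expect_true(all(truth$effects$effect == 0))
  cfg_bad <- sim_config(n_markers = 100, n_qtl = 0,
                        heritability_plot = 0.5, seed = 8)
  expect_error(assign_effects_and_tbv(pop$geno, cfg_bad), "n_qtl")
})

test_that("realised plot-level heritability matches the configured value", {
  pop <- sim_population(9, n_cross = 25, per_cross = 20, n_markers = 300)
  cfg <- sim_config(n_markers = 300, heritability_plot = 0.5,
                    locations = "siteA", reps = 1, gxe_ratio = 0,
                    loc_sd = 0, block_sd = 0, seed = 9)
  truth <- assign_effects_and_tbv(pop$geno, cfg)
  ratios <- vapply(1:20, function(s) {
    tr <- simulate_trials(truth, cfg, year = 2020, seed = s)
    merged <- dplyr::left_join(tr, truth$tbv, by = "line")
    err <- merged$yield_t_ha - cfg$grand_mean - merged$tbv
    var(merged$tbv) / (var(merged$tbv) + var(err))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})

test_that("trial tables have the promised structure and noise-free limit", {
  pop <- sim_population(10, n_cross = 5, per_cross = 10, n_markers = 100)
  cfg <- sim_config(n_markers = 100, locations = c("A", "B"), reps = 3,
                    seed = 10)
  truth <- assign_effects_and_tbv(pop$geno, cfg)
  tr <- simulate_trials(truth, cfg, year = 2021, seed = 2)
  expect_equal(nrow(tr), 50 * 3 * 2)
  expect_setequal(unique(tr$location), c("A", "B"))

  # noise-free: zero error, location, blocks and GxE
  cfg0 <- sim_config(n_markers = 100, heritability_plot = 1 - 1e-12,
                     gxe_ratio = 0, loc_sd = 0, block_sd = 0,
                     locations = "A", reps = 1, seed = 10)
  truth0 <- assign_effects_and_tbv(pop$geno, cfg0)
  tr0 <- simulate_trials(truth0, cfg0, year = 2021, seed = 3)
  merged <- dplyr::left_join(tr0, truth0$tbv, by = "line")
  expect_equal(merged$yield_t_ha, cfg0$grand_mean + merged$tbv,
               tolerance = 1e-5)

  # pooled within-line error variance tracks the configured value
  cfgv <- sim_config(n_markers = 100, heritability_plot = 0.5,
                     var_g = 0.25, gxe_ratio = 0, loc_sd = 0, block_sd = 0,
                     locations = "A", reps = 8, seed = 10)
  truthv <- assign_effects_and_tbv(pop$geno, cfgv)
  vars <- vapply(1:20, function(s) {
    trv <- simulate_trials(truthv, cfgv, year = 2021, seed = s)
    mean(tapply(trv$yield_t_ha, trv$line, var))
  }, numeric(1))
  expect_lt(abs(mean(vars) - 0.25) / 0.25, 0.10)
})

test_that("augmented design replicates checks and not test entries", {
  pop <- sim_population(11, n_cross = 4, per_cross = 10, n_markers = 100)
  cfg <- sim_config(n_markers = 100, design = "augmented", reps = 4,
                    n_checks = 3, locations = "A", seed = 11)
  truth <- assign_effects_and_tbv(pop$geno, cfg)
  checks <- rownames(pop$geno)[1:3]
  tr <- simulate_trials(truth, cfg, year = 2020, check_lines = checks,
                        seed = 4)
  counts <- table(tr$line)
  expect_true(all(counts[checks] == 4))
  expect_true(all(counts[setdiff(names(counts), checks)] == 1))
})

test_that("recurrent program responds to selection and not to noise", {
  cfg <- sim_config(n_founders = 20, n_markers = 200, n_chromosomes = 6,
                    n_crosses_per_cycle = 10, lines_per_cross = 10,
                    n_cycles = 2, locations = "A", reps = 2,
                    n_parents_recycled = 5, seed = 1)
  prog <- run_recurrent_program(cfg, select_method = "gebv")
  expect_equal(nrow(prog$cycle_means), 2)
  expect_equal(nrow(prog$cycles[[1]]$genotypes), 100)

  # determinism
  prog2 <- run_recurrent_program(cfg, select_method = "gebv")
  expect_equal(prog$cycle_means, prog2$cycle_means)

  # random selection: no systematic trend (20-seed average near 0)
  deltas <- vapply(1:10, function(s) {
    cfg_s <- sim_config(n_founders = 20, n_markers = 150, n_chromosomes = 6,
                        n_crosses_per_cycle = 8, lines_per_cross = 8,
                        n_cycles = 2, locations = "A", reps = 2,
                        n_parents_recycled = 5, seed = s)
    cm <- run_recurrent_program(cfg_s, select_method = "random")$cycle_means
    diff(cm$mean_tbv)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(length(deltas)) + 0.05)
})

test_that("era program programs the trend it promises", {
  cfg <- sim_config(n_markers = 300, seed = 3, locations = c("A", "B"))
  era <- simulate_era_program(cfg, trend = 0.3, n_years = 4,
                              lines_per_year = 300, seed = 3)
  slope <- coef(lm(mean_tbv ~ year, data = era$cohort_means))[2]
  expect_lt(abs(slope - 0.3), 0.08)
  # checks appear every year
  check_years <- era$trials |>
    dplyr::filter(.data$line %in% era$checks) |>
    dplyr::distinct(.data$year)
  expect_equal(nrow(check_years), 4)
  # truth identity holds for the era genotypes too
  eff <- era$truth$effects$effect
  expect_equal(era$truth$tbv$tbv,
               as.numeric(unclass(era$genotypes) %*% eff), tolerance = 1e-12)
})

test_that("genotype io round-trips through CSV and VCF", {
  pop <- sim_population(12, n_cross = 2, per_cross = 5, n_markers = 40,
                        het = 0.05)
  m <- inject_missing(pop$geno, 0.05, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_marker_matrix(m, csv)
  back <- read_marker_matrix(csv)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_marker_vcf(m, vcf)
  back2 <- read_marker_vcf(vcf)
  expect_equal(unclass(back2)[rownames(m), colnames(m)], unclass(m),
               ignore_attr = TRUE)
})
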