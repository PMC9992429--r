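test_that("lines with identical dosages get identical GEBVs", {
  geno <- sim_cohort(1, n = 40, m = 60)
  calls <- unclass(geno)
  calls[2, ] <- calls[1, ]
  geno <- marker_matrix(calls)
  d <- encode_dosage(geno)
  ph <- sim_pheno(geno, seed = 2, h2 = 0.5)
  fit <- compute_gebv(d, ph$pheno)
  expect_equal(fit$gebv$gebv[1], fit$gebv$gebv[2], tolerance = 1e-10)
})

test_that("GEBVs of the training set are centred under an intercept model", {
  geno <- sim_cohort(3, n = 80, m = 100)
  d <- encode_dosage(geno)
  ph <- sim_pheno(geno, seed = 4, h2 = 0.5)
  fit <- compute_gebv(d, ph$pheno)
  expect_lt(abs(mean(fit$gebv$gebv)), 0.05)
})

test_that("no heritable signal means no recovered signal", {
  rs <- vapply(1:20, function(s) {
    geno <- sim_cohort(s + 300, n = 300, m = 200)
    ph0 <- sim_pheno(geno, seed = s + 400, h2 = 0.5)
    # permuted phenotype destroys the genotype-phenotype link
    ph <- ph0$pheno
    ph$value <- withr::with_seed(s, sample(ph$value))
    fit <- compute_gebv(encode_dosage(geno), ph)
    cor(fit$gebv$gebv, ph0$tbv$tbv)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("simulated h2 = 0.5 yields strong TBV recovery", {
  rs <- vapply(1:5, function(s) {
    geno <- sim_cohort(s + 500, n = 500, m = 800)
    ph <- sim_pheno(geno, seed = s + 600, h2 = 0.5, n_qtl = 200)
    fit <- compute_gebv(encode_dosage(geno), ph$pheno)
    cor(fit$gebv$gebv, ph$tbv$tbv)
  }, numeric(1))
  expect_gt(mean(rs), 0.5)
})

test_that("constant phenotypes are flagged degenerate with zero GEBVs", {
  geno <- sim_cohort(7, n = 30, m = 40)
  d <- encode_dosage(geno)
  ph <- tibble::tibble(line = rownames(d), value = 5)
  expect_warning(fit <- compute_gebv(d, ph), "degenerate|Constant")
  expect_true(all(fit$gebv$gebv == 0))
  expect_true(fit$degenerate)
})

test_that("phenotyped lines must be genotyped", {
  geno <- sim_cohort(8, n = 20, m = 40)
  d <- encode_dosage(geno)
  ph <- tibble::tibble(line = c(rownames(d)[1:5], "GHOST"), value = rnorm(6))
  expect_error(compute_gebv(d, ph), "GHOST")
})

test_that("self-prediction reproduces the fitted GEBVs", {
  geno <- sim_cohort(9, n = 50, m = 120)
  d <- encode_dosage(geno)
  ph <- sim_pheno(geno, seed = 10, h2 = 0.5)
  direct <- compute_gebv(d, ph$pheno)
  pred <- predict_unphenotyped(d, ph$pheno, d, min_overlap = 100)
  expect_equal(pred$gebv, direct$gebv$gebv, tolerance = 1e-10)
  expect_equal(attr(pred, "marker_overlap"), 120)
})

test_that("training on parents predicts unphenotyped progeny", {
  # ~40 phenotyped parents, 500 unphenotyped progeny
  rs <- vapply(1:10, function(s) {
    pop <- sim_population(s + 40, n_founders = 40, n_markers = 300,
                          n_cross = 20, per_cross = 25)
    cfg <- pop$config
    truth <- assign_effects_and_tbv(pop$geno, sim_config(
      n_markers = 300, heritability_plot = 0.5, seed = s + 40))
    # parent phenotypes: TBV + noise at line-mean h2 ~ 0.5
    par_tbv <- compute_tbv(pop$founders, truth)
    ph <- withr::with_seed(s, tibble::tibble(
      line = par_tbv$line,
      value = par_tbv$tbv + rnorm(nrow(par_tbv), 0, sqrt(0.25))))
    dp <- encode_dosage(pop$founders)
    dt <- encode_dosage(pop$geno)
    pred <- predict_unphenotyped(dp, ph, dt)
    prog_tbv <- truth$tbv
    cor(pred$gebv, prog_tbv$tbv[match(pred$line, prog_tbv$line)])
  }, numeric(1))
  expect_gt(mean(rs), 0.2)
})

test_that("insufficient marker overlap is refused with a report", {
  g1 <- sim_cohort(11, n = 20, m = 30)
  g2 <- sim_cohort(12, n = 20, m = 30)
  colnames(g2) <- paste0("X", colnames(g2))
  d1 <- encode_dosage(g1); d2 <- encode_dosage(marker_matrix(unclass(g2)))
  ph <- tibble::tibble(line = rownames(d1), value = rnorm(20))
  expect_error(predict_unphenotyped(d1, ph, d2, min_overlap = 10),
               "overlap")
})

test_that("prediction accuracy is plain Pearson correlation with guards", {
  gb <- tibble::tibble(line = paste0("L", 1:5),
                       gebv = c(0.3, -0.2, 0.8, 0.1, -0.5))
  obs <- tibble::tibble(line = paste0("L", 1:5), value = gb$gebv)
  expect_equal(prediction_accuracy(gb, obs), 1.0)
  obs$value <- -gb$gebv
  expect_equal(prediction_accuracy(gb, obs), -1.0)
  # 5-pair hand computation
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 1.9, 3.4, 3.0, 4.8)
  hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  expect_equal(prediction_accuracy(
    tibble::tibble(line = paste0("L", 1:5), gebv = x),
    tibble::tibble(line = paste0("L", 1:5), value = y)), hand,
    tolerance = 1e-12)
  obs$value <- 1
  expect_error(prediction_accuracy(gb, obs), "constant")
  expect_error(prediction_accuracy(gb[1:2, ],
                                   dplyr::rename(gb[1:2, ],
                                                 value = gebv)), "3 shared")
})

test_that("relative efficiency follows its convention and inverts cleanly", {
  expect_equal(relative_efficiency(1, 1, "h2")$rec, 1)
  expect_equal(relative_efficiency(1, 1, "sqrt_h2")$rec, 1)
  expect_equal(relative_efficiency(0.5, 0.25, "h2")$rec, 2.0)
  expect_equal(relative_efficiency(0.5, 0.25, "sqrt_h2")$rec, 1.0)
  # the observed accuracy/efficiency pairing 0.701 / 2.623 round-trips
  H2 <- 0.701 / 2.623
  expect_equal(relative_efficiency(0.701, H2, "h2")$rec, 2.623,
               tolerance = 1e-12)
  expect_error(relative_efficiency(0.5, 0), "H2")
  expect_error(relative_efficiency(1.5, 0.5), "`r`")
})

test_that("parent selection ranks by GEBV with deterministic tie-breaks", {
  gb <- tibble::tibble(line = c("B", "A", "C", "D"),
                       gebv = c(1.0, 1.0, 2.0, -1.0))
  top <- select_parents(gb, 3)
  expect_equal(top$line, c("C", "A", "B"))   # tie at 1.0 broken by id
  expect_equal(select_parents(gb, 4)$line, c("C", "A", "B", "D"))
  expect_error(select_parents(gb, 0), "k")
  expect_error(select_parents(gb, 9), "exceeds")

  # truncation selection on GEBV raises the mean TBV of the selected set
  diffs <- vapply(1:10, function(s) {
    geno <- sim_cohort(s + 700, n = 200, m = 200)
    ph <- sim_pheno(geno, seed = s + 800, h2 = 0.5)
    fit <- compute_gebv(encode_dosage(geno), ph$pheno)
    sel <- select_parents(fit, 20)
    mean(ph$tbv$tbv[match(sel$line, ph$tbv$line)]) - mean(ph$tbv$tbv)
  }, numeric(1))
  expect_true(all(diffs > 0))
})
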