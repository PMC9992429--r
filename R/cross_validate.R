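#' Cross-validation over training-population fractions
#'
#' Random-sampling cross-validation of genomic prediction accuracy: at each
#' training fraction, `n_iter` times, `floor(fraction * n)` lines are drawn
#' without replacement as the training population, marker effects are fitted
#' on them, the remaining lines are predicted, and accuracy is recorded as
#' the Pearson correlation of GEBV with the observed value on the held-out
#' lines. Fraction 1.0 is supported as fit-to-all self-accuracy (train =
#' validate = all lines) and is flagged optimistic in the output — it mirrors
#' the 100% point of a training-size optimisation curve.
#'
#' Each iteration gets a counter-derived sub-seed, so any single iteration
#' can be reproduced independently and the whole result is deterministic
#' given `seed`.
#'
#' @param dosage A `dosage_matrix`.
#' @param pheno Tibble `line`/`value`, one observed value per line.
#' @param fractions Training-population fractions in (0, 1\]; the defaults
#'   are the classic 20-80% ladder.
#' @param n_iter Iterations per fraction (default 500).
#' @param seed Integer seed.
#' @return An object of class `cv_result`: a tibble with `fraction`,
#'   `n_train`, `mean_r`, `sd_r`, `n_iter`, `self_accuracy` flag, plus an
#'   `iterations` attribute holding every per-iteration accuracy.
#' @export
cross_validate <- function(dosage, pheno,
                           fractions = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8),
                           n_iter = 500, seed = 1) {
  pheno <- as_tibble(pheno)
  pheno <- pheno[pheno$line %in% rownames(dosage), ]
  n <- nrow(pheno)
  if (any(fractions <= 0 | fractions > 1)) {
    abort("Parameter error: fractions must lie in (0, 1].")
  }
  check_range(n_iter, "n_iter", 1, Inf, integer = TRUE)
  M <- as.matrix(dosage)[pheno$line, , drop = FALSE]
  y <- pheno$value

  res <- list(); iters <- list()
  for (f in fractions) {
    n_train <- floor(f * n)
    if (f < 1 && n - n_train < 3) {
      abort(sprintf(
        "Fraction %.2f leaves %d validation lines; need at least 3.",
        f, n - n_train))
    }
    if (f == 1) {
      gfit <- reml_solve(y, Z = M, compute_pev = "none")
      r <- safe_cor(as.numeric(M %*% gfit$u), y, "self-prediction vectors")
      res[[length(res) + 1]] <- tibble(
        fraction = f, n_train = n, mean_r = r, sd_r = 0, n_iter = 1L,
        self_accuracy = TRUE)
      iters[[length(iters) + 1]] <- tibble(fraction = f, iter = 1L, r = r)
      next
    }
    rs <- vapply(seq_len(n_iter), function(it) {
      with_seed(derive_seed(seed, sprintf("cv_f%s_i%d", f, it)), {
        tr <- sample.int(n, n_train)
        fit <- reml_solve(y[tr], Z = M[tr, , drop = FALSE],
                          compute_pev = "none")
        pred <- as.numeric(M[-tr, , drop = FALSE] %*% fit$u)
        obs <- y[-tr]
        if (sd(pred) < 1e-12 || sd(obs) < 1e-12) return(NA_real_)
        cor(pred, obs)
      })
    }, numeric(1))
    res[[length(res) + 1]] <- tibble(
      fraction = f, n_train = n_train, mean_r = mean(rs, na.rm = TRUE),
      sd_r = sd(rs, na.rm = TRUE), n_iter = n_iter, self_accuracy = FALSE)
    iters[[length(iters) + 1]] <- tibble(fraction = f,
                                         iter = seq_len(n_iter), r = rs)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "iterations") <- dplyr::bind_rows(iters)
  attr(out, "seed") <- seed
  class(out) <- c("cv_result", class(out))
  out
}

#' Plot a training-size optimisation curve
#'
#' Mean accuracy against training-population fraction with +/- 1 SD ribbon;
#' a self-accuracy point (fraction 1.0) is drawn distinctly because it is
#' optimistic.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                      ymax = .data$mean_r + .data$sd_r),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$self_accuracy),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Training population fraction",
                  y = "Prediction accuracy (r)",
                  title = "Training-population size optimisation") +
    ggplot2::theme_minimal()
}
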