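#' Filter lines by heterozygosity
#'
#' Drops lines whose proportion of heterozygous calls among their
#' *non-missing* calls is strictly greater than `het_max`. In inbred-line
#' programs (F7-F9 material) high residual heterozygosity indicates seed or
#' DNA contamination. A line at exactly the threshold is retained.
#'
#' @param m A [marker_matrix()].
#' @param het_max Maximum tolerated heterozygous proportion (default 0.15).
#' @return A filtered [marker_matrix()], survivor order preserved, with a
#'   `qc_report` attribute (tibble: entity, id, metric, value, action).
#' @export
filter_individuals <- function(m, het_max = 0.15) {
  check_range(het_max, "het_max", 0, 1)
  if (nrow(m) == 0 || ncol(m) == 0) abort("Input error: empty marker matrix.")
  het <- rowMeans(m == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0   # all-missing line: no zygosity information
  drop <- het > het_max
  report <- tibble(entity = "line", id = rownames(m),
                   metric = "het_rate", value = unname(het),
                   action = ifelse(drop, "removed", "kept"))
  out <- subset_markers(m, lines = rownames(m)[!drop])
  attr(out, "qc_report") <- report
  out
}

#' Filter markers by missingness and minor allele frequency
#'
#' Drops markers missing in strictly more than `miss_max` of lines, and
#' markers whose minor allele frequency is strictly below `maf_min`. MAF is
#' computed from non-missing calls, heterozygotes contributing one copy of
#' each allele. Markers exactly at either threshold are retained.
#'
#' @param m A [marker_matrix()].
#' @param miss_max Maximum tolerated missing proportion (default 0.15).
#' @param maf_min Minimum tolerated minor allele frequency (default 0.05).
#' @return A filtered [marker_matrix()] with a `qc_report` attribute.
#' @export
filter_markers <- function(m, miss_max = 0.15, maf_min = 0.05) {
  check_range(miss_max, "miss_max", 0, 1)
  check_range(maf_min, "maf_min", 0, 1)
  if (nrow(m) == 0 || ncol(m) == 0) abort("Input error: empty marker matrix.")
  miss <- colMeans(is.na(m))
  n_obs <- colSums(!is.na(m))
  p_alt <- colSums(m, na.rm = TRUE) / (2 * pmax(n_obs, 1))
  maf <- pmin(p_alt, 1 - p_alt)
  maf[n_obs == 0] <- 0
  drop <- miss > miss_max | maf < maf_min
  if (all(drop)) abort("No markers survive QC.")
  report <- dplyr::bind_rows(
    tibble(entity = "marker", id = colnames(m), metric = "missing_rate",
           value = unname(miss),
           action = ifelse(miss > miss_max, "removed", "kept")),
    tibble(entity = "marker", id = colnames(m), metric = "maf",
           value = unname(maf),
           action = ifelse(maf < maf_min, "removed", "kept")))
  out <- subset_markers(m, markers = colnames(m)[!drop])
  attr(out, "qc_report") <- report
  out
}

#' Run the full genotype QC chain
#'
#' Applies [filter_individuals()] then [filter_markers()] — lines first, in
#' that order, because the marker statistics depend on which lines remain.
#'
#' @inheritParams filter_individuals
#' @inheritParams filter_markers
#' @return A list with `genotypes` (filtered [marker_matrix()]) and `report`
#'   (combined QC tibble).
#' @export
qc_genotypes <- function(m, het_max = 0.15, miss_max = 0.15, maf_min = 0.05) {
  m1 <- filter_individuals(m, het_max = het_max)
  r1 <- attr(m1, "qc_report")
  m2 <- filter_markers(m1, miss_max = miss_max, maf_min = maf_min)
  r2 <- attr(m2, "qc_report")
  attr(m2, "qc_report") <- NULL
  list(genotypes = m2, report = dplyr::bind_rows(r1, r2))
}

#' Encode calls as centred dosages
#'
#' Recodes homozygous-reference as -1, heterozygous as 0 and homozygous-
#' alternate as +1, then imputes missing cells with the per-marker mean of
#' observed codes (so imputed values may be fractional). The heterozygote-
#' centred \{-1, 0, +1\} coding is the conventional input to ridge-regression
#' BLUP; the centring constant does not change GEBV contrasts.
#'
#' @param m A QC-filtered [marker_matrix()].
#' @return A numeric `dosage_matrix` (lines x markers, values in \[-1, 1\])
#'   with attributes `allele_freq` (alternate-allele frequency per marker)
#'   and `monomorphic` (logical; constant surviving columns, flagged).
#' @export
encode_dosage <- function(m) {
  if (any(colSums(!is.na(m)) == 0)) {
    abort(paste("Marker(s) with all calls missing; run filter_markers()",
                "before encoding."))
  }
  d <- unclass(m) - 1
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx) > 0) d[na_idx] <- mu[na_idx[, 2]]
  freq <- (mu + 1) / 2
  mono <- apply(d, 2, function(x) max(x) - min(x) < 1e-12)
  if (any(mono)) {
    inform(sprintf("%d monomorphic marker(s) after QC: %s", sum(mono),
                   paste(head(colnames(m)[mono], 5), collapse = ", ")))
  }
  structure(d, allele_freq = setNames(freq, colnames(m)),
            monomorphic = setNames(mono, colnames(m)),
            class = c("dosage_matrix", "matrix", "array"))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d lines x %d markers, codes in [-1, 1]\n",
              nrow(x), ncol(x)))
  invisible(x)
}
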