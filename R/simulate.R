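#' Configuration for the breeding-program simulator
#'
#' Collects and validates every knob of the synthetic breeding program:
#' founder panel, genetic map, trait architecture, line development
#' (biparental crosses advanced by repeated selfing, emulating rapid
#' generation advance to F7), multi-year multi-location yield trials, and
#' parent recycling. Defaults emulate an irrigated rice program genotyped on
#' a ~1k SNP panel: 12 chromosomes, inbred founders, plot yields around
#' 5.5 t/ha with genetic standard deviation 0.5 t/ha.
#'
#' @param n_founders Number of founder lines.
#' @param n_markers Total SNP markers on the panel.
#' @param n_chromosomes Chromosomes in the genetic map.
#' @param chrom_length_morgans Map length per chromosome (Morgans).
#' @param maf_range Founder allele-frequency range, within (0, 0.5].
#' @param n_qtl Markers carrying additive effects (must be <= n_markers;
#'   default: 200 or `n_markers`, whichever is smaller).
#' @param heritability_plot Plot-level heritability
#'   \eqn{\sigma^2_g/(\sigma^2_g + \sigma^2_e)}, in \[0, 1\].
#' @param var_g Target genetic variance among lines, (t/ha)^2.
#' @param gxe_ratio Line-by-location interaction variance as a fraction of
#'   `var_g`.
#' @param loc_sd,block_sd SD of location and blocking-factor effects (t/ha).
#' @param grand_mean Overall trial mean yield (t/ha).
#' @param n_crosses_per_cycle,lines_per_cross Crossing-block size.
#' @param selfing_generations Selfing generations after the F1 (default 6,
#'   emulating F7 material).
#' @param residual_het_rate Probability a homozygous cell is observed
#'   heterozygous (imperfect fixation), in \[0, 1\].
#' @param missing_rate Probability a call is missing, in \[0, 1\].
#' @param n_cycles Breeding cycles for [run_recurrent_program()].
#' @param years Calendar years, one per cycle (default 2019 onward).
#' @param locations Trial location labels.
#' @param design Trial design: `"RCBD"`, `"row-column"` or `"augmented"`.
#' @param reps Replicates (RCBD/row-column) or blocks (augmented).
#' @param n_checks Check varieties replicated in augmented designs.
#' @param n_parents_recycled Top-GEBV parents recycled each cycle (>= 2).
#' @param seed Integer seed making the whole program reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 40, n_markers = 800, n_chromosomes = 12,
                       chrom_length_morgans = 1.5, maf_range = c(0.1, 0.5),
                       n_qtl = NULL, heritability_plot = 0.5, var_g = 0.25,
                       gxe_ratio = 0.1, loc_sd = 0.25, block_sd = 0.15,
                       grand_mean = 5.5, n_crosses_per_cycle = 20,
                       lines_per_cross = 10, selfing_generations = 6,
                       residual_het_rate = 0.02, missing_rate = 0.03,
                       n_cycles = 2, years = NULL,
                       locations = c("Cumilla", "Gazipur", "Habiganj",
                                     "Rangpur"),
                       design = "RCBD", reps = 2, n_checks = 5,
                       n_parents_recycled = 10, seed = 1) {
  check_range(n_founders, "n_founders", 2, Inf, integer = TRUE)
  check_range(n_markers, "n_markers", 1, Inf, integer = TRUE)
  check_range(n_chromosomes, "n_chromosomes", 1, Inf, integer = TRUE)
  check_range(chrom_length_morgans, "chrom_length_morgans", 1e-6, Inf)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (is.null(n_qtl)) n_qtl <- min(200L, n_markers)
  check_range(n_qtl, "n_qtl", 0, Inf, integer = TRUE)
  if (n_qtl > n_markers) abort("`n_qtl` must not exceed `n_markers`.")
  check_range(heritability_plot, "heritability_plot", 0, 1)
  check_range(var_g, "var_g", 1e-12, Inf)
  check_range(gxe_ratio, "gxe_ratio", 0, Inf)
  check_range(loc_sd, "loc_sd", 0, Inf)
  check_range(block_sd, "block_sd", 0, Inf)
  check_range(grand_mean, "grand_mean", 0, Inf)
  check_range(n_crosses_per_cycle, "n_crosses_per_cycle", 1, Inf, integer = TRUE)
  check_range(lines_per_cross, "lines_per_cross", 1, Inf, integer = TRUE)
  check_range(selfing_generations, "selfing_generations", 0, Inf, integer = TRUE)
  check_range(residual_het_rate, "residual_het_rate", 0, 1)
  check_range(missing_rate, "missing_rate", 0, 1)
  check_range(n_cycles, "n_cycles", 1, Inf, integer = TRUE)
  if (is.null(years)) years <- 2019 + seq_len(n_cycles) - 1
  if (length(years) < n_cycles) abort("`years` must cover every cycle.")
  if (length(locations) < 1) abort("`locations` must name at least one site.")
  if (!design %in% c("RCBD", "row-column", "augmented")) {
    abort(sprintf("Unknown `design` '%s' (use RCBD, row-column, augmented).",
                  design))
  }
  check_range(reps, "reps", 1, Inf, integer = TRUE)
  check_range(n_checks, "n_checks", 0, Inf, integer = TRUE)
  check_range(n_parents_recycled, "n_parents_recycled", 2, Inf, integer = TRUE)
  check_range(seed, "seed", integer = TRUE)
  structure(as.list(environment()), class = "sim_config")
}

# Evenly spaced genetic map for the configured genome.
make_map <- function(n_markers, n_chromosomes, chrom_length) {
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  tibble(
    marker = sprintf("M%04d", seq_len(n_markers)),
    chrom = rep(seq_len(n_chromosomes), per),
    pos = unlist(lapply(per, function(k) chrom_length * seq_len(k) / (k + 1)))
  )
}

#' Simulate founder genotypes
#'
#' Draws fully inbred founder lines: each marker gets an alternate-allele
#' frequency uniform in `maf_range`, and each founder is homozygous 0 or 2
#' with that probability. Markers are placed on an evenly spaced genetic map.
#'
#' @param config A [sim_config()].
#' @return A [marker_matrix()] of `n_founders` x `n_markers` with a map
#'   attribute and an `allele_freq` attribute (the drawn frequencies).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "founders"), {
    map <- make_map(config$n_markers, config$n_chromosomes,
                    config$chrom_length_morgans)
    p <- runif(config$n_markers, config$maf_range[1], config$maf_range[2])
    calls <- matrix(
      2L * rbinom(config$n_founders * config$n_markers, 1,
                  rep(p, each = config$n_founders)),
      nrow = config$n_founders,
      dimnames = list(sprintf("F%03d", seq_len(config$n_founders)),
                      map$marker))
    out <- marker_matrix(calls, map = map)
    attr(out, "allele_freq") <- setNames(p, map$marker)
    out
  })
}

# One gamete from a pair of haplotypes: crossover count per chromosome is
# Poisson with mean equal to map length in Morgans, positions uniform, no
# interference.
make_gamete <- function(h1, h2, map_split, chrom_len) {
  gam <- integer(length(h1))
  for (ch in seq_along(map_split)) {
    idx <- map_split[[ch]]$idx
    pos <- map_split[[ch]]$pos
    len <- chrom_len[ch]
    n_xo <- rpois(1, len)
    xo <- if (n_xo > 0) sort(runif(n_xo, 0, len)) else numeric(0)
    # segment parity: which parental haplotype at each position
    seg <- findInterval(pos, xo)
    from1 <- (seg + rbinom(1, 1, 0.5)) %% 2 == 0
    gam[idx] <- ifelse(from1, h1[idx], h2[idx])
  }
  gam
}

split_map <- function(map) {
  lapply(split(seq_len(nrow(map)), map$chrom),
         function(i) list(idx = i, pos = map$pos[i]))
}

# A genotype vector (0/1/2) split into two haplotypes; heterozygous loci get
# alleles assigned to haplotypes at random (phase unknown).
geno_to_haplos <- function(g) {
  h1 <- as.integer(g >= 1)
  h2 <- as.integer(g == 2)
  het <- which(g == 1L)
  if (length(het) > 0) {
    flip <- runif(length(het)) < 0.5
    h1[het] <- ifelse(flip, 1L, 0L)
    h2[het] <- 1L - h1[het]
  }
  list(h1, h2)
}

#' Derive an inbred family from a biparental cross
#'
#' Crosses two genotyped parents, then advances each derived line from the F1
#' by single-seed-descent selfing for `selfing_generations` meioses, emulating
#' rapid-generation-advance line fixation. Expected residual per-locus
#' heterozygosity after g selfing generations is \eqn{(1/2)^g} before the
#' `residual_het_rate` injection, which flips homozygous cells to
#' heterozygous with the given probability (imperfect fixation as seen in
#' real F7-F9 panels).
#'
#' @param parents A [marker_matrix()] containing both parents (with map).
#' @param p1,p2 Parent line ids.
#' @param n_lines Number of derived lines.
#' @param selfing_generations Selfing meioses after the F1.
#' @param seed Integer seed.
#' @param residual_het_rate Per-cell heterozygosity injection rate.
#' @param cross_id Label used in the pedigree (default `p1 x p2`).
#' @param prefix Prefix for derived line ids.
#'
#' @return A list with `genotypes` (a [marker_matrix()], complete calls) and
#'   `pedigree` (tibble: line, parent1, parent2, cross_id).
#' @export
derive_inbred_family <- function(parents, p1, p2, n_lines,
                                 selfing_generations = 6, seed = 1,
                                 residual_het_rate = 0,
                                 cross_id = NULL, prefix = NULL) {
  if (!all(c(p1, p2) %in% rownames(parents))) {
    abort("Dimension error: both parents must be rows of `parents`.")
  }
  map <- attr(parents, "map")
  if (is.null(map)) abort("`parents` must carry a genetic map.")
  check_range(n_lines, "n_lines", 1, Inf, integer = TRUE)
  check_range(selfing_generations, "selfing_generations", 0, Inf,
              integer = TRUE)
  cross_id <- cross_id %||% paste(p1, p2, sep = " x ")
  prefix <- prefix %||% gsub("[^A-Za-z0-9]", "", cross_id)
  ms <- split_map(map)
  # chromosome length: markers sit at L*k/(m+1), so recover L from the last
  chrom_len <- vapply(ms, function(s) max(s$pos) * (length(s$pos) + 1) /
                        length(s$pos), numeric(1))

  with_seed(seed, {
    hp1 <- geno_to_haplos(parents[p1, ])
    hp2 <- geno_to_haplos(parents[p2, ])
    lines <- matrix(0L, n_lines, ncol(parents),
                    dimnames = list(sprintf("%s_%03d", prefix, seq_len(n_lines)),
                                    colnames(parents)))
    for (i in seq_len(n_lines)) {
      # F1: one gamete from each parent
      h1 <- make_gamete(hp1[[1]], hp1[[2]], ms, chrom_len)
      h2 <- make_gamete(hp2[[1]], hp2[[2]], ms, chrom_len)
      for (g in seq_len(selfing_generations)) {
        n1 <- make_gamete(h1, h2, ms, chrom_len)
        n2 <- make_gamete(h1, h2, ms, chrom_len)
        h1 <- n1; h2 <- n2
      }
      lines[i, ] <- h1 + h2
    }
    if (residual_het_rate > 0) {
      hom <- lines != 1L
      flip <- hom & matrix(runif(length(lines)) < residual_het_rate,
                           nrow(lines))
      lines[flip] <- 1L
    }
    list(
      genotypes = marker_matrix(lines, map = map,
                                trait_marker = attr(parents, "trait_marker")),
      pedigree = tibble(line = rownames(lines), parent1 = p1, parent2 = p2,
                        cross_id = cross_id))
  })
}

#' Inject missing calls
#'
#' Masks a fraction of calls completely at random, emulating genotyping
#' dropout. Applied to the *observed* copy of a genotype matrix; true
#' breeding values are always computed from complete genotypes.
#'
#' @param m A [marker_matrix()].
#' @param rate Per-cell missingness probability.
#' @param seed Integer seed.
#' @return A [marker_matrix()] with `NA` cells.
#' @export
inject_missing <- function(m, rate, seed = 1) {
  check_range(rate, "missing_rate", 0, 1)
  if (rate == 0) return(m)
  with_seed(seed, {
    mask <- matrix(runif(length(m)) < rate, nrow(m))
    out <- unclass(m)
    out[mask] <- NA_integer_
    marker_matrix(out, map = attr(m, "map"),
                  trait_marker = attr(m, "trait_marker"))
  })
}

#' Assign additive effects and true breeding values
#'
#' Samples `n_qtl` markers, draws their additive effects from a zero-mean
#' normal (the infinitesimal-style architecture behind ridge-regression
#' BLUP), and rescales so the realised variance of true breeding values among
#' the supplied lines equals `var_g` exactly. The plot error variance is then
#' set from `heritability_plot`: \eqn{\sigma^2_e = \sigma^2_g(1-h^2)/h^2}.
#' TBV is the exact dosage-weighted sum of effects for every line.
#'
#' @param m A complete (no missing calls) [marker_matrix()].
#' @param config A [sim_config()].
#' @return A list of class `true_values`: `tbv` (tibble line/tbv), `effects`
#'   (tibble marker/effect over all markers, zero off-QTL), `var_g`,
#'   `sigma2_e`, `h2`.
#' @export
assign_effects_and_tbv <- function(m, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(m)) abort("True values need complete genotypes (no NA).")
  h2 <- config$heritability_plot
  if (config$n_qtl == 0 && h2 > 0) {
    abort("Configuration error: `n_qtl` = 0 with positive `heritability_plot`.")
  }
  effects <- setNames(rep(0, ncol(m)), colnames(m))
  if (h2 > 0) {
    with_seed(derive_seed(config$seed, "effects"), {
      qtl <- sample(colnames(m), config$n_qtl)
      a <- rnorm(config$n_qtl)
      tbv_raw <- as.numeric(unclass(m)[, qtl, drop = FALSE] %*% a)
      s <- sd(tbv_raw)
      if (s < 1e-12) {
        abort("No genetic variance among lines at the sampled QTL.")
      }
      effects[qtl] <- a * sqrt(config$var_g) / s
    })
  }
  tbv <- as.numeric(unclass(m) %*% effects)
  sigma2_e <- if (h2 > 0) config$var_g * (1 - h2) / h2 else config$var_g
  structure(list(
    tbv = tibble(line = rownames(m), tbv = tbv),
    effects = tibble(marker = colnames(m), effect = unname(effects)),
    var_g = if (h2 > 0) config$var_g else 0,
    sigma2_e = sigma2_e, h2 = h2
  ), class = "true_values")
}

#' True breeding values for new genotypes under fixed effects
#'
#' @param m A complete [marker_matrix()].
#' @param truth A `true_values` object whose effects to apply.
#' @return A tibble with `line` and `tbv`.
#' @export
compute_tbv <- function(m, truth) {
  stopifnot(inherits(truth, "true_values"))
  eff <- setNames(truth$effects$effect, truth$effects$marker)
  if (!all(colnames(m) %in% names(eff))) {
    abort("Dimension error: genotypes carry markers without assigned effects.")
  }
  tibble(line = rownames(m),
         tbv = as.numeric(unclass(m) %*% eff[colnames(m)]))
}

#' Simulate multi-location yield trials
#'
#' Generates plot records for one trial per location in a given year:
#' phenotype = grand mean + TBV + location effect + line-by-location
#' deviation + design-factor effects + plot error. Supported designs: RCBD
#' (replicate blocks), row-column (replicates with row and column effects)
#' and augmented (checks replicated in every block, test entries unreplicated).
#'
#' @param truth A `true_values` object covering every line to be planted.
#' @param config A [sim_config()] (supplies design, reps, locations, error
#'   and interaction variances).
#' @param year Calendar year stamped on the records.
#' @param lines Line ids to plant (default: all lines in `truth`).
#' @param check_lines For the augmented design: ids replicated in each block.
#' @param seed Integer seed.
#'
#' @return A tibble of plot records: `line`, `trial`, `year`, `location`,
#'   `design`, `rep`, `row`, `col`, `block`, `yield_t_ha`.
#' @export
simulate_trials <- function(truth, config, year, lines = NULL,
                            check_lines = NULL, seed = 1) {
  stopifnot(inherits(truth, "true_values"), inherits(config, "sim_config"))
  tbv <- setNames(truth$tbv$tbv, truth$tbv$line)
  lines <- lines %||% truth$tbv$line
  if (!all(lines %in% names(tbv))) {
    abort("Every planted line needs a true breeding value.")
  }
  design <- config$design
  if (!design %in% c("RCBD", "row-column", "augmented")) {
    abort(sprintf("Unknown `design` '%s'.", design))
  }
  err_sd <- sqrt(truth$sigma2_e)
  gxe_sd <- sqrt(config$gxe_ratio * truth$var_g)

  with_seed(seed, {
    loc_eff <- setNames(rnorm(length(config$locations), 0, config$loc_sd),
                        config$locations)
    out <- purrr::map_dfr(config$locations, function(loc) {
      trial_id <- paste(year, loc, sep = "_")
      gxe <- setNames(rnorm(length(lines), 0, gxe_sd), lines)
      base <- config$grand_mean + loc_eff[loc] + tbv[lines] + gxe
      if (design == "RCBD") {
        plots <- purrr::map_dfr(seq_len(config$reps), function(r) {
          tibble(line = lines, rep = r, row = NA_integer_, col = NA_integer_,
                 block = paste0("rep", r))
        })
      } else if (design == "row-column") {
        nr <- max(1L, floor(sqrt(length(lines))))
        nc <- ceiling(length(lines) / nr)
        plots <- purrr::map_dfr(seq_len(config$reps), function(r) {
          ord <- sample(lines)
          cell <- seq_along(ord)
          tibble(line = ord, rep = r,
                 row = ((cell - 1L) %/% nc) + 1L,
                 col = ((cell - 1L) %% nc) + 1L,
                 block = paste0("rep", r))
        })
      } else {  # augmented: checks in every block, tests once
        checks <- check_lines %||% head(lines, config$n_checks)
        tests <- setdiff(lines, checks)
        blk <- rep(seq_len(config$reps), length.out = length(tests))
        plots <- dplyr::bind_rows(
          purrr::map_dfr(seq_len(config$reps), function(b) {
            tibble(line = checks, rep = NA_integer_, row = NA_integer_,
                   col = NA_integer_, block = paste0("blk", b))
          }),
          tibble(line = tests, rep = NA_integer_, row = NA_integer_,
                 col = NA_integer_, block = paste0("blk", sample(blk))))
      }
      # blocking-factor effects
      blocks <- unique(plots$block)
      blk_eff <- setNames(rnorm(length(blocks), 0, config$block_sd), blocks)
      eff <- blk_eff[plots$block]
      if (design == "row-column") {
        nr_all <- max(plots$row); nc_all <- max(plots$col)
        row_eff <- rnorm(nr_all, 0, config$block_sd)
        col_eff <- rnorm(nc_all, 0, config$block_sd)
        eff <- eff + row_eff[plots$row] + col_eff[plots$col]
      }
      dplyr::mutate(plots,
                    trial = trial_id, year = year, location = loc,
                    design = design,
                    yield_t_ha = unname(base[.data$line] + eff +
                                          rnorm(nrow(plots), 0, err_sd))) |>
        dplyr::select("line", "trial", "year", "location", "design", "rep",
                      "row", "col", "block", "yield_t_ha")
    })
    out
  })
}

#' Run a recurrent genomic-selection program
#'
#' Simulates `n_cycles` cycles: cross the current parents, derive inbred
#' families, run multi-location trials, estimate GEBVs from stage-1 BLUEs
#' with the rrBLUP machinery, recycle the top-GEBV lines as next-cycle
#' parents. Per-cycle mean true breeding value is recorded, so the realised
#' genetic trend is known ground truth. With `select_method = "random"` the
#' program applies no selection pressure (null trend); `"tbv"` selects on
#' the truth (upper bound).
#'
#' @param config A [sim_config()].
#' @param select_method `"gebv"` (default), `"tbv"` or `"random"`.
#' @return A list of class `breeding_program`: `cycle_means` (tibble: cycle,
#'   year, mean_tbv, mean_tbv_selected), `cycles` (per-cycle genotypes,
#'   truth, trials, blues, gebv table, parents), `pedigree`, `truth`.
#' @export
run_recurrent_program <- function(config,
                                  select_method = c("gebv", "tbv", "random")) {
  stopifnot(inherits(config, "sim_config"))
  select_method <- match.arg(select_method)
  if (config$n_parents_recycled < 2) {
    abort("Configuration error: `n_parents_recycled` must be >= 2.")
  }
  founders <- simulate_founders(config)
  parents_geno <- founders
  pedigree <- tibble(line = rownames(founders), parent1 = NA_character_,
                     parent2 = NA_character_, cross_id = NA_character_)
  truth <- NULL
  cycles <- list()
  cycle_means <- tibble()

  for (cy in seq_len(config$n_cycles)) {
    seed_cy <- derive_seed(config$seed, paste0("cycle", cy))
    year <- config$years[cy]
    pool <- rownames(parents_geno)
    crosses <- with_seed(seed_cy, {
      purrr::map_dfr(seq_len(config$n_crosses_per_cycle), function(k) {
        pr <- sample(pool, 2)
        tibble(cross_id = sprintf("C%d_%02d", cy, k), p1 = pr[1], p2 = pr[2])
      })
    })
    fams <- purrr::pmap(crosses, function(cross_id, p1, p2) {
      derive_inbred_family(parents_geno, p1, p2,
                           n_lines = config$lines_per_cross,
                           selfing_generations = config$selfing_generations,
                           seed = derive_seed(seed_cy, cross_id),
                           residual_het_rate = config$residual_het_rate,
                           cross_id = cross_id,
                           prefix = sprintf("L%d%s", cy,
                                            sub("^C\\d+_", "", cross_id)))
    })
    geno <- do.call(rbind, lapply(fams, function(f) unclass(f$genotypes)))
    geno <- marker_matrix(geno, map = attr(founders, "map"))
    pedigree <- dplyr::bind_rows(pedigree,
                                 purrr::map_dfr(fams, "pedigree"))

    if (is.null(truth)) {
      truth <- assign_effects_and_tbv(geno, config)
    } else {
      truth_cy <- compute_tbv(geno, truth)
      truth <- structure(modifyList(truth, list(tbv = truth_cy)),
                         class = "true_values")
    }

    trials <- simulate_trials(truth, config, year = year,
                              lines = rownames(geno),
                              seed = derive_seed(seed_cy, "trials"))
    blues_tr <- fit_trials(trials)
    blues <- blues_tr$blues |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(value = mean(.data$blue), .groups = "drop")

    obs <- inject_missing(geno, config$missing_rate,
                          seed = derive_seed(seed_cy, "missing"))
    qc <- qc_genotypes(obs)
    dos <- encode_dosage(qc$genotypes)

    sel_pool <- intersect(rownames(geno), rownames(dos))
    selected <- switch(
      select_method,
      gebv = {
        gfit <- compute_gebv(dos, dplyr::filter(blues,
                                                .data$line %in% sel_pool))
        select_parents(gfit, config$n_parents_recycled)$line
      },
      tbv = {
        tb <- truth$tbv[truth$tbv$line %in% sel_pool, ]
        tb$line[order(-tb$tbv)][seq_len(config$n_parents_recycled)]
      },
      random = with_seed(derive_seed(seed_cy, "randsel"),
                         sample(sel_pool, config$n_parents_recycled))
    )

    cycle_means <- dplyr::bind_rows(cycle_means, tibble(
      cycle = cy, year = year,
      mean_tbv = mean(truth$tbv$tbv),
      mean_tbv_selected = mean(truth$tbv$tbv[truth$tbv$line %in% selected])))
    cycles[[cy]] <- list(genotypes = geno, truth_tbv = truth$tbv,
                         trials = trials, blues = blues,
                         selected = selected)
    parents_geno <- subset_markers(geno, lines = selected)
  }
  structure(list(cycle_means = cycle_means, cycles = cycles,
                 pedigree = pedigree, truth = truth, config = config),
            class = "breeding_program")
}

#' Simulate an era-trial series with a programmed genetic trend
#'
#' Builds yearly cohorts of inbred lines whose expected mean true breeding
#' value increases by exactly `trend` t/ha per year, implemented as a
#' coordinated per-year shift of QTL allele frequencies in the direction of
#' their effects (the signature selection leaves in a breeding program). A
#' fixed set of check lines is planted every year, anchoring environment
#' effects across eras. This is the ground-truth generator for genetic-gain
#' (era) regression.
#'
#' @param config A [sim_config()].
#' @param trend Programmed gain, t/ha per year.
#' @param n_years Number of yearly cohorts.
#' @param lines_per_year Cohort size.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `era_program`: `trials` (all plot records),
#'   `genotypes` (complete calls, cohorts plus checks), `truth`
#'   (`true_values`), `line_year` (tibble line/year of first evaluation),
#'   `cohort_means` (tibble year/mean_tbv), `checks`.
#' @export
simulate_era_program <- function(config, trend = 0, n_years = 4,
                                 lines_per_year = 400, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  check_range(n_years, "n_years", 2, Inf, integer = TRUE)
  check_range(lines_per_year, "lines_per_year", 2, Inf, integer = TRUE)
  years <- config$years[1] + seq_len(n_years) - 1

  with_seed(derive_seed(seed, "era"), {
    map <- make_map(config$n_markers, config$n_chromosomes,
                    config$chrom_length_morgans)
    p0 <- runif(config$n_markers, config$maf_range[1], config$maf_range[2])
    qtl <- sample(config$n_markers, config$n_qtl)
    a <- rep(0, config$n_markers)
    a[qtl] <- rnorm(config$n_qtl)
    # scale so cohort-0 TBV variance is var_g: inbred draws have
    # var(dosage) = 4 p (1 - p)
    s2 <- sum(4 * p0[qtl] * (1 - p0[qtl]) * a[qtl]^2)
    a <- a * sqrt(config$var_g / s2)
    # per-year frequency shift delivering E[delta mean TBV] = trend
    dp <- rep(0, config$n_markers)
    if (trend != 0) dp[qtl] <- trend * a[qtl] / (2 * sum(a[qtl]^2))

    draw_cohort <- function(pfreq, n, prefix) {
      calls <- matrix(
        2L * rbinom(n * length(pfreq), 1, rep(pfreq, each = n)),
        nrow = n,
        dimnames = list(sprintf("%s_%03d", prefix, seq_len(n)), map$marker))
      calls
    }
    checks <- draw_cohort(p0, config$n_checks, "CHK")
    cohorts <- lapply(seq_along(years) - 1, function(t) {
      pt <- pmin(pmax(p0 + dp * t, 0.02), 0.98)
      draw_cohort(pt, lines_per_year, paste0("Y", years[t + 1]))
    })
    geno <- marker_matrix(do.call(rbind, c(cohorts, list(checks))), map = map)

    eff <- setNames(a, map$marker)
    tbv <- tibble(line = rownames(geno),
                  tbv = as.numeric(unclass(geno) %*% eff))
    sigma2_e <- if (config$heritability_plot > 0) {
      config$var_g * (1 - config$heritability_plot) / config$heritability_plot
    } else config$var_g
    truth <- structure(list(
      tbv = tbv, effects = tibble(marker = map$marker, effect = a),
      var_g = config$var_g, sigma2_e = sigma2_e,
      h2 = config$heritability_plot), class = "true_values")

    trials <- purrr::map_dfr(seq_along(years), function(i) {
      cohort_lines <- rownames(cohorts[[i]])
      simulate_trials(truth, config, year = years[i],
                      lines = c(cohort_lines, rownames(checks)),
                      check_lines = rownames(checks),
                      seed = derive_seed(seed, paste0("trials", years[i])))
    })
    line_year <- trials |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(year = min(.data$year), .groups = "drop")
    cohort_means <- purrr::map_dfr(seq_along(years), function(i) {
      tibble(year = years[i],
             mean_tbv = mean(tbv$tbv[tbv$line %in% rownames(cohorts[[i]])]))
    })
    structure(list(trials = trials, genotypes = geno, truth = truth,
                   line_year = line_year, cohort_means = cohort_means,
                   checks = rownames(checks)),
              class = "era_program")
  })
}
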