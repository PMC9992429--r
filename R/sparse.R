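#' Build the common share of a sparse-testing design
#'
#' Samples `floor(frac * n)` lines to be planted at every location, under the
#' connectivity constraint that *every cross* in the population is
#' represented. Pass 1 takes one line per cross greedily, preferring crosses
#' that share a parent with a cross already covered (ties by cross id) so
#' the common share carries pedigree connectivity; pass 2 fills the
#' remaining slots by seeded uniform sampling.
#'
#' @param population Character vector of line ids (or tibble with `line`).
#' @param cross_map Tibble `line`/`cross_id` mapping every line to its cross.
#' @param parent_map Tibble `cross_id`/`parent1`/`parent2`.
#' @param frac Common-share fraction of the population (default 0.40).
#' @param seed Integer seed.
#' @return Character vector of common-share line ids.
#' @export
build_common_share <- function(population, cross_map, parent_map = NULL,
                               frac = 0.40, seed = 1) {
  if (is.data.frame(population)) population <- population$line
  population <- as.character(population)
  cross_map <- as_tibble(cross_map)
  if (!all(c("line", "cross_id") %in% names(cross_map))) {
    abort("`cross_map` needs columns line, cross_id.")
  }
  unmapped <- setdiff(population, cross_map$line)
  if (length(unmapped) > 0) {
    abort(sprintf("%d line(s) have no cross assignment: %s", length(unmapped),
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  check_range(frac, "frac", 0, 1)
  n_slots <- floor(frac * length(population))
  cmap <- cross_map[cross_map$line %in% population, ]
  crosses <- sort(unique(cmap$cross_id))
  if (n_slots < length(crosses)) {
    abort(sprintf(
      "Infeasibility error: common share of %d slots cannot cover %d crosses.",
      n_slots, length(crosses)))
  }

  # order crosses so that each (after the first) shares a parent with an
  # earlier one where possible: greedy connectivity preference
  if (!is.null(parent_map)) {
    pm <- as_tibble(parent_map)
    pm <- pm[match(crosses, pm$cross_id), ]
    ordered <- crosses[1]
    remaining <- crosses[-1]
    covered_parents <- unlist(pm[pm$cross_id == crosses[1],
                                 c("parent1", "parent2")])
    while (length(remaining) > 0) {
      shares <- vapply(remaining, function(cr) {
        any(unlist(pm[pm$cross_id == cr, c("parent1", "parent2")]) %in%
              covered_parents)
      }, logical(1))
      nxt <- if (any(shares)) remaining[shares][1] else remaining[1]
      ordered <- c(ordered, nxt)
      covered_parents <- union(covered_parents,
                               unlist(pm[pm$cross_id == nxt,
                                         c("parent1", "parent2")]))
      remaining <- setdiff(remaining, nxt)
    }
    crosses <- ordered
  }

  with_seed(seed, {
    pass1 <- vapply(crosses, function(cr) {
      cand <- sort(cmap$line[cmap$cross_id == cr])
      cand[sample.int(length(cand), 1)]
    }, character(1))
    pool <- setdiff(population, pass1)
    extra <- if (n_slots > length(pass1)) {
      sample(pool, n_slots - length(pass1))
    } else character(0)
    common <- population[population %in% c(pass1, extra)]
    common
  })
}

#' Build a multi-location sparse-testing design
#'
#' Splits a breeding population into `n_tp` location-specific training
#' populations: every TP contains the common share, and the non-common
#' remainder is dealt out `floor(step_frac * |remainder|)` lines at a time
#' *without replacement* across TPs, so no test entry is duplicated between
#' locations. With `step_frac = 1/n_tp` the remainder is exhausted and every
#' line is tested somewhere.
#'
#' @param population Character vector of line ids (or tibble with `line`).
#' @param common Common-share line ids (from [build_common_share()]).
#' @param n_tp Number of training populations/locations (default 4).
#' @param step_frac Fraction of the remainder drawn per TP (default 0.25).
#' @param locations Location labels, length `n_tp`.
#' @param seed Integer seed.
#' @return An object of class `sparse_design`: tibble `line`, `tp`,
#'   `location`, `is_common` (one row per line-TP assignment), with
#'   attributes `common`, `unique_sets`, `untested`, `fractions`, `seed`.
#' @export
build_sparse_design <- function(population, common, n_tp = 4,
                                step_frac = 0.25, locations = NULL,
                                seed = 1) {
  if (is.data.frame(population)) population <- population$line
  population <- as.character(population)
  check_range(n_tp, "n_tp", 1, Inf, integer = TRUE)
  check_range(step_frac, "step_frac", 0, 1)
  if (step_frac * n_tp > 1 + 1e-12) {
    abort(sprintf(
      "Infeasibility error: %d draws of %.0f%% exceed the remainder.",
      n_tp, 100 * step_frac))
  }
  if (!all(common %in% population)) {
    abort("`common` must be a subset of `population`.")
  }
  locations <- locations %||% paste0("site", seq_len(n_tp))
  if (length(locations) != n_tp) {
    abort("`locations` must supply one label per TP.")
  }
  remainder <- setdiff(population, common)
  draw_size <- floor(step_frac * length(remainder))

  unique_sets <- with_seed(seed, {
    pool <- remainder
    lapply(seq_len(n_tp), function(t) {
      take <- sample(pool, draw_size)
      pool <<- setdiff(pool, take)
      take
    })
  })
  assigned <- unlist(unique_sets)
  untested <- setdiff(remainder, assigned)

  out <- purrr::map_dfr(seq_len(n_tp), function(t) {
    tibble(line = c(common, unique_sets[[t]]),
           tp = t, location = locations[t],
           is_common = c(rep(TRUE, length(common)),
                         rep(FALSE, length(unique_sets[[t]]))))
  })
  structure(out, common = common, unique_sets = unique_sets,
            untested = untested,
            fractions = c(common = length(common) / length(population),
                          step = step_frac),
            seed = seed, class = c("sparse_design", class(out)))
}

#' Diagnostics for a sparse-testing design
#'
#' Sizes, pairwise TP overlaps, per-cross representation in the common
#' share and per TP, and the coverage audit (lines tested nowhere are
#' listed, never silently dropped).
#'
#' @param design A `sparse_design`.
#' @param cross_map Optional tibble `line`/`cross_id` for connectivity checks.
#' @return A list: `tp_sizes` (tibble), `overlap` (matrix), `untested`
#'   (character), `cross_representation` (tibble or NULL),
#'   `crosses_missing_from_common` (character or NULL), `tp_share_of_population`.
#' @export
design_diagnostics <- function(design, cross_map = NULL) {
  common <- attr(design, "common")
  usets <- attr(design, "unique_sets")
  n_tp <- length(usets)
  tps <- lapply(seq_len(n_tp), function(t) c(common, usets[[t]]))
  overlap <- outer(seq_len(n_tp), seq_len(n_tp),
                   Vectorize(function(i, j) length(intersect(tps[[i]],
                                                             tps[[j]]))))
  dimnames(overlap) <- list(paste0("TP", seq_len(n_tp)),
                            paste0("TP", seq_len(n_tp)))
  pop_size <- length(unique(design$line)) + length(attr(design, "untested"))
  res <- list(
    tp_sizes = tibble(tp = seq_len(n_tp),
                      size = lengths(tps),
                      n_common = length(common),
                      n_unique = lengths(usets)),
    overlap = overlap,
    untested = attr(design, "untested"),
    tp_share_of_population = lengths(tps) / pop_size,
    cross_representation = NULL,
    crosses_missing_from_common = NULL)
  if (!is.null(cross_map)) {
    cm <- as_tibble(cross_map)
    crosses <- unique(cm$cross_id)
    in_common <- unique(cm$cross_id[cm$line %in% common])
    res$crosses_missing_from_common <- setdiff(crosses, in_common)
    res$cross_representation <- purrr::map_dfr(seq_len(n_tp), function(t) {
      tibble(tp = t,
             n_crosses = length(unique(cm$cross_id[cm$line %in% tps[[t]]])),
             n_crosses_total = length(crosses))
    })
  }
  res
}

#' Plot a sparse-testing allocation
#'
#' Tile map of lines (ordered common first) against TPs.
#'
#' @param object A `sparse_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sparse_design <- function(object, ...) {
  df <- as_tibble(object)
  ord <- unique(df$line[order(!df$is_common)])
  df$line <- factor(df$line, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = as.integer(.data$line),
                                   y = factor(.data$tp),
                                   fill = .data$is_common)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Line (common share first)", y = "Training population",
                  fill = "Common share",
                  title = "Sparse-testing allocation") +
    ggplot2::theme_minimal()
}
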