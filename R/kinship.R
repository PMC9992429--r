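#' Pedigree additive relationship matrix (tabular method)
#'
#' Builds the numerator relationship matrix A from a pedigree by the tabular
#' method: founders (unknown parents) are taken as unrelated and non-inbred,
#' \eqn{a_{ii} = 1 + F_i} with \eqn{F_i = a_{p_1 p_2}/2}, and
#' \eqn{a_{ij} = (a_{j p_1} + a_{j p_2})/2}. Repeated selfing entries
#' (`parent1 == parent2`) are supported, so inbreeding accumulates as
#' \eqn{F_{g+1} = (1 + F_g)/2}.
#'
#' @param pedigree A data frame with columns `line`, `parent1`, `parent2`
#'   (`NA` for unknown parents). Rows may be in any order as long as the
#'   pedigree is acyclic; a topological sort is applied. Parents that never
#'   appear as lines are added as founders with a warning.
#'
#' @return A symmetric numeric matrix with line ids as dimnames. Diagonal
#'   entries are `1 + F`.
#' @export
build_a_matrix <- function(pedigree) {
  ped <- as_tibble(pedigree)
  need <- c("line", "parent1", "parent2")
  if (!all(need %in% names(ped))) {
    abort("`pedigree` needs columns line, parent1, parent2.")
  }
  ped <- dplyr::mutate(ped, dplyr::across(dplyr::all_of(need), as.character))
  if (anyDuplicated(ped$line)) abort("Duplicated line ids in pedigree.")

  parents <- setdiff(na.omit(c(ped$parent1, ped$parent2)), ped$line)
  if (length(parents) > 0) {
    warn(sprintf("%d parent(s) not listed as lines; treated as founders: %s",
                 length(parents),
                 paste(head(parents, 5), collapse = ", ")))
    ped <- dplyr::bind_rows(
      tibble(line = parents, parent1 = NA_character_, parent2 = NA_character_),
      ped)
  }

  # Topological sort: parents must precede offspring.
  order_ids <- character(0)
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$parent1) | remaining$parent1 %in% placed) &
      (is.na(remaining$parent2) | remaining$parent2 %in% placed)
    if (!any(ready)) {
      abort("Structure error: pedigree contains a cycle.")
    }
    order_ids <- c(order_ids, remaining$line[ready])
    placed <- order_ids
    remaining <- remaining[!ready, , drop = FALSE]
  }
  ped <- ped[match(order_ids, ped$line), ]

  nl <- nrow(ped)
  A <- matrix(0, nl, nl, dimnames = list(ped$line, ped$line))
  idx <- setNames(seq_len(nl), ped$line)
  p1 <- idx[ped$parent1]
  p2 <- idx[ped$parent2]
  for (i in seq_len(nl)) {
    a1 <- p1[i]; a2 <- p2[i]
    if (i > 1) {
      js <- seq_len(i - 1)
      v <- 0.5 * ((if (!is.na(a1)) A[js, a1] else 0) +
                    (if (!is.na(a2)) A[js, a2] else 0))
      A[js, i] <- v
      A[i, js] <- v
    }
    A[i, i] <- 1 + if (!is.na(a1) && !is.na(a2)) 0.5 * A[a1, a2] else 0
  }
  A
}

#' Genomic relationship matrix
#'
#' VanRaden method-1 genomic relationships from a dosage matrix coded
#' \{-1, 0, +1\}: columns are centred at twice the allele-frequency deviation
#' from 0.5 and the cross-product is scaled by \eqn{2\sum_k p_k(1-p_k)}.
#'
#' @param d A `dosage_matrix` from [encode_dosage()] (or any numeric
#'   lines-by-markers matrix in \[-1, 1\]).
#' @return A symmetric genomic relationship matrix with line ids as dimnames.
#' @export
build_g_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) abort("Need at least 2 lines to build G.")
  p <- (colMeans(d) + 1) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom < 1e-12) {
    abort("Degenerate-kernel error: all markers are monomorphic.")
  }
  W <- sweep(d, 2, 2 * (p - 0.5))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(d), rownames(d))
  G
}
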