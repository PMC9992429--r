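#' SNP marker matrix
#'
#' A light container for biallelic SNP calls on breeding lines: an integer
#' matrix of alternate-allele counts with lines in rows and markers in
#' columns. Calls take four states: `0` (homozygous reference), `1`
#' (heterozygous), `2` (homozygous alternate) and `NA` (missing). An optional
#' genetic map (`marker`, `chrom`, `pos` in Morgans) and a logical
#' trait-specific-marker flag ride along as attributes; trait-marker flags are
#' carried as metadata only and never enter any computation.
#'
#' @param calls Integer matrix in \{0, 1, 2, NA\} with unique rownames (line
#'   ids) and colnames (marker ids).
#' @param map Optional tibble with columns `marker`, `chrom`, `pos` (Morgans),
#'   one row per column of `calls`.
#' @param trait_marker Optional logical vector flagging trait-specific markers.
#'
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, map = NULL, trait_marker = NULL) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix.")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` needs rownames (line ids) and colnames (marker ids).")
  }
  if (anyDuplicated(rownames(calls))) abort("Line ids must be unique.")
  if (anyDuplicated(colnames(calls))) abort("Marker ids must be unique.")
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) abort("Calls must be 0, 1, 2 or NA.")
  storage.mode(calls) <- "integer"
  if (!is.null(map)) {
    map <- as_tibble(map)
    if (!all(c("marker", "chrom", "pos") %in% names(map)) ||
        nrow(map) != ncol(calls)) {
      abort("`map` must have columns marker/chrom/pos, one row per marker.")
    }
  }
  if (!is.null(trait_marker) &&
      (!is.logical(trait_marker) || length(trait_marker) != ncol(calls))) {
    abort("`trait_marker` must be logical, one flag per marker.")
  }
  structure(calls,
            map = map,
            trait_marker = trait_marker,
            class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  miss <- mean(is.na(x))
  het <- mean(x == 1L, na.rm = TRUE)
  cat(sprintf(
    "<marker_matrix> %d lines x %d markers | %.1f%% missing, %.1f%% het calls\n",
    nrow(x), ncol(x), 100 * miss, 100 * het))
  invisible(x)
}

# Subset while keeping attributes in sync.
subset_markers <- function(m, lines = NULL, markers = NULL) {
  map <- attr(m, "map")
  tm <- attr(m, "trait_marker")
  li <- lines %||% rownames(m)
  mk <- markers %||% colnames(m)
  out <- unclass(m)[li, mk, drop = FALSE]
  keep <- match(mk, colnames(m))
  marker_matrix(out,
                map = if (!is.null(map)) map[keep, ] else NULL,
                trait_marker = if (!is.null(tm)) tm[keep] else NULL)
}

#' Convert a marker matrix to a long tibble
#'
#' @param x A [marker_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `line`, `marker`, `call`.
#' @export
as_tibble.marker_matrix <- function(x, ...) {
  tibble(line = rep(rownames(x), times = ncol(x)),
         marker = rep(colnames(x), each = nrow(x)),
         call = as.integer(x))
}

#' Read and write tabular genotype matrices
#'
#' The tabular interchange format is a CSV with a `line` column followed by
#' one column per marker holding calls in \{0, 1, 2\} or empty for missing.
#'
#' @param m A [marker_matrix()].
#' @param path File path.
#' @return `read_marker_matrix()` returns a [marker_matrix()];
#'   `write_marker_matrix()` returns `path` invisibly.
#' @export
write_marker_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m))
  df <- cbind(line = rownames(m), df)
  readr::write_csv(as_tibble(df), path, na = "")
  invisible(path)
}

#' @rdname write_marker_matrix
#' @export
read_marker_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- as.character(df[[1]])
  marker_matrix(calls)
}

#' Write genotypes as a diploid VCF
#'
#' Emits plain VCFv4.2 text with unphased `GT` calls (`0/0`, `0/1`, `1/1`,
#' `./.`), one sample per line and one record per marker. Map positions in
#' Morgans are scaled to integer coordinates; without a map, markers are
#' placed consecutively on chromosome 1.
#'
#' @param m A [marker_matrix()].
#' @param path Output file path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_marker_vcf <- function(m, path) {
  map <- attr(m, "map")
  if (is.null(map)) {
    map <- tibble(marker = colnames(m), chrom = 1L, pos = seq_len(ncol(m)))
    pos_bp <- map$pos
  } else {
    pos_bp <- as.integer(round(map$pos * 1e6)) + 1L
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines_out <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(m)), collapse = "\t"))
  body <- vapply(seq_len(ncol(m)), function(j) {
    calls <- m[, j]
    gt <- ifelse(is.na(calls), "./.", gt_code[as.character(calls)])
    paste(c(map$chrom[j], pos_bp[j], colnames(m)[j], "A", "G", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines_out, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses the `GT` field (phased or unphased) of a VCF into a
#' [marker_matrix()] of alternate-allele counts. Requires the vcfR package.
#'
#' @param path Path to a VCF file.
#' @return A [marker_matrix()].
#' @export
read_marker_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  counts <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                   dimnames = list(colnames(gt), rownames(gt)))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  counts[] <- lut[t(gt)]
  marker_matrix(counts)
}
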