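#' Tetranucleotide frequency vectors
#'
#' Counts all overlapping 4-mers of each sequence on the given strand only
#' (no reverse-complement collapsing, so there are 256 columns in
#' lexicographic order AAAA..TTTT), skips any window containing a non-ACGT
#' symbol, and divides by the number of valid windows so each row sums to 1.
#'
#' @param sequences Character vector of DNA sequences (optionally named) or a
#'   [Biostrings::DNAStringSet].
#' @return Tibble with `seq_id` followed by 256 frequency columns, one row
#'   per sequence.
#' @examples
#' tetranucleotide_frequencies("ACGTACGT")$ACGT
#' @export
tetranucleotide_frequencies <- function(sequences) {
  if (is.character(sequences)) {
    ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
    x <- Biostrings::DNAStringSet(sequences)
  } else if (inherits(sequences, "DNAStringSet")) {
    x <- sequences
    ids <- names(x) %||% paste0("seq", seq_along(x))
  } else {
    abort("`sequences` must be a character vector or DNAStringSet.")
  }
  counts <- Biostrings::oligonucleotideFrequency(x, width = 4, step = 1)
  valid <- rowSums(counts)
  if (any(valid < 1)) {
    bad <- ids[valid < 1]
    abort(paste0("sequence too short/ambiguous (no valid 4-mer window): ",
                 paste(bad, collapse = ", ")))
  }
  freq <- counts / valid
  colnames(freq) <- tetra_names()
  dplyr::bind_cols(tibble(seq_id = ids), as_tibble(freq))
}

#' Normalize a coverage table for sample data size
#'
#' Equalizes per-sample totals: each sample column is divided by its column
#' sum and multiplied by the mean column sum, so differences in sequencing
#' effort between samples no longer distort between-sample comparisons while
#' values stay on a fold-coverage-like scale.
#'
#' @param coverage Wide coverage tibble: `scaffold_id` plus one numeric
#'   column per sample.
#' @return Tibble of the same shape with attribute `normalized = TRUE`; all
#'   sample column sums equal the mean raw column sum.
#' @examples
#' cov <- tibble::tibble(scaffold_id = c("a", "b"),
#'                       s1 = c(10, 90), s2 = c(100, 200))
#' colSums(normalize_coverage(cov)[, -1])
#' @export
normalize_coverage <- function(coverage) {
  check_coverage(coverage)
  mat <- as.matrix(coverage[, -1, drop = FALSE])
  sums <- colSums(mat)
  if (any(sums == 0)) {
    abort(paste0("sample column(s) sum to zero: ",
                 paste(colnames(mat)[sums == 0], collapse = ", ")))
  }
  out_mat <- sweep(mat, 2, mean(sums) / sums, `*`)
  out <- dplyr::bind_cols(coverage[, 1], as_tibble(out_mat))
  attr(out, "normalized") <- TRUE
  out
}

check_coverage <- function(coverage) {
  if (!is.data.frame(coverage) || names(coverage)[1] != "scaffold_id")
    abort("`coverage` must be a data frame whose first column is `scaffold_id`.")
  if (ncol(coverage) < 2)
    abort("`coverage` needs at least one sample column.")
  mat <- as.matrix(coverage[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(mat < 0) || anyNA(mat))
    abort("coverage values must be non-negative numbers.")
  if (anyDuplicated(coverage$scaffold_id))
    abort("scaffold ids in `coverage` must be unique.")
  invisible(coverage)
}

is_normalized <- function(coverage) isTRUE(attr(coverage, "normalized"))

#' Build the combined coverage + tetranucleotide feature matrix
#'
#' Assembles the matrix fed to the emergent self-organizing map: one row per
#' scaffold strictly longer than `min_length` (the binning gate, 8 kb by
#' default), with a coverage block (one column per sample, the
#' scaffold's normalized coverage series rescaled to unit sum and multiplied
#' by `coverage_weight`) followed by a tetranucleotide block (256 columns,
#' frequencies multiplied by `tetra_weight`). The per-row unit-sum scaling
#' puts both blocks on comparable magnitudes so neither dominates the SOM's
#' Euclidean metric; the block weights let you re-balance them.
#'
#' @param scaffolds Tibble with `scaffold_id`, `length` and `sequence`
#'   columns (as produced by the synthetic generator or [read_scaffolds()]).
#' @param coverage Normalized coverage tibble from [normalize_coverage()].
#' @param min_length Length gate in bp; scaffolds with `length > min_length`
#'   are retained (default 8000).
#' @param coverage_weight,tetra_weight Block weights (defaults 1, 1).
#' @return Tibble `scaffold_id` + sample columns + 256 tetranucleotide
#'   columns with attributes `coverage_cols`, `tetra_cols` and `weights`.
#' @export
build_feature_matrix <- function(scaffolds, coverage, min_length = 8000,
                                 coverage_weight = 1, tetra_weight = 1) {
  stopifnot(all(c("scaffold_id", "length", "sequence") %in% names(scaffolds)))
  check_coverage(coverage)
  if (!is_normalized(coverage))
    abort("`coverage` is not normalized; call normalize_coverage() first.")

  keep <- scaffolds[scaffolds$length > min_length, ]
  if (nrow(keep) == 0)
    abort(sprintf("no scaffold exceeds min_length = %d.", min_length))
  missing <- setdiff(keep$scaffold_id, coverage$scaffold_id)
  if (length(missing) > 0) {
    abort(paste0("scaffold(s) missing from the coverage table: ",
                 paste(missing, collapse = ", ")))
  }

  sample_cols <- names(coverage)[-1]
  cov_mat <- as.matrix(coverage[match(keep$scaffold_id, coverage$scaffold_id),
                                -1, drop = FALSE])
  row_sums <- rowSums(cov_mat)
  zero_rows <- row_sums == 0
  if (any(zero_rows)) {
    warn(paste0("scaffold(s) with all-zero coverage left as zero rows: ",
                paste(keep$scaffold_id[zero_rows], collapse = ", ")))
    row_sums[zero_rows] <- 1
  }
  cov_block <- cov_mat / row_sums * coverage_weight

  tetra <- tetranucleotide_frequencies(
    setNames(keep$sequence, keep$scaffold_id))
  tetra_block <- as.matrix(tetra[, -1, drop = FALSE]) * tetra_weight

  out <- dplyr::bind_cols(
    tibble(scaffold_id = keep$scaffold_id),
    as_tibble(cov_block), as_tibble(tetra_block))
  attr(out, "coverage_cols") <- sample_cols
  attr(out, "tetra_cols") <- tetra_names()
  attr(out, "weights") <- c(coverage = coverage_weight, tetra = tetra_weight)
  out
}

# numeric matrix view of a feature tibble (rows named by scaffold_id)
feature_values <- function(features) {
  m <- as.matrix(features[, -1, drop = FALSE])
  rownames(m) <- features$scaffold_id
  m
}
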