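# rpS3-based species-level community profiling: greedy centroid clustering
# of ribosomal protein S3 sequences, percent-abundance tables from scaffold
# coverage, phylum rollups, and Bray-Curtis PCoA ordination.

# Align query against centroid with free end gaps and report identity
# (matches / aligned columns, internal gaps count against identity) and span
# (aligned columns / full alignment columns including terminal overhangs).
align_stats <- function(query, centroid, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(centroid),
    type = "overlap",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend
  )
  aligned_cols <- Biostrings::nchar(aln)  # overlap region incl internal gaps
  if (aligned_cols == 0) return(list(identity = 0, span = 0))
  p <- aln@pattern@range
  s <- aln@subject@range
  left <- max(BiocGenerics::start(p) - 1L, BiocGenerics::start(s) - 1L)
  right <- max(nchar(query) - BiocGenerics::end(p),
               nchar(centroid) - BiocGenerics::end(s))
  total_cols <- aligned_cols + left + right
  list(
    identity = Biostrings::nmatch(aln) / aligned_cols,
    span = aligned_cols / total_cols
  )
}

#' Cluster rpS3 sequences into species-level units
#'
#' Greedy centroid clustering: sequences are processed longest-first; each
#' query is aligned (global with free end gaps, BLOSUM62, affine gap open
#' 11 / extend 1) to the existing centroids in order and joins the first
#' centroid reaching at least `identity` over at least `span` of the
#' alignment; otherwise it founds a new cluster. A sequence that matches a
#' centroid at the identity threshold but never satisfies the span condition
#' (a short fragment) is excluded rather than clustered. At the default 99%
#' identity the clusters approximate species-level units.
#'
#' @param sequences Named character vector of amino-acid sequences or an
#'   [Biostrings::AAStringSet].
#' @param identity Identity threshold in (0, 1]; default 0.99.
#' @param span Minimum fraction of alignment columns the query must cover;
#'   default 0.60.
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @return List with `members` (tibble: `seq_id`, `cluster_id`,
#'   `centroid_id`) and `excluded` (character vector of span-failing ids).
#' @examples
#' seqs <- c(a = "MKVLDQWSPR", b = "MKVLDQWSPR", c = "AAAAAAAAAA")
#' cluster_species(seqs, identity = 0.9, span = 0.5)$members
#' @export
cluster_species <- function(sequences, identity = 0.99, span = 0.60,
                            gap_open = 11, gap_extend = 1) {
  if (inherits(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (length(sequences) == 0)
    return(list(members = tibble(seq_id = character(),
                                 cluster_id = character(),
                                 centroid_id = character()),
                excluded = character()))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (identity <= 0 || identity > 1 || span <= 0 || span > 1)
    abort("`identity` and `span` must lie in (0, 1].")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequences)))
    warn("non-amino-acid symbols (beyond X) present in input sequences.")

  scoring <- list(matrix = "BLOSUM62", gap_open = gap_open,
                  gap_extend = gap_extend)
  ord <- order(-nchar(sequences))
  centroid_ids <- character(0)
  assign_to <- character(length(sequences))
  names(assign_to) <- names(sequences)
  excluded <- character(0)

  for (i in ord) {
    id <- names(sequences)[i]
    hit <- NA_character_
    span_failed <- FALSE
    for (cid in centroid_ids) {
      st <- align_stats(sequences[[i]], sequences[[cid]], scoring)
      if (st$identity >= identity) {
        if (st$span >= span) { hit <- cid; break }
        span_failed <- TRUE
      }
    }
    if (!is.na(hit)) {
      assign_to[id] <- hit
    } else if (span_failed) {
      excluded <- c(excluded, id)
      assign_to[id] <- NA_character_
    } else {
      centroid_ids <- c(centroid_ids, id)
      assign_to[id] <- id
    }
  }

  kept <- !is.na(assign_to)
  cluster_label <- setNames(zero_pad_ids("cluster", length(centroid_ids)),
                            centroid_ids)
  members <- tibble(
    seq_id = names(assign_to)[kept],
    cluster_id = unname(cluster_label[assign_to[kept]]),
    centroid_id = unname(assign_to[kept])
  )
  list(members = members, excluded = excluded)
}

#' Percent-abundance table of species clusters
#'
#' The abundance of a cluster in a sample is the summed normalized coverage
#' of the scaffolds encoding its member rpS3 sequences; each sample column
#' is then rescaled to percent so columns sum to 100 over detected clusters.
#'
#' @param clusters `members` tibble from [cluster_species()] (or the list
#'   itself).
#' @param coverage Normalized coverage tibble ([normalize_coverage()]).
#' @param scaffold_map Tibble mapping `seq_id` (rpS3 id) to `scaffold_id`
#'   and optionally `taxon` (the `rps3_map` of a synthetic community works
#'   directly, its `rps3_id` column is accepted as `seq_id`).
#' @return Tibble `cluster_id` (+ `taxon` when available) + one percent
#'   column per sample; each sample column sums to 100.
#' @export
abundance_table <- function(clusters, coverage, scaffold_map) {
  if (is.list(clusters) && !is.data.frame(clusters))
    clusters <- clusters$members
  check_coverage(coverage)
  if (!is_normalized(coverage))
    abort("`coverage` is not normalized; call normalize_coverage() first.")
  if ("rps3_id" %in% names(scaffold_map) && !"seq_id" %in% names(scaffold_map))
    scaffold_map <- dplyr::rename(scaffold_map, seq_id = "rps3_id")

  joined <- dplyr::left_join(clusters, scaffold_map, by = "seq_id")
  missing <- joined$cluster_id[!joined$scaffold_id %in% coverage$scaffold_id |
                                 is.na(joined$scaffold_id)]
  if (length(missing) > 0)
    abort(paste0("cluster(s) with no coverage-mapped scaffold: ",
                 paste(unique(missing), collapse = ", ")))

  sample_cols <- names(coverage)[-1]
  cov <- coverage[match(joined$scaffold_id, coverage$scaffold_id), -1,
                  drop = FALSE]
  agg <- dplyr::bind_cols(joined["cluster_id"], cov) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sample_cols), sum),
                     .groups = "drop")
  mat <- as.matrix(agg[, sample_cols, drop = FALSE])
  totals <- colSums(mat)
  totals[totals == 0] <- 1
  pct <- sweep(mat, 2, totals, `/`) * 100

  out <- dplyr::bind_cols(agg["cluster_id"], as_tibble(pct))
  if ("taxon" %in% names(joined)) {
    centroid_taxon <- joined |>
      dplyr::distinct(.data$cluster_id, .data$centroid_id, .keep_all = TRUE) |>
      dplyr::filter(.data$seq_id == .data$centroid_id) |>
      dplyr::select("cluster_id", "taxon")
    out <- dplyr::left_join(out, centroid_taxon, by = "cluster_id") |>
      dplyr::relocate("taxon", .after = "cluster_id")
  }
  out
}

#' Roll species abundances up to phylum level
#'
#' Sums the percent abundances of all clusters sharing a phylum label, as
#' used for stacked community bar charts; sample column sums are preserved.
#' Clusters without a label are pooled as `"Unclassified"` with a warning.
#'
#' @param abundance Tibble from [abundance_table()] including a `taxon`
#'   column.
#' @return Tibble `taxon` + one percent column per sample.
#' @export
phylum_rollup <- function(abundance) {
  if (!"taxon" %in% names(abundance))
    abort("`abundance` must carry a `taxon` column to roll up.")
  if (any(is.na(abundance$taxon))) {
    warn("cluster(s) without a phylum label assigned to \"Unclassified\".")
    abundance$taxon[is.na(abundance$taxon)] <- "Unclassified"
  }
  sample_cols <- setdiff(names(abundance), c("cluster_id", "taxon"))
  abundance |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sample_cols), sum),
                     .groups = "drop")
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i) over the abundance columns;
#' 0 for identical samples, 1 for samples with disjoint taxon support. The
#' measure is a semimetric (it can violate the triangle inequality).
#'
#' @param abundance Abundance tibble (`cluster_id`/`taxon` + sample
#'   columns) or a numeric matrix with taxa as rows and samples as columns.
#' @return Symmetric sample-by-sample distance matrix with zero diagonal.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' bray_curtis_matrix(m)["a", "b"]  # 1/3
#' @export
bray_curtis_matrix <- function(abundance) {
  mat <- abundance_matrix(abundance)
  if (any(mat < 0)) abort("abundances must be non-negative.")
  empty <- colSums(mat) == 0
  if (sum(empty) >= 2)
    warn("two or more all-zero samples; their mutual distance is defined as 0.")
  # empty samples are warned about above with a defined convention
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(mat), method = "bray")))
  d[is.nan(d)] <- 0
  diag(d) <- 0
  d
}

abundance_matrix <- function(abundance) {
  if (is.matrix(abundance)) return(abundance)
  id_cols <- intersect(c("cluster_id", "taxon"), names(abundance))
  mat <- as.matrix(abundance[, setdiff(names(abundance), id_cols),
                             drop = FALSE])
  rownames(mat) <- abundance[[id_cols[1]]]
  mat
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and returns coordinates scaled by
#' the square roots of the top `k` positive eigenvalues. Negative
#' eigenvalues (possible for semimetrics like Bray-Curtis) are dropped and
#' reported.
#'
#' @param distances Symmetric distance matrix with zero diagonal.
#' @param k Number of axes (default 2); truncated with a warning if fewer
#'   positive eigenvalues exist.
#' @return A `pcoa` object: list with `coordinates` (tibble: `sample_id`,
#'   `Axis1` ... `Axisk`), `eigenvalues`, `proportion_explained` (over
#'   positive eigenvalues), and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(distances, k = 2) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) ||
      any(abs(diag(d)) > 1e-12))
    abort("`distances` must be a symmetric matrix with zero diagonal.")
  n <- nrow(d)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > 1e-12)
  if (k > n_pos) {
    warn(sprintf("only %d positive eigenvalue(s); returning %d axis/axes.",
                 n_pos, n_pos))
    k <- n_pos
  }
  k <- min(k, ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  dimnames(coords) <- list(NULL, if (k > 0) paste0("Axis", seq_len(k)))
  ids <- rownames(d) %||% paste0("sample", seq_len(n))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble(sample_id = ids),
                                     as_tibble(coords)),
      eigenvalues = eig[eig > 1e-12],
      proportion_explained = eig[eig > 1e-12] / sum(eig[eig > 1e-12]),
      negative_eigenvalues = eig[eig < -1e-12]
    ),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat(sprintf(
    "<pcoa_ordination> %d samples, %d axes (%.1f%% of positive inertia)\n",
    nrow(x$coordinates), k, 100 * sum(x$proportion_explained[seq_len(k)])))
  invisible(x)
}

#' @rdname pcoa_ordination
#' @param x A `pcoa_ordination`.
#' @param ... Unused.
#' @export
tidy.pcoa_ordination <- function(x, ...) x$coordinates

#' Per-cluster occurrence summaries
#'
#' Descriptive statistics of cluster detection across samples (a cluster is
#' "detected" in a sample when its percent abundance is positive): number of
#' samples detected, mean and sd of percent abundance over the samples where
#' detected.
#'
#' @param abundance Tibble from [abundance_table()].
#' @return Tibble: `cluster_id`, `n_detected`, `mean_abundance`,
#'   `sd_abundance`.
#' @export
occurrence_summary <- function(abundance) {
  sample_cols <- setdiff(names(abundance), c("cluster_id", "taxon"))
  abundance |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample_id",
                        values_to = "pct") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_detected = sum(.data$pct > 0),
      mean_abundance = mean(.data$pct[.data$pct > 0]),
      sd_abundance = stats::sd(.data$pct[.data$pct > 0]),
      .groups = "drop"
    )
}
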