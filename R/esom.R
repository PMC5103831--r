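# Toroidal batch emergent self-organizing map for genome binning.
#
# Training is batch SOM: each epoch assigns every row to its best matching
# unit (BMU), then replaces every neuron by the Gaussian-neighborhood-
# weighted mean of all rows, with the neighborhood radius decaying linearly.
# Batch updates make training deterministic given the seeded initialization,
# unlike the online rule, and reduce exactly to Lloyd's k-means step when the
# radius is zero.

# toroidal grid coordinates for neurons 1..rows*cols (row-major)
grid_coords <- function(rows, cols) {
  tibble(
    neuron = seq_len(rows * cols),
    r = rep(seq_len(rows) - 1L, each = cols),
    c = rep(seq_len(cols) - 1L, times = rows)
  )
}

# squared toroidal Euclidean grid distances between all neuron pairs
grid_dist2 <- function(rows, cols) {
  g <- grid_coords(rows, cols)
  dr <- abs(outer(g$r, g$r, `-`)); dr <- pmin(dr, rows - dr)
  dc <- abs(outer(g$c, g$c, `-`)); dc <- pmin(dc, cols - dc)
  dr^2 + dc^2
}

# squared Euclidean distances between data rows and neuron weights
cross_dist2 <- function(x, w) {
  d2 <- outer(rowSums(x^2), rowSums(w^2), `+`) - 2 * tcrossprod(x, w)
  pmax(d2, 0)
}

#' Train a toroidal emergent self-organizing map
#'
#' Fits a batch SOM on the scaffold feature matrix. The map is toroidal (row
#' 0 wraps to the last row, likewise for columns), so bins are never
#' squeezed against a map border. Per epoch every row is assigned to its
#' best matching unit (BMU), then each neuron is set to the Gaussian-
#' neighborhood-weighted mean of all rows, with the neighborhood radius
#' decaying linearly from `radius_start` to `radius_end` on the toroidal
#' grid metric. With radius 0 an epoch is exactly one Lloyd k-means step
#' (neurons that attract no rows keep their weights). Weights are
#' initialized by sampling training rows, so the fit is deterministic given
#' `seed`.
#'
#' @param features Feature tibble from [build_feature_matrix()] (first
#'   column row ids, remaining columns numeric), or any numeric data frame
#'   shaped that way.
#' @param rows,cols Grid dimensions. The default sizes the map at roughly
#'   twice the number of training rows (capped at 4096 neurons), aspect
#'   1:1.6 — genuinely *emergent* maps need many neurons per cluster so that
#'   U-matrix ridges can close around each genome territory; the classical
#'   `5 * sqrt(n)` heuristic leaves far too few when dozens of genomes
#'   share the map.
#' @param epochs Training epochs (default 30).
#' @param radius_start Initial neighborhood radius; default half the larger
#'   grid dimension.
#' @param radius_end Final radius (default 0.3, tight enough that final
#'   epochs approach per-neuron k-means refinement).
#' @param seed Integer seed for the initialization.
#' @return An `esom` object: list with `weights` (neurons x features
#'   matrix), `rows`, `cols`, `grid` (neuron coordinates), `bmu` (tibble:
#'   scaffold_id, neuron, r, c, dist), quantization errors `qe_initial`,
#'   `qe_final`, and `config`.
#' @examples
#' m <- matrix(rnorm(200), 50, 4,
#'             dimnames = list(NULL, paste0("f", 1:4)))
#' feats <- tibble::tibble(scaffold_id = paste0("s", 1:50),
#'                         tibble::as_tibble(m))
#' model <- train_esom(feats, rows = 4, cols = 6, epochs = 5, seed = 1)
#' glance(model)
#' @export
train_esom <- function(features, rows = NULL, cols = NULL, epochs = 30,
                       radius_start = NULL, radius_end = 0.3, seed = 1) {
  x <- feature_values(features)
  if (anyNA(x) || any(!is.finite(x)))
    abort("feature matrix contains NA or non-finite values.")
  n <- nrow(x)
  if (n < 1) abort("feature matrix is empty.")
  if (epochs < 1) abort("`epochs` must be >= 1.")

  if (is.null(rows) || is.null(cols)) {
    n_neurons <- min(4096, max(64, 2 * n))
    rows <- max(2L, round(sqrt(n_neurons / 1.6)))
    cols <- max(2L, round(n_neurons / rows))
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  n_neurons <- rows * cols
  if (n_neurons < 4) abort("grid must have at least 4 neurons.")
  if (n_neurons > 50 * n)
    warn(sprintf("grid has %d neurons for only %d rows; map will be sparse.",
                 n_neurons, n))
  if (is.null(radius_start)) radius_start <- max(rows, cols) / 2

  w <- withr::with_seed(seed, {
    x[sample.int(n, n_neurons, replace = n_neurons > n), , drop = FALSE]
  })
  rownames(w) <- NULL

  gd2 <- grid_dist2(rows, cols)
  radii <- if (epochs == 1) radius_end else
    radius_start + (radius_end - radius_start) * (seq_len(epochs) - 1) / (epochs - 1)

  qe_initial <- NA_real_
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    d2 <- cross_dist2(x, w)
    bmu <- max.col(-d2, ties.method = "first")
    if (e == 1) qe_initial <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))

    r <- radii[e]
    h <- if (r > 0) exp(-gd2 / (2 * r^2)) else diag(n_neurons)
    a <- matrix(0, n, n_neurons)
    a[cbind(seq_len(n), bmu)] <- 1
    s <- crossprod(a, x)              # per-neuron row sums
    counts <- colSums(a)
    num <- h %*% s
    den <- as.vector(h %*% counts)
    upd <- den > 0
    w[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }

  d2 <- cross_dist2(x, w)
  bmu <- max.col(-d2, ties.method = "first")
  qe_final <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
  g <- grid_coords(rows, cols)

  structure(
    list(
      weights = w, rows = rows, cols = cols, grid = g,
      bmu = tibble(
        scaffold_id = rownames(x) %||% as.character(seq_len(n)),
        neuron = bmu, r = g$r[bmu], c = g$c[bmu],
        dist = sqrt(d2[cbind(seq_len(n), bmu)])
      ),
      qe_initial = qe_initial, qe_final = qe_final,
      config = list(epochs = epochs, radius_start = radius_start,
                    radius_end = radius_end, seed = seed)
    ),
    class = "esom"
  )
}

#' @export
print.esom <- function(x, ...) {
  cat(sprintf(
    "<esom> %d x %d toroidal map, %d features, %d rows mapped; QE %.4g -> %.4g\n",
    x$rows, x$cols, ncol(x$weights), nrow(x$bmu), x$qe_initial, x$qe_final))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-row BMU assignments of a trained map
#' @param x An `esom` model.
#' @param ... Unused.
#' @return Tibble with one row per training row: `scaffold_id`, `neuron`,
#'   grid coordinates `r`, `c`, and BMU `dist`.
#' @export
tidy.esom <- function(x, ...) x$bmu

#' One-row training summary of a trained map
#' @param x An `esom` model.
#' @param ... Unused.
#' @return Tibble with grid dimensions, epochs, and initial/final
#'   quantization error.
#' @export
glance.esom <- function(x, ...) {
  tibble(
    rows = x$rows, cols = x$cols, n_neurons = x$rows * x$cols,
    n = nrow(x$bmu), epochs = x$config$epochs,
    qe_initial = x$qe_initial, qe_final = x$qe_final
  )
}

# the 8 toroidal grid neighbors of each neuron (row-major indexing)
toroidal_neighbors <- function(rows, cols) {
  g <- grid_coords(rows, cols)
  offsets <- cbind(
    dr = rep(-1:1, times = 3), dc = rep(-1:1, each = 3))
  offsets <- offsets[!(offsets[, 1] == 0 & offsets[, 2] == 0), ]
  lapply(seq_len(rows * cols), function(i) {
    nr <- (g$r[i] + offsets[, 1]) %% rows
    nc <- (g$c[i] + offsets[, 2]) %% cols
    as.integer(nr * cols + nc + 1L)
  })
}

#' Compute the U-matrix of a trained map
#'
#' The unified distance matrix: each cell holds the mean Euclidean distance
#' from its neuron's weight vector to the weights of its 8 toroidal grid
#' neighbors. Low "valleys" are regions of similar neurons (clusters); high
#' "ridges" are cluster boundaries. Wraparound neighbors are used at every
#' edge.
#'
#' @param model A trained `esom`.
#' @return A `umatrix` tibble: `neuron`, `r`, `c`, `u` with attributes
#'   `rows`, `cols`.
#' @export
compute_umatrix <- function(model) {
  stopifnot(inherits(model, "esom"))
  nb <- toroidal_neighbors(model$rows, model$cols)
  w <- model$weights
  u <- vapply(seq_along(nb), function(i) {
    diff <- w[nb[[i]], , drop = FALSE] -
      matrix(w[i, ], length(nb[[i]]), ncol(w), byrow = TRUE)
    mean(sqrt(rowSums(diff^2)))
  }, numeric(1))
  out <- dplyr::mutate(model$grid, u = u)
  attr(out, "rows") <- model$rows
  attr(out, "cols") <- model$cols
  class(out) <- c("umatrix", class(out))
  out
}

#' Delineate genome bins from U-matrix valleys
#'
#' Automates the delineation that is done by hand (polygon selection) in
#' classic ESOM binning: neurons whose U-matrix value falls below the
#' `u_threshold_quantile` quantile of all U values are "valley" cells;
#' connected components of valley cells (8-connectivity with toroidal
#' wraparound) become candidate bins; every scaffold inherits the component
#' of its BMU. Scaffolds whose BMU is a ridge cell, or whose component holds
#' fewer than `min_bin_scaffolds` scaffolds, are left `UNBINNED`.
#'
#' The default valley quantile sits just below the site-percolation
#' threshold of an 8-neighbor square lattice (about 0.407): above it, valley
#' cells almost surely coalesce into one giant component that spans the
#' torus and merges unrelated bins, regardless of how well the map is
#' organized.
#'
#' @param model A trained `esom`.
#' @param umatrix Matching U-matrix from [compute_umatrix()] (computed if
#'   omitted).
#' @param u_threshold_quantile Valley quantile in (0, 1); default 0.40.
#' @param min_bin_scaffolds Minimum scaffolds per bin; default 5.
#' @return A bin assignment tibble: `scaffold_id`, `bin` (label or
#'   `"UNBINNED"`). Every input scaffold appears exactly once.
#' @export
delineate_bins <- function(model, umatrix = NULL,
                           u_threshold_quantile = 0.40,
                           min_bin_scaffolds = 5) {
  stopifnot(inherits(model, "esom"))
  if (is.null(umatrix)) umatrix <- compute_umatrix(model)
  if (!is.numeric(u_threshold_quantile) || u_threshold_quantile <= 0 ||
      u_threshold_quantile >= 1)
    abort("`u_threshold_quantile` must lie strictly in (0, 1).")
  if (attr(umatrix, "rows") != model$rows || attr(umatrix, "cols") != model$cols)
    abort("U-matrix grid does not match the model grid.")

  thr <- quantile(umatrix$u, u_threshold_quantile, names = FALSE)
  valley <- which(umatrix$u < thr)

  comp <- rep(NA_integer_, model$rows * model$cols)
  if (length(valley) > 0) {
    nb <- toroidal_neighbors(model$rows, model$cols)
    in_valley <- logical(model$rows * model$cols)
    in_valley[valley] <- TRUE
    edges <- purrr::map(valley, function(i) {
      j <- nb[[i]][in_valley[nb[[i]]]]
      if (length(j)) cbind(i, j) else NULL
    })
    edge_mat <- do.call(rbind, edges)
    gr <- igraph::graph_from_data_frame(
      d = if (is.null(edge_mat)) data.frame(from = character(), to = character())
          else data.frame(from = as.character(edge_mat[, 1]),
                          to = as.character(edge_mat[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(valley)))
    membership <- igraph::components(gr)$membership
    comp[as.integer(names(membership))] <- as.integer(membership)
  }

  bin_of_row <- comp[model$bmu$neuron]
  counts <- table(bin_of_row)
  small <- as.integer(names(counts)[counts < min_bin_scaffolds])
  bin_of_row[bin_of_row %in% small] <- NA_integer_

  labels <- sort(unique(bin_of_row[!is.na(bin_of_row)]))
  relabel <- setNames(zero_pad_ids("bin", length(labels)), labels)
  tibble(
    scaffold_id = model$bmu$scaffold_id,
    bin = ifelse(is.na(bin_of_row), "UNBINNED",
                 relabel[as.character(bin_of_row)])
  )
}

#' Score a bin assignment against a truth table
#'
#' Computes the adjusted Rand index (ARI) between the binning and the true
#' genome labels over binned scaffolds (UNBINNED scaffolds are excluded from
#' the ARI but reported as a fraction), plus per-bin precision and recall
#' against each bin's best-matching genome.
#'
#' @param assignment Tibble `scaffold_id`, `bin` from [delineate_bins()].
#' @param truth Tibble `scaffold_id`, `genome_id` (e.g.
#'   `community$truth$scaffold_genome`).
#' @return List with `ari`, `unbinned_fraction`, `n_bins`, and `per_bin`
#'   (tibble: bin, genome_id, n, precision, recall).
#' @export
evaluate_binning <- function(assignment, truth) {
  missing <- setdiff(assignment$scaffold_id, truth$scaffold_id)
  if (length(missing) > 0)
    abort(paste0("scaffold(s) without a truth label: ",
                 paste(head(missing, 5), collapse = ", ")))
  joined <- dplyr::inner_join(assignment, truth, by = "scaffold_id")
  binned <- joined[joined$bin != "UNBINNED", ]
  ari <- if (nrow(binned) == 0) NA_real_ else
    mclust::adjustedRandIndex(binned$bin, binned$genome_id)

  per_bin <- binned |>
    dplyr::count(.data$bin, .data$genome_id) |>
    dplyr::group_by(.data$bin) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::count(binned, .data$bin, name = "bin_size"),
                     by = "bin") |>
    dplyr::left_join(dplyr::count(joined, .data$genome_id,
                                  name = "genome_size"),
                     by = "genome_id") |>
    dplyr::mutate(precision = .data$n / .data$bin_size,
                  recall = .data$n / .data$genome_size) |>
    dplyr::select("bin", "genome_id", n = "bin_size", "precision", "recall")

  list(
    ari = ari,
    unbinned_fraction = mean(joined$bin == "UNBINNED"),
    n_bins = length(unique(binned$bin)),
    per_bin = per_bin
  )
}
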