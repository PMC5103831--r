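# Small in-code fixtures shared across test files.

# a quick community small enough for unit tests (short genomes)
small_community <- function(n_genomes = 3, n_samples = 4, seed = 11,
                            length_bp = 8e4, overrides = list(), ...) {
  overrides$length_bp <- overrides$length_bp %||% length_bp
  simulate_community(n_genomes, n_samples, seed, overrides = overrides, ...)
}

# feature tibble from a plain matrix
features_from_matrix <- function(x, ids = NULL) {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(scaffold_id = ids %||% paste0("s", seq_len(nrow(x)))),
    tibble::as_tibble(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two well-separated Gaussian blobs with labels
blob_features <- function(n_per = 200, d = 4, sep = 5, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d, 0), n_per, d),
               matrix(rnorm(n_per * d, sep), n_per, d))
  })
  list(
    features = features_from_matrix(x),
    truth = tibble::tibble(
      scaffold_id = paste0("s", seq_len(2 * n_per)),
      genome_id = rep(c("blob_a", "blob_b"), each = n_per))
  )
}

# long-format grouped measurements for one analyte
grouped_data <- function(values_by_group) {
  tibble::tibble(
    group = rep(names(values_by_group), lengths(values_by_group)),
    value = unlist(values_by_group, use.names = FALSE)
  )
}
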