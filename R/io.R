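# File-format readers and writers. All tables are tab-delimited UTF-8 with
# a header line; readers tolerate '#'-prefixed comment lines and CRLF line
# endings. Annotation coordinates are 1-based inclusive.

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that move between files and the named
#' character vectors used throughout the package. Sequences are written
#' wrapped at 80 columns; descriptions after the first whitespace in a
#' header are preserved on read ids.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @param type `"dna"` or `"aa"`.
#' @return `read_fasta()` returns a named character vector;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(sequences)
       else Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Read a scaffold FASTA into a scaffold table
#'
#' @param path FASTA path.
#' @return Tibble `scaffold_id`, `length`, `gc`, `sequence` (ids are the
#'   FASTA headers up to the first whitespace).
#' @export
read_scaffolds <- function(path) {
  seqs <- read_fasta(path, "dna")
  ids <- sub("\\s.*$", "", names(seqs))
  tibble(
    scaffold_id = ids,
    length = nchar(seqs),
    gc = gc_content(unname(seqs)),
    sequence = unname(seqs)
  )
}

#' Read and write tab-delimited tables
#'
#' `read_table_tsv()` tolerates '#' comment lines and CRLF endings;
#' `write_table_tsv()` always emits a header line.
#'
#' @param path File path.
#' @param x Data frame.
#' @param comment Optional character vector of comment lines written above
#'   the header (each prefixed with `# `).
#' @return `read_table_tsv()` returns a tibble; `write_table_tsv()` returns
#'   `path` invisibly.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a coverage table
#'
#' @param path TSV with `scaffold_id` and one numeric column per sample.
#' @param normalized Whether the stored values are already size-normalized.
#' @return Coverage tibble with the `normalized` attribute set.
#' @export
read_coverage <- function(path, normalized = FALSE) {
  out <- read_table_tsv(path)
  check_coverage(out)
  attr(out, "normalized") <- normalized
  out
}

#' Write all files of a synthetic community
#'
#' Emits scaffolds.fasta (80-column wrap), coverage.tsv, truth.tsv,
#' markers.tsv (1-based inclusive coordinates), rps3.faa, taxa.tsv and
#' design.json into `dir`.
#'
#' @param community A `synthetic_community`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(setNames(community$scaffolds$sequence,
                       community$scaffolds$scaffold_id),
              p("scaffolds.fasta"), "dna")
  write_table_tsv(community$coverage, p("coverage.tsv"),
                  comment = "raw fold coverage, one column per sample")
  write_table_tsv(community$truth$scaffold_genome, p("truth.tsv"),
                  comment = "scaffold_id -> source genome")
  write_table_tsv(community$markers, p("markers.tsv"),
                  comment = "single-copy marker loci, 1-based inclusive coordinates")
  write_fasta(community$rps3, p("rps3.faa"), "aa")
  write_table_tsv(community$rps3_map, p("taxa.tsv"),
                  comment = "rpS3 locus -> scaffold and taxon")
  design <- community$design
  jsonlite::write_json(
    list(n_genomes = design$n_genomes, n_samples = design$n_samples,
         depth_effect = design$depth_effect, seed = design$seed,
         read_length = design$read_length,
         samples = design$samples,
         genomes = design$genomes[, c("genome_id", "domain", "taxon",
                                      "length_bp", "gc_target")]),
    p("design.json"), auto_unbox = TRUE, digits = NA)
  files <- c(scaffolds = p("scaffolds.fasta"), coverage = p("coverage.tsv"),
             truth = p("truth.tsv"), markers = p("markers.tsv"),
             rps3 = p("rps3.faa"), taxa = p("taxa.tsv"),
             design = p("design.json"))
  invisible(files)
}

pipeline_defaults <- list(
  n_genomes = 20, n_samples = 10, depth_effect = 1,
  min_length = 8000, coverage_weight = 1, tetra_weight = NULL,
  rows = NULL, cols = NULL, epochs = 30, radius_end = 0.3,
  u_threshold_quantile = 0.40, min_bin_scaffolds = 5,
  duplication_cap = 0.10, mad_cutoff = 3.5,
  identity = 0.99, span = 0.60, alpha = 0.05
)

#' Validate a pipeline configuration
#'
#' Fills defaults and checks ranges. `seed` is mandatory: every stochastic
#' stage derives its randomness from it.
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return Validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  if (is.null(config$seed))
    abort("config is missing required field \"seed\".")
  cfg <- utils::modifyList(pipeline_defaults, config)
  if (cfg$u_threshold_quantile <= 0 || cfg$u_threshold_quantile >= 1)
    abort("`u_threshold_quantile` must lie in (0, 1).")
  if (cfg$identity <= 0 || cfg$identity > 1 || cfg$span <= 0 || cfg$span > 1)
    abort("`identity` and `span` must lie in (0, 1].")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    abort("`alpha` must lie in (0, 1).")
  cfg
}

#' Run the full binning and profiling pipeline
#'
#' Orchestrates: synthesize (unless a `community` is supplied) -> feature
#' matrix -> ESOM training -> U-matrix bin delineation -> marker-based QC
#' and contaminant refinement -> rpS3 species clustering and percent
#' abundances with phylum rollup -> Bray-Curtis PCoA. When `out_dir` is
#' given, every stage output is written there (TSV/FASTA/JSON) and listed in
#' the returned manifest; the run report records every parameter.
#'
#' @param config Named list (or YAML path) of parameters; see
#'   [validate_config()]. `seed` is required.
#' @param community Optional pre-built `synthetic_community` (overrides
#'   synthesis).
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages (default TRUE).
#' @return List with `community`, `features`, `model`, `umatrix`, `bins`
#'   (refined assignment), `bin_quality`, `flags`, `clusters`, `abundance`,
#'   `phylum_abundance`, `braycurtis`, `pcoa`, `evaluation`, `report`.
#' @export
run_pipeline <- function(config, community = NULL, out_dir = NULL,
                         quiet = TRUE) {
  cfg <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(config = cfg, stages = list(), files = character())

  say("synthesizing community (seed %d)...", cfg$seed)
  if (is.null(community)) {
    community <- simulate_community(cfg$n_genomes, cfg$n_samples, cfg$seed,
                                    overrides = cfg$overrides %||% list())
  }
  report$stages$synthesize <- list(
    n_scaffolds = nrow(community$scaffolds),
    n_genomes = community$design$n_genomes,
    n_samples = community$design$n_samples)

  say("building feature matrix...")
  norm_cov <- normalize_coverage(community$coverage)
  # default tetra weight balances the expected row norms of the two
  # unit-sum blocks (1/sqrt(d) each) so neither dominates the SOM metric
  n_samples <- ncol(community$coverage) - 1L
  tetra_weight <- cfg$tetra_weight %||% sqrt(256 / n_samples)
  features <- build_feature_matrix(
    community$scaffolds, norm_cov, min_length = cfg$min_length,
    coverage_weight = cfg$coverage_weight, tetra_weight = tetra_weight)
  report$stages$features <- list(
    n_rows = nrow(features), n_cols = ncol(features) - 1L)

  say("training ESOM...")
  model <- train_esom(features, rows = cfg$rows, cols = cfg$cols,
                      epochs = cfg$epochs, radius_end = cfg$radius_end,
                      seed = cfg$seed)
  umatrix <- compute_umatrix(model)
  bins0 <- delineate_bins(model, umatrix,
                          u_threshold_quantile = cfg$u_threshold_quantile,
                          min_bin_scaffolds = cfg$min_bin_scaffolds)
  report$stages$esom <- c(as.list(glance(model)),
                          n_bins = length(setdiff(unique(bins0$bin),
                                                  "UNBINNED")))

  say("bin QC...")
  flags <- flag_contaminants(bins0, community$scaffolds, norm_cov,
                             taxa = dplyr::left_join(
                               community$truth$scaffold_genome,
                               community$truth$genome_info[, c("genome_id", "taxon")],
                               by = "genome_id")[, c("scaffold_id", "taxon")],
                             mad_cutoff = cfg$mad_cutoff)
  bins <- refine_bins(bins0, flags)
  bin_quality <- assess_bins(bins, community$markers,
                             duplication_cap = cfg$duplication_cap)
  evaluation <- evaluate_binning(bins, community$truth$scaffold_genome)
  report$stages$qc <- list(
    n_flagged = nrow(flags),
    n_draft_quality = sum(bin_quality$draft_quality),
    ari = evaluation$ari,
    unbinned_fraction = evaluation$unbinned_fraction)

  say("community profile...")
  clusters <- cluster_species(community$rps3, identity = cfg$identity,
                              span = cfg$span)
  abundance <- abundance_table(clusters, norm_cov, community$rps3_map)
  phylum_abundance <- phylum_rollup(abundance)
  braycurtis <- bray_curtis_matrix(abundance)
  pcoa <- pcoa_ordination(braycurtis, k = 2)
  report$stages$profile <- list(
    n_clusters = length(unique(clusters$members$cluster_id)),
    n_excluded = length(clusters$excluded),
    n_phyla = nrow(phylum_abundance))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_community(community, file.path(out_dir, "community"))
    p <- function(f) file.path(out_dir, f)
    write_table_tsv(features, p("features.tsv"),
                    comment = sprintf("coverage block: %s | tetra block: 256 4-mers",
                                      paste(attr(features, "coverage_cols"),
                                            collapse = " ")))
    w <- as_tibble(model$weights, .name_repair = "minimal")
    names(w) <- colnames(features)[-1]
    write_table_tsv(dplyr::bind_cols(model$grid, w), p("weights.tsv"))
    write_table_tsv(umatrix, p("umatrix.tsv"))
    write_table_tsv(bins, p("bins.tsv"))
    write_table_tsv(flags, p("flags.tsv"))
    write_table_tsv(dplyr::select(bin_quality, -"copy_counts"),
                    p("bin_quality.tsv"))
    write_table_tsv(clusters$members, p("clusters.tsv"))
    write_table_tsv(abundance, p("abundance.tsv"))
    write_table_tsv(phylum_abundance, p("phylum_abundance.tsv"))
    write_table_tsv(as_tibble(braycurtis, rownames = "sample_id"),
                    p("braycurtis.tsv"))
    write_table_tsv(pcoa$coordinates, p("pcoa.tsv"))
    report$files <- c(files, features = p("features.tsv"),
                      weights = p("weights.tsv"), umatrix = p("umatrix.tsv"),
                      bins = p("bins.tsv"), flags = p("flags.tsv"),
                      bin_quality = p("bin_quality.tsv"),
                      clusters = p("clusters.tsv"),
                      abundance = p("abundance.tsv"),
                      phylum_abundance = p("phylum_abundance.tsv"),
                      braycurtis = p("braycurtis.tsv"), pcoa = p("pcoa.tsv"))
    report$versions <- list(
      seriesbin = as.character(utils::packageVersion("seriesbin")),
      r = R.version.string)
    jsonlite::write_json(
      report[c("config", "stages", "files", "versions")],
      p("run_report.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    report$files <- c(report$files, report = p("run_report.json"))
  }

  list(community = community, features = features, model = model,
       umatrix = umatrix, bins = bins, bin_quality = bin_quality,
       flags = flags, clusters = clusters, abundance = abundance,
       phylum_abundance = phylum_abundance, braycurtis = braycurtis,
       pcoa = pcoa, evaluation = evaluation, report = report)
}
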