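#' Design a synthetic soil community
#'
#' Lays out a seeded multi-genome, multi-sample community emulating the
#' statistical structure of a time/depth-resolved soil metagenome series:
#' several genomes with genome-specific order-3 Markov composition (so their
#' tetranucleotide signatures are separable), log-normal abundance profiles
#' with a shared depth preference per genome (within-depth correlation), and
#' per-sample sequencing-depth factors. By default samples alternate between
#' a shallow (10-20 cm) and a deep (30-40 cm) horizon until the deep quota
#' (40% of samples) is filled, so ten samples split six shallow / four deep.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed; all downstream generation is deterministic given
#'   the design (the seed is stored in it).
#' @param overrides Named list overriding defaults. Recognised entries:
#'   `length_bp` (scalar or per-genome vector), `gc_target` (scalar/vector),
#'   `domain` (character scalar/vector, `"bacteria"`/`"archaea"`),
#'   `taxon` (character vector per genome), `depth_effect` (log-scale
#'   abundance shift between depth horizons, default 1), `archaea_fraction`
#'   (default 0.2), `read_length` (default 250), `markov_order` (default 3),
#'   `signature_strength` (Beta concentration for per-context base splits;
#'   smaller = stronger genome signatures, default 1), `mu_log_abundance`
#'   (default log(8)), `sd_log_abundance` (default 0.7), `sd_within`
#'   (per-sample log-abundance noise, default 1 — abundance series vary
#'   strongly between time points, as in rain-perturbed soil),
#'   `sd_depth_factor` (default 0.15).
#' @return A `community_design` object: a list with `genomes` (tibble:
#'   genome_id, domain, taxon, length_bp, gc_target, markov_order,
#'   transition_seed), `samples` (tibble: sample_id, depth, timepoint,
#'   depth_factor), `abundance` (tibble: genome_id + one column of true mean
#'   fold-coverage per sample), and scalars `n_genomes`, `n_samples`,
#'   `depth_effect`, `read_length`, `signature_strength`, `seed`.
#' @examples
#' design <- design_community(3, 4, seed = 1)
#' design$samples
#' @export
design_community <- function(n_genomes, n_samples = 10, seed,
                             overrides = list()) {
  if (!is.numeric(n_genomes) || length(n_genomes) != 1 || n_genomes < 1)
    abort("`n_genomes` must be a single integer >= 1.")
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1)
    abort("`n_samples` must be a single integer >= 1.")
  if (missing(seed) || !is.numeric(seed))
    abort("`seed` is required and must be an integer.")
  n_genomes <- as.integer(n_genomes)
  n_samples <- as.integer(n_samples)
  seed <- as.integer(seed)

  opt <- function(name, default) overrides[[name]] %||% default
  depth_effect <- opt("depth_effect", 1)
  read_length <- opt("read_length", 250L)
  markov_order <- opt("markov_order", 3L)
  signature_strength <- opt("signature_strength", 1)
  archaea_fraction <- opt("archaea_fraction", 0.2)

  bacterial_phyla <- c(
    "Proteobacteria", "Acidobacteria", "Verrucomicrobia", "Actinobacteria",
    "Gemmatimonadetes", "Chloroflexi", "Rokubacteria", "Nitrospirae",
    "Bacteroidetes", "Armatimonadetes"
  )
  archaeal_phyla <- c("Bathyarchaeota", "Thaumarchaeota", "Euryarchaeota")

  withr::with_seed(seed, {
    # sample layout: alternate shallow/deep until the deep quota is met
    n_deep <- floor(0.4 * n_samples)
    depth <- rep("shallow", n_samples)
    if (n_deep > 0) {
      idx <- seq_len(min(n_samples, 2L * n_deep))
      depth[idx[idx %% 2 == 0]] <- "deep"
    }
    samples <- tibble(
      sample_id = zero_pad_ids("S", n_samples),
      depth = depth,
      timepoint = paste0("T", ceiling(seq_len(n_samples) / 2)),
      depth_factor = opt("sample_depth_factors",
                         rlnorm(n_samples, 0, opt("sd_depth_factor", 0.15)))
    )

    domain <- opt("domain",
                  ifelse(runif(n_genomes) < archaea_fraction,
                         "archaea", "bacteria"))
    domain <- rep_len(domain, n_genomes)
    taxon <- opt("taxon", ifelse(
      domain == "archaea",
      sample(archaeal_phyla, n_genomes, replace = TRUE),
      sample(bacterial_phyla, n_genomes, replace = TRUE)
    ))
    genomes <- tibble(
      genome_id = zero_pad_ids("G", n_genomes),
      domain = domain,
      taxon = rep_len(taxon, n_genomes),
      length_bp = as.integer(rep_len(
        opt("length_bp", round(runif(n_genomes, 1.8e6, 2.6e6))), n_genomes)),
      gc_target = rep_len(opt("gc_target", runif(n_genomes, 0.35, 0.65)),
                          n_genomes),
      markov_order = as.integer(markov_order),
      transition_seed = sample.int(.Machine$integer.max - 1L, n_genomes)
    )
    if (any(genomes$length_bp < 50000))
      abort("every `length_bp` must be >= 50,000.")
    if (any(genomes$gc_target <= 0.2 | genomes$gc_target >= 0.8))
      abort("every `gc_target` must lie in (0.2, 0.8).")

    # log-normal abundances: genome baseline + genome-specific depth shift
    mu <- rnorm(n_genomes, opt("mu_log_abundance", log(8)),
                opt("sd_log_abundance", 0.7))
    delta <- rnorm(n_genomes, 0, depth_effect)
    eps <- matrix(rnorm(n_genomes * n_samples, 0, opt("sd_within", 1)),
                  n_genomes, n_samples)
    is_deep <- as.numeric(samples$depth == "deep")
    log_ab <- outer(mu, rep(1, n_samples)) +
      outer(delta, is_deep) + eps
    ab <- exp(log_ab)
    colnames(ab) <- samples$sample_id
    abundance <- dplyr::bind_cols(
      tibble(genome_id = genomes$genome_id), as_tibble(ab))

    structure(
      list(
        genomes = genomes, samples = samples, abundance = abundance,
        n_genomes = n_genomes, n_samples = n_samples,
        depth_effect = depth_effect, read_length = as.integer(read_length),
        signature_strength = signature_strength, seed = seed
      ),
      class = "community_design"
    )
  })
}

#' @export
print.community_design <- function(x, ...) {
  cat(sprintf(
    "<community_design> %d genomes x %d samples (%d shallow / %d deep), seed %d\n",
    x$n_genomes, x$n_samples, sum(x$samples$depth == "shallow"),
    sum(x$samples$depth == "deep"), x$seed))
  invisible(x)
}

# Per-context transition rows with P(G)+P(C) fixed at gc_target, so the
# genome-wide GC is pinned while the within-GC / within-AT splits carry the
# genome-specific tetranucleotide signature.
markov_transitions <- function(gc_target, order, strength) {
  n_ctx <- 4L^order
  u <- rbeta(n_ctx, strength, strength)  # C share of the GC mass
  v <- rbeta(n_ctx, strength, strength)  # A share of the AT mass
  cbind(
    A = (1 - gc_target) * v,
    C = gc_target * u,
    G = gc_target * (1 - u),
    T = (1 - gc_target) * (1 - v)
  )
}

#' Generate genome sequences for a community design
#'
#' Draws each genome from its own seeded order-3 (by default) Markov chain
#' over \{A,C,G,T\}. Every transition row carries probability mass
#' `gc_target` on G+C, so the realized GC content is tightly pinned to the
#' target, while the per-context split of that mass between G vs C (and A vs
#' T) is genome-specific — this is what makes tetranucleotide signatures
#' separable between genomes.
#'
#' @param design A `community_design`.
#' @return Named character vector, genome_id -> DNA string.
#' @examples
#' design <- design_community(2, 2, seed = 1, overrides = list(length_bp = 6e4))
#' nchar(generate_genome_sequences(design))
#' @export
generate_genome_sequences <- function(design) {
  stopifnot(inherits(design, "community_design"))
  g <- design$genomes
  seqs <- purrr::map_chr(seq_len(nrow(g)), function(i) {
    withr::with_seed(g$transition_seed[i], {
      tr <- markov_transitions(g$gc_target[i], g$markov_order[i],
                               design$signature_strength)
      init <- c((1 - g$gc_target[i]) / 2, g$gc_target[i] / 2,
                g$gc_target[i] / 2, (1 - g$gc_target[i]) / 2)
      sample_markov_sequence(tr, g$length_bp[i], g$markov_order[i], init)
    })
  })
  setNames(seqs, g$genome_id)
}

#' Fragment genomes into scaffolds and simulate a coverage table
#'
#' Cuts every genome into non-overlapping scaffolds with log-normal lengths
#' (minimum enforced), simulates per-scaffold per-sample fold coverage as
#' negative-binomial read counts (mean = true abundance x sample depth factor
#' x scaffold length / read length) converted back to fold coverage, plants
#' the full domain-appropriate single-copy marker set (51 bacterial / 38
#' archaeal loci) uniformly at random across each genome's scaffolds, places
#' one rpS3 locus per genome, and emits the complete truth table.
#'
#' rpS3 amino-acid sequences (length 220) descend from a common root through
#' a per-taxon ancestor, with per-genome divergence `rps3_divergence`;
#' identical-taxon genomes are therefore more similar to each other than to
#' other taxa, and small divergences exercise cluster merging.
#'
#' @param design A `community_design`.
#' @param genomes Named DNA string vector from [generate_genome_sequences()].
#' @param min_scaffold Minimum scaffold length in bp (default 1000).
#' @param scaffold_meanlog,scaffold_sdlog Log-normal scaffold length
#'   parameters (defaults `log(12000)` and 0.6, giving a sizeable fraction of
#'   scaffolds above the 8 kb binning gate).
#' @param dispersion Negative-binomial dispersion of read counts (default
#'   0.2; variance = mu + dispersion * mu^2). Coverage from read mapping is
#'   overdispersed relative to Poisson.
#' @param rps3_divergence Per-genome amino-acid divergence from the taxon
#'   ancestor (default 0.04, placing distinct genomes below the 99% species
#'   threshold).
#' @return A `synthetic_community` object: list with `scaffolds` (tibble:
#'   scaffold_id, genome_id, length, gc, sequence), `coverage` (raw wide
#'   coverage tibble: scaffold_id + one column per sample), `truth` (list
#'   with `scaffold_genome`, `genome_info`, `abundance`), `markers` (tibble:
#'   scaffold_id, start, end, marker_id, genome_id; 1-based inclusive),
#'   `rps3` (named amino-acid string vector), `rps3_map` (tibble: rps3_id,
#'   scaffold_id, genome_id, taxon), and the `design`.
#' @examples
#' design <- design_community(2, 3, seed = 5, overrides = list(length_bp = 8e4))
#' com <- fragment_and_cover(design, generate_genome_sequences(design))
#' head(com$coverage)
#' @export
fragment_and_cover <- function(design, genomes,
                               min_scaffold = 1000,
                               scaffold_meanlog = log(12000),
                               scaffold_sdlog = 0.6,
                               dispersion = 0.2,
                               rps3_divergence = 0.04) {
  stopifnot(inherits(design, "community_design"))
  if (!all(design$genomes$genome_id %in% names(genomes)))
    abort("`genomes` must contain a sequence for every genome in the design.")

  g <- design$genomes
  samples <- design$samples
  ab <- as.matrix(design$abundance[, samples$sample_id, drop = FALSE])
  rownames(ab) <- design$abundance$genome_id

  withr::with_seed(design$seed + 1L, {
    # --- fragmentation --------------------------------------------------
    scaffold_rows <- purrr::map(seq_len(nrow(g)), function(i) {
      gid <- g$genome_id[i]
      seq_i <- genomes[[gid]]
      L <- nchar(seq_i)
      lens <- integer(0)
      pos <- 0L
      while (pos < L) {
        len <- max(min_scaffold,
                   round(rlnorm(1, scaffold_meanlog, scaffold_sdlog)))
        if (pos + len > L) {
          rem <- L - pos
          if (rem >= min_scaffold) lens <- c(lens, rem)
          break
        }
        lens <- c(lens, as.integer(len))
        pos <- pos + as.integer(len)
      }
      if (length(lens) == 0)
        abort(sprintf("genome %s is too short to yield any scaffold >= %d bp.",
                      gid, min_scaffold))
      starts <- cumsum(c(1L, head(lens, -1)))
      tibble(
        genome_id = gid,
        start = starts, length = lens,
        sequence = stringr::str_sub(seq_i, starts, starts + lens - 1L)
      )
    })
    scaffolds <- dplyr::bind_rows(scaffold_rows)
    scaffolds$scaffold_id <- zero_pad_ids("scaffold", nrow(scaffolds))
    scaffolds$gc <- gc_content(scaffolds$sequence)
    scaffolds <- dplyr::select(scaffolds, "scaffold_id", "genome_id",
                               "length", "gc", "sequence")

    # --- coverage: NB read counts -> fold coverage ----------------------
    n_sc <- nrow(scaffolds)
    mu_fold <- ab[scaffolds$genome_id, , drop = FALSE] *
      rep(samples$depth_factor, each = n_sc)
    mu_reads <- mu_fold * scaffolds$length / design$read_length
    reads <- matrix(
      rnbinom(length(mu_reads), size = 1 / dispersion, mu = as.vector(mu_reads)),
      nrow = n_sc
    )
    fold <- reads * design$read_length / scaffolds$length
    colnames(fold) <- samples$sample_id
    coverage <- dplyr::bind_cols(
      tibble(scaffold_id = scaffolds$scaffold_id), as_tibble(fold))
    attr(coverage, "normalized") <- FALSE

    # --- marker loci (annotations, uniform over scaffolds) --------------
    markers <- dplyr::bind_rows(purrr::map(seq_len(nrow(g)), function(i) {
      gid <- g$genome_id[i]
      ids <- marker_set(g$domain[i])
      sc <- scaffolds[scaffolds$genome_id == gid, ]
      host <- sample(nrow(sc), length(ids), replace = TRUE)
      locus_len <- pmin(900L, sc$length[host])
      start <- purrr::map2_int(sc$length[host], locus_len,
                               ~ sample.int(.x - .y + 1L, 1))
      tibble(
        scaffold_id = sc$scaffold_id[host],
        start = start, end = start + locus_len - 1L,
        marker_id = ids, genome_id = gid
      )
    }))

    # --- rpS3 amino-acid sequences --------------------------------------
    aa <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
    root <- paste(sample(aa, 220, replace = TRUE), collapse = "")
    taxa <- unique(g$taxon)
    taxon_anc <- setNames(
      purrr::map_chr(taxa, ~ mutate_aa(root, 0.25, aa)), taxa)
    rps3 <- setNames(
      purrr::map_chr(seq_len(nrow(g)),
                     ~ mutate_aa(taxon_anc[[g$taxon[.x]]],
                                 rps3_divergence, aa)),
      paste0("rps3_", g$genome_id))
    rps3_host <- purrr::map_chr(g$genome_id, function(gid) {
      sc <- scaffolds$scaffold_id[scaffolds$genome_id == gid]
      sc[sample.int(length(sc), 1)]
    })
    rps3_map <- tibble(
      rps3_id = names(rps3),
      scaffold_id = rps3_host,
      genome_id = g$genome_id,
      taxon = g$taxon
    )

    truth <- list(
      scaffold_genome = dplyr::select(scaffolds, "scaffold_id", "genome_id"),
      genome_info = dplyr::left_join(
        dplyr::select(g, "genome_id", "domain", "taxon"),
        dplyr::select(rps3_map, "genome_id", "rps3_id"),
        by = "genome_id"),
      abundance = design$abundance
    )

    structure(
      list(scaffolds = scaffolds, coverage = coverage, truth = truth,
           markers = markers, rps3 = rps3, rps3_map = rps3_map,
           design = design),
      class = "synthetic_community"
    )
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "<synthetic_community> %d scaffolds from %d genomes x %d samples (%d scaffolds > 8 kb)\n",
    nrow(x$scaffolds), x$design$n_genomes, x$design$n_samples,
    sum(x$scaffolds$length > 8000)))
  invisible(x)
}

mutate_aa <- function(sequence, rate, alphabet) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

gc_content <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  freq <- Biostrings::letterFrequency(x, letters = c("G", "C"))
  as.numeric(rowSums(freq) / Biostrings::width(x))
}

#' Simulate a complete synthetic community in one call
#'
#' Convenience wrapper chaining [design_community()],
#' [generate_genome_sequences()] and [fragment_and_cover()].
#'
#' @inheritParams design_community
#' @param ... Passed to [fragment_and_cover()] (`min_scaffold`, `dispersion`,
#'   `scaffold_meanlog`, `scaffold_sdlog`, `rps3_divergence`).
#' @return A `synthetic_community` (see [fragment_and_cover()]).
#' @export
simulate_community <- function(n_genomes, n_samples = 10, seed,
                               overrides = list(), ...) {
  design <- design_community(n_genomes, n_samples, seed, overrides)
  fragment_and_cover(design, generate_genome_sequences(design), ...)
}
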