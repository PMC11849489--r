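# Synthetic data generators -------------------------------------------------
#
# Seeded generators for repertoires, multi-group cohorts with motif
# spike-ins, and annotation references, emulating the statistical structure
# the analyses assume: IMGT-conformant CDR3s (C...F/W anchors), heavy-tailed
# (power-law) clone sizes, weighted V/J usage, and group-specific 3-mer
# motifs inserted into a stated fraction of clones.

#' Simulation configuration
#'
#' @param n_clones Number of unique clonotypes to generate.
#' @param length_range Two integers within 8..24; CDR3 lengths are drawn
#'   uniformly from this range (default 10..18, the central TRB range).
#' @param clone_size_law `"power_law"` (discrete Pareto, heavy-tailed),
#'   `"geometric"`, or `"constant"` (all counts 1, a perfectly even
#'   repertoire).
#' @param law_param Power-law exponent (default 2, truncated at count 1)
#'   or geometric success probability.
#' @param v_genes,j_genes Named numeric vectors: gene symbol to usage
#'   weight.
#' @param spike_motifs Named numeric vector: 3-mer motif to per-clone
#'   insertion probability (e.g. `c(GTG = 0.3)`); `NULL` for none.
#' @param seed Integer RNG seed (one stream per generator invocation).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_clones = 1000,
                              length_range = c(10, 18),
                              clone_size_law = c("power_law", "geometric",
                                                 "constant"),
                              law_param = 2,
                              v_genes = default_v_genes(),
                              j_genes = default_j_genes(),
                              spike_motifs = NULL,
                              seed = 1) {
  clone_size_law <- match.arg(clone_size_law)
  stopifnot(
    n_clones >= 1,
    length(length_range) == 2,
    length_range[1] >= 8, length_range[2] <= 24,
    length_range[1] <= length_range[2]
  )
  if (!is.null(spike_motifs)) {
    stopifnot(!is.null(names(spike_motifs)),
              all(nchar(names(spike_motifs)) == 3),
              all(spike_motifs >= 0 & spike_motifs <= 1))
  }
  if (length(v_genes) == 0 || length(j_genes) == 0) {
    abort("v_genes and j_genes must be non-empty.",
          class = "tcr_config_error")
  }
  structure(
    list(
      n_clones = as.integer(n_clones),
      length_range = as.integer(length_range),
      clone_size_law = clone_size_law,
      law_param = law_param,
      v_genes = v_genes,
      j_genes = j_genes,
      spike_motifs = spike_motifs,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

default_v_genes <- function() {
  g <- c("TRBV2", "TRBV5-1", "TRBV6-5", "TRBV7-2", "TRBV7-9", "TRBV9",
         "TRBV12-3", "TRBV19", "TRBV20-1", "TRBV27", "TRBV28", "TRBV30")
  setNames(c(4, 8, 7, 6, 6, 5, 5, 6, 10, 5, 6, 3), g)
}

default_j_genes <- function() {
  g <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-3", "TRBJ2-5",
         "TRBJ2-7")
  setNames(c(8, 6, 5, 12, 7, 6, 14), g)
}

# Random IMGT-conformant CDR3s: C anchor, interior uniform over the 20
# letters, F/W C-terminal anchor at 0.9/0.1.
random_cdr3 <- function(n, length_range) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(l) {
    paste0(
      "C",
      paste(sample(AA20, l - 2, replace = TRUE), collapse = ""),
      sample(c("F", "W"), 1, prob = c(0.9, 0.1))
    )
  }, character(1))
}

# Insert a motif over a random interior window (never touching the anchor
# positions 1 and L).
insert_motif <- function(seq, motif) {
  l <- nchar(seq)
  k <- nchar(motif)
  start <- sample(seq(2, l - k), 1)
  paste0(substr(seq, 1, start - 1), motif, substr(seq, start + k, l))
}

draw_counts <- function(n, law, param) {
  switch(law,
    power_law = pmax(1L, as.integer(floor(runif(n)^(-1 / (param - 1))))),
    geometric = rgeom(n, prob = param) + 1L,
    constant = rep(1L, n)
  )
}

#' Simulate a repertoire
#'
#' Generates `n_clones` unique, QC-clean CDR3 clonotypes under the
#' configuration: every sequence passes [validate_cdr3()] by construction
#' and V/J genes are always present, so [apply_qc()] drops nothing.
#' Deterministic for a fixed config (including its seed).
#'
#' @param config A [simulation_config()].
#' @param sample_id Sample identifier.
#' @param metadata Metadata list attached to the repertoire.
#' @return A `tcr_repertoire`.
#' @export
simulate_repertoire <- function(config = simulation_config(),
                                sample_id = "sim", metadata = list()) {
  withr::with_seed(config$seed, {
    seqs <- character(0)
    while (length(seqs) < config$n_clones) {
      batch <- random_cdr3(config$n_clones - length(seqs) + 50,
                           config$length_range)
      if (!is.null(config$spike_motifs)) {
        for (motif in names(config$spike_motifs)) {
          hit <- runif(length(batch)) < config$spike_motifs[[motif]]
          batch[hit] <- vapply(batch[hit], insert_motif, character(1),
                               motif = motif)
        }
      }
      seqs <- unique(c(seqs, batch))
    }
    seqs <- seqs[seq_len(config$n_clones)]
    repertoire(
      cdr3_aa = seqs,
      v_gene = sample(names(config$v_genes), config$n_clones,
                      replace = TRUE, prob = config$v_genes),
      j_gene = sample(names(config$j_genes), config$n_clones,
                      replace = TRUE, prob = config$j_genes),
      count = draw_counts(config$n_clones, config$clone_size_law,
                          config$law_param),
      sample_id = sample_id,
      metadata = metadata
    )
  })
}

#' Simulate a labelled cohort with group-specific motif spike-ins
#'
#' Each group's samples receive that group's spike motifs; a group named
#' `"healthy"` never receives spikes. Per-sample seeds are drawn from one
#' stream seeded by `seed`, so the whole cohort is reproducible.
#'
#' @param n_per_group Named integer vector: group label to number of
#'   samples (at least 2 groups for embedding workflows).
#' @param base_config A [simulation_config()] supplying everything except
#'   spikes and seeds.
#' @param spike_motifs Named list: group label to named numeric vector of
#'   motif insertion probabilities (e.g.
#'   `list(A = c(GTG = 0.3), B = c(WQW = 0.3))`). Motifs shared between
#'   groups are allowed but logged.
#' @param seed Integer seed for the cohort stream.
#' @return List with `repertoires` (named list of `tcr_repertoire`) and
#'   `labels` (named character vector, sample id to group).
#' @export
simulate_cohort <- function(n_per_group, base_config = simulation_config(),
                            spike_motifs = list(), seed = 1) {
  stopifnot(!is.null(names(n_per_group)), all(n_per_group >= 1))
  shared <- unlist(purrr::map(spike_motifs, names))
  if (anyDuplicated(shared)) {
    message(sprintf("spike motif(s) shared across groups: %s",
                    paste(unique(shared[duplicated(shared)]), collapse = ", ")))
  }
  total <- sum(n_per_group)
  sample_seeds <- withr::with_seed(seed, sample.int(2^31 - 1, total))
  i <- 0L
  reps <- list()
  labels <- character(0)
  for (group in names(n_per_group)) {
    spikes <- if (group == "healthy") NULL else spike_motifs[[group]]
    for (j in seq_len(n_per_group[[group]])) {
      i <- i + 1L
      id <- sprintf("%s_%02d", group, j)
      cfg <- base_config
      cfg$spike_motifs <- spikes
      cfg$seed <- sample_seeds[i]
      reps[[id]] <- simulate_repertoire(cfg, sample_id = id,
                                        metadata = list(group = group))
      labels[id] <- group
    }
  }
  list(repertoires = reps, labels = labels)
}

#' Simulate an annotation reference
#'
#' Random QC-valid CDR3 records with uniformly assigned condition, cell
#' type, and cell source. When `planted_queries` is given, the reference
#' additionally contains, for each planted sequence, an exact copy
#' (distance 0) and a one-substitution interior variant (distance 1), so
#' expected fuzzy-search hits are known by construction. This is a
#' synthetic stand-in sharing the schema of curated TCR databases, not
#' real annotation data.
#'
#' @param n_records Number of random records (>= 1).
#' @param conditions,cell_types,cell_sources Label pools.
#' @param seed Integer seed.
#' @param planted_queries Optional character vector of valid CDR3s to
#'   plant.
#' @return Tibble of reference records.
#' @export
simulate_reference <- function(n_records,
                               conditions = c("melanoma", "COVID-19",
                                              "NSCLC"),
                               cell_types = c("CD8+", "CD4+", "T cell"),
                               cell_sources = c("PBMC", "TIL", "blood"),
                               seed = 1,
                               planted_queries = NULL) {
  stopifnot(n_records >= 1)
  withr::with_seed(seed, {
    seqs <- unique(random_cdr3(n_records + 100, c(10, 18)))[seq_len(n_records)]
    planted <- character(0)
    if (!is.null(planted_queries)) {
      variants <- vapply(toupper(planted_queries), function(q) {
        pos <- sample(seq(2, nchar(q) - 1), 1)
        old <- substr(q, pos, pos)
        new <- sample(setdiff(AA20, old), 1)
        paste0(substr(q, 1, pos - 1), new, substr(q, pos + 1, nchar(q)))
      }, character(1))
      planted <- c(toupper(planted_queries), unname(variants))
    }
    all_seqs <- c(planted, seqs)
    tibble::tibble(
      cdr3_aa = all_seqs,
      v_gene = sample(names(default_v_genes()), length(all_seqs),
                      replace = TRUE),
      j_gene = sample(names(default_j_genes()), length(all_seqs),
                      replace = TRUE),
      condition = sample(conditions, length(all_seqs), replace = TRUE),
      cell_type = sample(cell_types, length(all_seqs), replace = TRUE),
      cell_source = sample(cell_sources, length(all_seqs), replace = TRUE),
      provenance = "synthetic"
    )
  })
}
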