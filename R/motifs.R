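# 3-mer motif features and embedding ----------------------------------------
#
# Workflow: sliding-window k-mer decomposition (k = 3), samples x motifs
# count matrix, sample-total filter (drop top/bottom 20%), group prevalence
# filter (motif present in > 50% of disease samples), Mann-Whitney
# disease-specificity filter against a healthy cohort (keep P <= 0.05),
# per-motif Z-score normalization, and a diffusion-map embedding with
# Nystrom-style out-of-sample projection.

MOTIF_STAGES <- c("raw", "sample_filtered", "prevalence_filtered",
                  "mwu_filtered", "normalized")

#' Count k-mer motifs in a repertoire
#'
#' Sliding window with step 1: a sequence of length L contributes
#' L - k + 1 windows (sequences shorter than k contribute none). With
#' `weighted = TRUE` each window is multiplied by the clone count.
#'
#' @param rep A `tcr_repertoire` (QC-passed in the standard workflow).
#' @param k Word length (default 3).
#' @param weighted Multiply window counts by clone counts.
#' @return Tibble with columns `motif`, `count`, sorted by motif.
#' @export
count_kmers <- function(rep, k = 3, weighted = FALSE) {
  stopifnot(k >= 1)
  seqs <- rep$cdr3_aa
  w <- if (weighted) rep$count else rep(1, length(seqs))
  lens <- nchar(seqs)
  short <- lens < k
  if (any(short)) {
    message(sprintf("%d sequence(s) shorter than k = %d contribute no windows.",
                    sum(short), k))
  }
  keep <- which(!short)
  if (!length(keep)) {
    return(tibble::tibble(motif = character(), count = numeric()))
  }
  windows <- purrr::map(keep, function(i) {
    l <- lens[i]
    substring(seqs[i], 1:(l - k + 1), k:l)
  })
  tall <- tibble::tibble(
    motif = unlist(windows),
    w = base::rep(w[keep], lens[keep] - k + 1)
  )
  tall |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(count = sum(.data$w), .groups = "drop") |>
    dplyr::arrange(.data$motif)
}

#' Build a samples-by-motifs count matrix
#'
#' Columns are the union of motifs observed across samples (absent motif:
#' 0); the motif universe is bounded above by `20^k` (8000 for the default
#' 3-mers). The result records its processing `stage`, starting at
#' `"raw"`.
#'
#' @param samples List of `tcr_repertoire` objects (sample ids must be
#'   unique).
#' @param labels Named character vector: sample id to group label (disease
#'   name or `"healthy"`); unlabelled samples get `"unlabeled"`.
#' @param k Word length.
#' @param weighted Passed to [count_kmers()].
#' @return A `motif_matrix` tibble: `sample_id`, `label`, then one numeric
#'   column per motif.
#' @export
build_motif_matrix <- function(samples, labels = NULL, k = 3,
                               weighted = FALSE) {
  stopifnot(length(samples) >= 1)
  ids <- unname(purrr::map_chr(samples, sample_id))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample id(s): %s.",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "tcr_identity_error")
  }
  counts <- purrr::map(samples, count_kmers, k = k, weighted = weighted)
  motifs <- sort(unique(unlist(purrr::map(counts, "motif"))))
  values <- purrr::map(counts, function(ct) {
    v <- setNames(numeric(length(motifs)), motifs)
    v[ct$motif] <- ct$count
    v
  })
  mat <- do.call(rbind, values)
  lab <- if (is.null(labels)) rep("unlabeled", length(ids)) else {
    unname(labels[ids]) |> dplyr::coalesce("unlabeled")
  }
  new_motif_matrix(
    tibble::tibble(sample_id = ids, label = lab) |>
      dplyr::bind_cols(tibble::as_tibble(mat)),
    stage = "raw", k = k
  )
}

new_motif_matrix <- function(tbl, stage, k = 3, center = NULL, scale = NULL) {
  stage <- match.arg(stage, MOTIF_STAGES)
  structure(tbl,
    stage = stage, k = k, center = center, scale = scale,
    class = unique(c("motif_matrix", class(tibble::tibble())))
  )
}

#' Motif-matrix accessors
#'
#' @param m A `motif_matrix`.
#' @return `motif_names()` the motif column names, `motif_values()` the
#'   numeric samples x motifs matrix (sample ids as row names),
#'   `motif_stage()` the processing stage.
#' @export
motif_names <- function(m) setdiff(names(m), c("sample_id", "label"))

#' @rdname motif_names
#' @export
motif_values <- function(m) {
  mat <- as.matrix(tibble::as_tibble(m)[motif_names(m)])
  rownames(mat) <- m$sample_id
  mat
}

#' @rdname motif_names
#' @export
motif_stage <- function(m) attr(m, "stage")

#' Drop samples with extreme motif totals
#'
#' Samples are ranked by total motif count; the bottom `lower_q` and top
#' `upper_q` quantile tails are removed (`ceiling(n * q)` samples per
#' non-empty tail, so at least one sample leaves each tail whenever
#' `q > 0`). Ties are broken by sample id for determinism.
#'
#' @param m A `motif_matrix` at stage `"raw"`.
#' @param lower_q,upper_q Tail fractions (default 0.2 each).
#' @return The filtered matrix at stage `"sample_filtered"`.
#' @export
filter_samples <- function(m, lower_q = 0.2, upper_q = 0.2) {
  check_stage(m, "raw")
  n <- nrow(m)
  totals <- rowSums(motif_values(m))
  ord <- order(totals, m$sample_id)
  n_lo <- if (lower_q > 0) ceiling(n * lower_q) else 0L
  n_hi <- if (upper_q > 0) ceiling(n * upper_q) else 0L
  if (n_lo + n_hi >= n) {
    abort("sample filter would remove every sample.",
          class = "tcr_empty_error")
  }
  drop <- c(head(ord, n_lo), utils::tail(ord, n_hi))
  keep <- setdiff(seq_len(n), drop)
  new_motif_matrix(m[sort(keep), , drop = FALSE],
                   stage = "sample_filtered", k = attr(m, "k"))
}

#' Keep motifs prevalent within a disease group
#'
#' A disease-specific motif should occur in the majority of that disease's
#' samples: motifs with a nonzero count in strictly more than `min_frac`
#' of the `group`'s samples are kept, the rest removed from the matrix.
#'
#' @param m A `motif_matrix` at stage `"sample_filtered"`.
#' @param group Group label to assess prevalence in.
#' @param min_frac Strict prevalence threshold (default 0.5).
#' @return The filtered matrix at stage `"prevalence_filtered"`.
#' @export
filter_prevalence <- function(m, group, min_frac = 0.5) {
  check_stage(m, "sample_filtered")
  in_group <- m$label == group
  if (!any(in_group)) {
    abort(sprintf("no samples labelled '%s'.", group),
          class = "tcr_label_error")
  }
  vals <- motif_values(m)
  prev <- colMeans(vals[in_group, , drop = FALSE] > 0)
  keep <- motif_names(m)[prev > min_frac]
  new_motif_matrix(
    tibble::as_tibble(m)[c("sample_id", "label", keep)],
    stage = "prevalence_filtered", k = attr(m, "k")
  )
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U with midrank ties. The two-sided P value is exact (the full
#' tie-aware permutation distribution of U, computed by a counting
#' recursion over rank subsets) when `n * m <= 400`, and otherwise uses
#' the normal approximation with tie-corrected variance and continuity
#' correction. With ties the permutation distribution of U is symmetric
#' about nm/2 (rank reversal is measure-preserving), and the exact
#' two-sided P is `P(|U - nm/2| >= |u_obs - nm/2|)`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return One-row tibble: `u` (U statistic of `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) {
    abort("both samples must be non-empty.", class = "tcr_empty_error")
  }
  res <- mwu_core(x, y)
  tibble::tibble(u = res$u, p_value = res$p, method = res$method)
}

mwu_core <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n * m <= 400) {
    list(u = u, p = mwu_exact_p(r, n, u), method = "exact")
  } else {
    list(u = u, p = mwu_normal_p(r, n, m, u), method = "normal")
  }
}

# Exact two-sided P by dynamic programming over the (doubled, integer)
# midranks: counts, for every achievable rank sum, the number of size-n
# subsets attaining it. Counts stay below 2^53 for the sizes admitted.
mwu_exact_p <- function(r, n, u_obs) {
  r2 <- as.integer(round(2 * r))
  total <- length(r2)
  maxsum <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  # dp[[j]][s+1] = number of j-subsets with doubled rank sum s
  dp <- matrix(0, nrow = n + 1, ncol = maxsum + 1)
  dp[1, 1] <- 1
  for (val in r2) {
    jmax <- n
    for (j in jmax:1) {
      shifted <- c(rep(0, val), dp[j, seq_len(maxsum + 1 - val)])
      dp[j + 1, ] <- dp[j + 1, ] + shifted
    }
  }
  counts <- dp[n + 1, ]
  sums2 <- which(counts > 0) - 1
  probs <- counts[counts > 0] / sum(counts[counts > 0])
  # doubled U values and symmetric two-sided tail
  nm <- n * (total - n)
  u2 <- sums2 - n * (n + 1)
  dev_obs <- abs(2 * u_obs - nm)
  sum(probs[abs(u2 - nm) >= dev_obs - 1e-9])
}

mwu_normal_p <- function(r, n, m, u) {
  nt <- n + m
  ties <- table(r)
  mu <- n * m / 2
  sigma2 <- (n * m / 12) * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sigma2 <= 0) {
    return(1)
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Remove motifs not specific to disease
#'
#' For each motif column of the disease matrix, compares the disease
#' samples' values against the healthy samples' values (a motif absent
#' from the healthy matrix is compared against all zeros) with
#' [mann_whitney_u()]; motifs with `P > alpha` are removed.
#'
#' @param disease A `motif_matrix` at stage `"prevalence_filtered"`.
#' @param healthy A `motif_matrix` (any stage past raw counting).
#' @param alpha Significance threshold (default 0.05); motifs are kept iff
#'   `P <= alpha`.
#' @param value `"count"` (default) to compare raw per-sample counts, or
#'   `"frequency"` to compare counts normalised by sample totals.
#' @return The filtered disease matrix at stage `"mwu_filtered"`, with the
#'   per-motif P values in the `mwu_p` attribute.
#' @export
filter_mwu <- function(disease, healthy, alpha = 0.05,
                       value = c("count", "frequency")) {
  value <- match.arg(value)
  check_stage(disease, "prevalence_filtered")
  if (nrow(healthy) == 0 || nrow(disease) == 0) {
    abort("both matrices need at least one sample.",
          class = "tcr_empty_error")
  }
  dvals <- motif_values(disease)
  hvals <- motif_values(healthy)
  if (value == "frequency") {
    dvals <- dvals / pmax(rowSums(dvals), 1)
    hvals <- hvals / pmax(rowSums(hvals), 1)
  }
  pv <- purrr::map_dbl(motif_names(disease), function(motif) {
    hy <- if (motif %in% colnames(hvals)) hvals[, motif] else
      numeric(nrow(hvals))
    mwu_core(dvals[, motif], hy)$p
  })
  names(pv) <- motif_names(disease)
  keep <- names(pv)[pv <= alpha]
  out <- new_motif_matrix(
    tibble::as_tibble(disease)[c("sample_id", "label", keep)],
    stage = "mwu_filtered", k = attr(disease, "k")
  )
  attr(out, "mwu_p") <- pv
  out
}

#' Z-score normalise a motif matrix
#'
#' Per motif column: subtract the column mean and divide by the population
#' standard deviation (zero-variance columns become all zeros). Column
#' means and SDs are retained in the `center`/`scale` attributes so new
#' samples can be projected onto the same scale.
#'
#' @param m A `motif_matrix`.
#' @param margin `"motif"` (default, per column across samples) or
#'   `"sample"` (per row).
#' @return The normalised matrix at stage `"normalized"`.
#' @export
zscore_normalize <- function(m, margin = c("motif", "sample")) {
  margin <- match.arg(margin)
  vals <- motif_values(m)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (margin == "motif") {
    center <- colMeans(vals)
    scale <- apply(vals, 2, pop_sd)
    z <- sweep(vals, 2, center)
    z <- sweep(z, 2, ifelse(scale > 0, scale, 1), "/")
    z[, scale == 0] <- 0
  } else {
    rc <- rowMeans(vals)
    rs <- apply(vals, 1, pop_sd)
    z <- sweep(vals, 1, rc)
    z <- sweep(z, 1, ifelse(rs > 0, rs, 1), "/")
    z[rs == 0, ] <- 0
    center <- colMeans(vals)
    scale <- apply(vals, 2, pop_sd)
  }
  new_motif_matrix(
    tibble::tibble(sample_id = m$sample_id, label = m$label) |>
      dplyr::bind_cols(tibble::as_tibble(z)),
    stage = "normalized", k = attr(m, "k"),
    center = center, scale = scale
  )
}

check_stage <- function(m, expected) {
  if (!identical(attr(m, "stage"), expected)) {
    abort(sprintf("motif matrix must be at stage '%s' (is '%s').",
                  expected, attr(m, "stage")),
          class = "tcr_state_error")
  }
  invisible(m)
}

#' @export
tidy.motif_matrix <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-c("sample_id", "label"),
                        names_to = "motif", values_to = "value")
}

#' @export
glance.motif_matrix <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_motifs = length(motif_names(x)),
    stage = motif_stage(x)
  )
}

#' Write a motif matrix with its sidecar metadata
#'
#' `values.tsv` holds the samples x motifs table; `meta.json` records the
#' stage, k, labels, and (when normalised) the column means and SDs.
#'
#' @param m A `motif_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_motif_matrix <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(m), file.path(dir, "values.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(stage = motif_stage(m), k = attr(m, "k"),
         labels = as.list(setNames(m$label, m$sample_id)),
         center = as.list(attr(m, "center")),
         scale = as.list(attr(m, "scale"))),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
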