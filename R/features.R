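# General repertoire statistics ---------------------------------------------

#' Renyi entropy of a clone frequency distribution
#'
#' The one-parameter Renyi family
#' \deqn{H_\alpha = \frac{1}{1-\alpha} \log_b \sum_{i=1}^{N} P_i^\alpha}
#' where \eqn{P_i} is the frequency of clone i and N the number of unique
#' sequences. The order \eqn{\alpha} sets the sensitivity to abundance:
#' \eqn{\alpha = 0} gives \eqn{\log_b N} (richness, all sequences weighted
#' equally), \eqn{\alpha \to 1} the Shannon entropy, and
#' \eqn{\alpha = \infty} the min-entropy \eqn{-\log_b \max_i P_i}. The
#' three special cases are evaluated exactly; other orders use a
#' numerically stable log-sum-exp.
#'
#' @param freqs Probability vector: positive values summing to 1 (within
#'   1e-6).
#' @param alpha Non-negative order; `Inf` allowed.
#' @param base Logarithm base (> 1); default 2 (bits).
#' @return The Renyi entropy (scalar, in log-base-`base` units).
#' @examples
#' renyi_entropy(rep(0.25, 4), alpha = 0) # log2(4) = 2
#' @export
renyi_entropy <- function(freqs, alpha, base = 2) {
  if (length(freqs) == 0) {
    abort("`freqs` must be non-empty.", class = "tcr_empty_error")
  }
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    abort("`freqs` must be strictly positive and finite.",
          class = "tcr_validation_error")
  }
  if (abs(sum(freqs) - 1) > 1e-6) {
    abort("`freqs` must sum to 1 (within 1e-6).",
          class = "tcr_validation_error")
  }
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0) {
    abort("`alpha` must be a single non-negative number.",
          class = "tcr_domain_error")
  }
  if (length(base) != 1 || base <= 1) {
    abort("`base` must be a single number > 1.", class = "tcr_domain_error")
  }
  if (alpha == 0) {
    return(log(length(freqs), base))
  }
  if (is.infinite(alpha)) {
    return(-log(max(freqs), base))
  }
  if (alpha == 1) {
    return(-sum(freqs * log(freqs, base)))
  }
  lp <- alpha * log(freqs) # natural log, shifted for stability
  m <- max(lp)
  lse <- m + log(sum(exp(lp - m)))
  (1 / (1 - alpha)) * (lse / log(base))
}

#' Renyi diversity profile of a repertoire
#'
#' Evaluates [renyi_entropy()] over a grid of orders. The curve is flat for
#' a perfectly even repertoire and falls steeply with increasing
#' \eqn{\alpha} when a few clones dominate.
#'
#' @param rep A `tcr_repertoire` (non-empty).
#' @param alphas Order grid; the default spans the conventional display
#'   range including 0, 1 (Shannon) and `Inf`.
#' @param base Logarithm base.
#' @param weighting `"count"` (clone-mass frequencies, default) or
#'   `"unique"` (each unique sequence weighted equally).
#' @return A `diversity_profile` tibble with columns `alpha`, `entropy`.
#' @export
diversity_profile <- function(rep,
                              alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, Inf),
                              base = 2, weighting = c("count", "unique")) {
  weighting <- match.arg(weighting)
  freqs <- repertoire_freqs(rep, weighting)
  out <- tibble::tibble(
    alpha = alphas,
    entropy = purrr::map_dbl(alphas, renyi_entropy, freqs = freqs, base = base)
  )
  structure(out,
    base = base, sample_id = sample_id(rep),
    class = c("diversity_profile", class(out))
  )
}

#' Repertoire clonality (one minus the Pielou evenness)
#'
#' \deqn{clonality = 1 - \frac{-\sum_i P_i \log_b P_i}{\log_b N}}
#' 0 for a maximally diverse repertoire with even frequencies, near 1 for a
#' repertoire driven by clonal dominance. A single-clonotype repertoire
#' (where the Pielou index is undefined) is scored 1, the maximal-dominance
#' convention.
#'
#' @inheritParams diversity_profile
#' @return Scalar in \[0, 1\].
#' @export
clonality <- function(rep, base = 2, weighting = c("count", "unique")) {
  weighting <- match.arg(weighting)
  freqs <- repertoire_freqs(rep, weighting)
  n <- length(freqs)
  if (n == 1) {
    return(1)
  }
  shannon <- -sum(freqs * log(freqs, base))
  1 - shannon / log(n, base)
}

#' CDR3 length distribution
#'
#' @param rep A `tcr_repertoire`.
#' @param weighted `FALSE` counts unique sequences per length; `TRUE` sums
#'   clone frequencies per length (values then sum to 1).
#' @return Tibble with columns `length`, `value`, ascending in `length`.
#' @export
length_distribution <- function(rep, weighted = FALSE) {
  tibble::tibble(length = nchar(rep$cdr3_aa),
                 w = if (weighted) rep$frequency else 1) |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(value = sum(.data$w), .groups = "drop") |>
    dplyr::arrange(.data$length)
}

#' V or J gene usage
#'
#' Per-gene share of unique sequences (`weighted = FALSE`) or of clone mass
#' (`weighted = TRUE`); shares sum to 1. Records without a gene annotation
#' are excluded from the denominator.
#'
#' @param rep A `tcr_repertoire` with gene annotations.
#' @param segment `"V"` or `"J"`.
#' @param weighted Weight by clone counts.
#' @return Tibble with columns `gene`, `frequency`, descending.
#' @export
gene_usage <- function(rep, segment = c("V", "J"), weighted = FALSE) {
  segment <- match.arg(segment)
  gene <- if (segment == "V") rep$v_gene else rep$j_gene
  w <- if (weighted) rep$count else rep(1, nrow(rep))
  keep <- !is.na(gene) & gene != ""
  if (!any(keep)) {
    abort(sprintf("no %s gene annotations present.", segment),
          class = "tcr_annotation_error")
  }
  tibble::tibble(gene = gene[keep], w = w[keep]) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(frequency = sum(.data$w), .groups = "drop") |>
    dplyr::mutate(frequency = .data$frequency / sum(.data$frequency)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene)
}

#' V-J gene pairing frequencies
#'
#' Share of clonotypes (or clone mass) carrying each (V, J) pair; the grand
#' total is 1 and the marginals over V and J reproduce [gene_usage()] on
#' fully annotated repertoires.
#'
#' @inheritParams gene_usage
#' @return Tibble with columns `v_gene`, `j_gene`, `frequency`.
#' @export
vj_pairing <- function(rep, weighted = FALSE) {
  w <- if (weighted) rep$count else rep(1, nrow(rep))
  keep <- rep$v_gene != "" & rep$j_gene != ""
  if (!any(keep)) {
    abort("no V/J gene annotations present.", class = "tcr_annotation_error")
  }
  tibble::tibble(v_gene = rep$v_gene[keep], j_gene = rep$j_gene[keep],
                 w = w[keep]) |>
    dplyr::group_by(.data$v_gene, .data$j_gene) |>
    dplyr::summarise(frequency = sum(.data$w), .groups = "drop") |>
    dplyr::mutate(frequency = .data$frequency / sum(.data$frequency)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$v_gene, .data$j_gene)
}

#' Clonal composition: top clones and the rest
#'
#' The `top_n` most frequent clones (frequency ties broken by
#' lexicographic CDR3) with the remaining clone mass aggregated into an
#' `other_frequency` attribute; listed frequencies plus the remainder sum
#' to 1.
#'
#' @param rep A `tcr_repertoire` (non-empty).
#' @param top_n Number of clones to list individually.
#' @return A `clonal_composition` tibble (`cdr3_aa`, `frequency`,
#'   non-increasing) with attribute `other_frequency`.
#' @export
clonal_composition <- function(rep, top_n = 10) {
  if (nrow(rep) == 0) {
    abort("repertoire is empty.", class = "tcr_empty_error")
  }
  ord <- rep |>
    tibble::as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$cdr3_aa)
  top <- head(ord, top_n)[c("cdr3_aa", "frequency")]
  structure(top,
    other_frequency = max(0, 1 - sum(top$frequency)),
    top_n = top_n,
    class = c("clonal_composition", class(top))
  )
}

#' @export
glance.clonal_composition <- function(x, ...) {
  tibble::tibble(
    n_top = nrow(x),
    top_frequency = sum(x$frequency),
    other_frequency = attr(x, "other_frequency")
  )
}

#' Position weight matrix of a sequence set
#'
#' Per-position amino-acid probabilities for equal-length sequences,
#' optionally weighted. No pseudocounts: probabilities are over observed
#' letters only, and each position's probabilities sum to 1.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param weights Optional non-negative weights (default: equal).
#' @return A `tcr_pwm` tibble in long form (`position`, `aa`, `prob`) with
#'   attributes `seq_length` and `support` (number of sequences).
#' @export
position_weight_matrix <- function(seqs, weights = NULL) {
  if (length(seqs) == 0) {
    abort("`seqs` must be non-empty.", class = "tcr_empty_error")
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) {
    abort("all sequences must share one length.",
          class = "tcr_length_mismatch_error")
  }
  weights <- weights %||% rep(1, length(seqs))
  weights <- weights / sum(weights)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  out <- purrr::map_dfr(seq_len(lens), function(p) {
    tapply(weights, chars[, p], sum) |>
      (\(v) tibble::tibble(position = p, aa = names(v),
                           prob = as.numeric(v)))()
  })
  structure(out,
    seq_length = lens, support = length(seqs),
    class = c("tcr_pwm", class(out))
  )
}

#' Sequence logo matrix of the most frequent CDR3s
#'
#' Selects the `top_n` most frequent sequences (ties lexicographic), groups
#' them by length to avoid any implicit alignment, and returns the
#' position weight matrix of the modal-length group (ties broken toward the
#' shorter length). PWMs for every length group are attached as the
#' `length_groups` attribute.
#'
#' @param rep A `tcr_repertoire` (non-empty).
#' @param top_n Number of top-frequency sequences to summarise.
#' @return A `tcr_pwm` for the modal length, with attribute
#'   `length_groups` (named list of `tcr_pwm`, one per length).
#' @export
top_logo <- function(rep, top_n = 100) {
  if (nrow(rep) == 0) {
    abort("repertoire is empty.", class = "tcr_empty_error")
  }
  sel <- rep |>
    tibble::as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$cdr3_aa) |>
    head(top_n)
  groups <- split(sel$cdr3_aa, nchar(sel$cdr3_aa))
  pwms <- purrr::map(groups, position_weight_matrix)
  sizes <- lengths(groups)
  modal <- names(groups)[order(-sizes, as.integer(names(groups)))][1]
  out <- pwms[[modal]]
  attr(out, "length_groups") <- pwms
  out
}
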