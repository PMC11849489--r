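# Fuzzy annotation against a reference database -----------------------------
#
# Queries are matched against annotated reference CDR3s with at most one
# mismatch. "Mismatch" follows edit-distance (Levenshtein) semantics by
# default -- one substitution, insertion, or deletion -- matching the
# fuzziness of full-text search engines; a substitutions-only (Hamming)
# mode is available. Distance-1 lookups use a deletion-variant index (each
# sequence is keyed by itself and every single-deletion form), whose
# results are contractually identical to a brute-force scan.

#' Read an annotation reference table
#'
#' TSV with header `cdr3_aa`, `v_gene`, `j_gene`, `condition`,
#' `cell_type`, `cell_source`, `provenance` (only `cdr3_aa` is mandatory;
#' missing annotation columns are filled with `""`).
#'
#' @param path TSV file path.
#' @return Tibble of reference records.
#' @export
read_reference <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(tbl, "cdr3_aa", path)
  for (col in c("v_gene", "j_gene", "condition", "cell_type",
                "cell_source", "provenance")) {
    if (!col %in% names(tbl)) tbl[[col]] <- ""
    tbl[[col]] <- dplyr::coalesce(tbl[[col]], "")
  }
  tbl$cdr3_aa <- toupper(tbl$cdr3_aa)
  tibble::as_tibble(tbl)
}

# All single-deletion forms of a sequence.
deletion_variants <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i) {
    paste0(substr(s, 1, i - 1), substr(s, i + 1, n))
  }, character(1))
}

#' Build a fuzzy-search index over reference records
#'
#' Records must each pass [validate_cdr3()]. The index supports exact and
#' distance-1 lookups without a full scan; duplicate CDR3s with different
#' annotations are retained as separate records.
#'
#' @param records Data frame of reference records (as from
#'   [read_reference()] or [simulate_reference()]).
#' @return An `annotation_index`.
#' @export
build_reference_index <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("reference records must be non-empty.", class = "tcr_empty_error")
  }
  records <- tibble::as_tibble(records)
  records$cdr3_aa <- toupper(records$cdr3_aa)
  verdict <- validate_cdr3(records$cdr3_aa)
  if (any(!verdict$valid)) {
    bad <- which(!verdict$valid)[1]
    abort(sprintf("reference record %d ('%s') fails CDR3 validation (%s).",
                  bad, records$cdr3_aa[bad], verdict$reason[bad]),
          class = "tcr_validation_error")
  }
  keys <- purrr::map(records$cdr3_aa, ~ c(.x, deletion_variants(.x)))
  ids <- rep(seq_len(nrow(records)), lengths(keys))
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = length(ids))
  grouped <- split(ids, unlist(keys))
  for (key in names(grouped)) assign(key, grouped[[key]], envir = env)
  structure(list(records = records, env = env),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("# annotation index: %d reference records\n", nrow(x$records)))
  invisible(x)
}

#' Fuzzy search for similar reference CDR3s
#'
#' Returns every reference record within `max_mismatch` of the query:
#' Levenshtein edit distance by default, Hamming (substitutions only,
#' equal lengths) with `substitutions_only = TRUE`. For
#' `max_mismatch <= 1` the deletion-variant index is used; larger radii
#' fall back to a full scan.
#'
#' @param index An `annotation_index`.
#' @param query CDR3 amino-acid string.
#' @param max_mismatch Maximum distance (default 1).
#' @param substitutions_only Use Hamming instead of Levenshtein semantics.
#' @return Tibble of hits (`query_cdr3`, `matched_cdr3`, `edit_distance`,
#'   annotation columns), sorted by distance then matched sequence; empty
#'   when nothing matches.
#' @export
fuzzy_search <- function(index, query, max_mismatch = 1,
                         substitutions_only = FALSE) {
  query <- toupper(query)
  recs <- index$records
  if (max_mismatch <= 1) {
    keys <- if (max_mismatch == 0) query else c(query, deletion_variants(query))
    hits <- unique(unlist(
      mget(keys, envir = index$env, ifnotfound = list(NULL))
    ))
  } else {
    hits <- seq_len(nrow(recs))
  }
  if (!length(hits)) {
    return(empty_hits())
  }
  cand <- recs$cdr3_aa[hits]
  if (substitutions_only) {
    same_len <- nchar(cand) == nchar(query)
    dist <- rep(NA_integer_, length(cand))
    if (any(same_len)) {
      dist[same_len] <- hamming_distance(rep(query, sum(same_len)),
                                         cand[same_len])
    }
    keep <- !is.na(dist) & dist <= max_mismatch
  } else {
    dist <- as.integer(adist(query, cand))
    keep <- dist <= max_mismatch
  }
  if (!any(keep)) {
    return(empty_hits())
  }
  out <- recs[hits[keep], , drop = FALSE] |>
    dplyr::rename(matched_cdr3 = "cdr3_aa") |>
    dplyr::mutate(query_cdr3 = query, edit_distance = dist[keep],
                  .before = 1) |>
    dplyr::arrange(.data$edit_distance, .data$matched_cdr3)
  tibble::as_tibble(out)
}

empty_hits <- function() {
  tibble::tibble(
    query_cdr3 = character(), edit_distance = integer(),
    matched_cdr3 = character(), v_gene = character(), j_gene = character(),
    condition = character(), cell_type = character(),
    cell_source = character(), provenance = character()
  )
}

#' Annotate a repertoire against a reference index
#'
#' Cancer- and disease-associated clones are typically among the most
#' frequent, so only the `top_n` clonotypes by frequency are queried
#' (frequency ties broken by lexicographic CDR3). One output row per
#' (query, hit) pair; queries without any hit appear once with
#' `annotated = FALSE`.
#'
#' @param rep A QC-passed `tcr_repertoire`.
#' @param index An `annotation_index`.
#' @param top_n Number of top-frequency clonotypes to query
#'   (default 3000).
#' @inheritParams fuzzy_search
#' @return Annotation tibble: `query_cdr3`, `query_frequency`,
#'   `annotated`, `edit_distance`, `matched_cdr3` and the annotation
#'   columns.
#' @export
annotate_repertoire <- function(rep, index, top_n = 3000, max_mismatch = 1,
                                substitutions_only = FALSE) {
  queries <- rep |>
    tibble::as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$cdr3_aa) |>
    head(top_n)
  rows <- purrr::map2_dfr(queries$cdr3_aa, queries$frequency,
    function(q, f) {
      hits <- fuzzy_search(index, q, max_mismatch = max_mismatch,
                           substitutions_only = substitutions_only)
      if (nrow(hits) == 0) {
        dplyr::bind_rows(
          empty_hits(),
          tibble::tibble(query_cdr3 = q, query_frequency = f,
                         annotated = FALSE)
        )
      } else {
        dplyr::mutate(hits, query_frequency = f, annotated = TRUE,
                      .after = "query_cdr3")
      }
    })
  rows
}

#' Enrichment summary over an annotation field
#'
#' For each label of the chosen field, the number of distinct query
#' sequences with at least one hit carrying that label (a query annotated
#' with two labels counts once under each) -- the counts behind a treemap
#' of enriched conditions, cell types, or cell sources.
#'
#' @param table Output of [annotate_repertoire()].
#' @param field `"condition"`, `"cell_type"`, or `"cell_source"`.
#' @return Tibble (`label`, `unique_sequences`), descending.
#' @export
enrichment_summary <- function(table,
                               field = c("condition", "cell_type",
                                         "cell_source")) {
  field <- match.arg(field)
  table |>
    dplyr::filter(.data$annotated) |>
    dplyr::distinct(.data$query_cdr3, label = .data[[field]]) |>
    dplyr::count(.data$label, name = "unique_sequences") |>
    dplyr::arrange(dplyr::desc(.data$unique_sequences), .data$label)
}
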