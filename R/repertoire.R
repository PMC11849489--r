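#' Construct a TCR repertoire
#'
#' A repertoire is the canonical unit all analyses consume: a tibble with one
#' row per clonotype and columns `cdr3_aa` (upper-case amino-acid CDR3),
#' `v_gene`, `j_gene` (gene symbols, `""` when unknown), `count` (clone
#' abundance, >= 1) and `frequency` (count divided by the repertoire total).
#' The sample identifier and free-form metadata (disease label, timepoint,
#' tissue, ...) travel as attributes.
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param v_gene,j_gene Gene symbols, recycled; `NA` becomes `""`.
#' @param count Integer clone counts, recycled; missing or zero counts
#'   default to 1 so frequency-based statistics stay defined.
#' @param sample_id Sample identifier string.
#' @param metadata Named list of strings (e.g. `list(disease = "melanoma")`).
#' @return A `tcr_repertoire` tibble.
#' @examples
#' repertoire(c("CASSLGETQYF", "CASRPDRGYTF"), count = c(7, 3))
#' @export
repertoire <- function(cdr3_aa, v_gene = "", j_gene = "", count = 1L,
                       sample_id = "sample", metadata = list()) {
  tbl <- tibble::tibble(
    cdr3_aa = as.character(cdr3_aa),
    v_gene = as.character(v_gene),
    j_gene = as.character(j_gene),
    count = count
  )
  as_repertoire(tbl, sample_id = sample_id, metadata = metadata)
}

#' Coerce a data frame to a repertoire
#'
#' Requires a `cdr3_aa` column; `v_gene`, `j_gene` and `count` are filled
#' with defaults when absent. Sequences are upper-cased, counts of zero or
#' `NA` become 1, and frequencies are (re)computed from the counts.
#'
#' @param x A data frame with at least a `cdr3_aa` column.
#' @inheritParams repertoire
#' @return A `tcr_repertoire` tibble.
#' @export
as_repertoire <- function(x, sample_id = NULL, metadata = NULL) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame.", class = "tcr_type_error")
  }
  if (!"cdr3_aa" %in% names(x)) {
    abort("column `cdr3_aa` is required.", class = "tcr_schema_error")
  }
  tbl <- tibble::as_tibble(x)
  if (!"v_gene" %in% names(tbl)) tbl$v_gene <- ""
  if (!"j_gene" %in% names(tbl)) tbl$j_gene <- ""
  if (!"count" %in% names(tbl)) tbl$count <- 1L

  tbl <- tbl |>
    dplyr::mutate(
      cdr3_aa = toupper(as.character(.data$cdr3_aa)),
      v_gene = dplyr::coalesce(as.character(.data$v_gene), ""),
      j_gene = dplyr::coalesce(as.character(.data$j_gene), ""),
      count = suppressWarnings(as.numeric(.data$count))
    )
  if (any(tbl$count < 0, na.rm = TRUE)) {
    abort("clone counts must be non-negative.", class = "tcr_validation_error")
  }
  tbl$count <- as.integer(round(dplyr::coalesce(tbl$count, 1)))
  tbl$count[tbl$count == 0L] <- 1L
  tbl <- tbl[c("cdr3_aa", "v_gene", "j_gene", "count",
               setdiff(names(tbl), c("cdr3_aa", "v_gene", "j_gene", "count",
                                     "frequency")))]

  out <- new_repertoire(
    tbl,
    sample_id = sample_id %||% attr(x, "sample_id") %||% "sample",
    metadata = metadata %||% attr(x, "metadata") %||% list()
  )
  refresh_frequency(out)
}

# Low-level constructor; assumes canonical columns.
new_repertoire <- function(tbl, sample_id = "sample", metadata = list()) {
  structure(
    tibble::as_tibble(tbl),
    sample_id = sample_id,
    metadata = metadata,
    class = c("tcr_repertoire", class(tibble::tibble()))
  )
}

# Rebuild repertoire attributes after a dplyr verb stripped them.
restore_repertoire <- function(tbl, template) {
  out <- new_repertoire(tbl,
    sample_id = sample_id(template),
    metadata = metadata(template)
  )
  attr(out, "qc_report") <- attr(template, "qc_report")
  out
}

# Recompute frequency = count / total; empty repertoire keeps an empty column.
refresh_frequency <- function(rep) {
  tot <- sum(rep$count)
  rep$frequency <- if (tot > 0) rep$count / tot else numeric(nrow(rep))
  rep
}

#' Repertoire accessors
#'
#' @param rep A `tcr_repertoire`.
#' @return `sample_id()` the sample identifier, `metadata()` the metadata
#'   list, `total_count()` the summed clone counts, `n_clonotypes()` the
#'   number of clonotype records.
#' @export
sample_id <- function(rep) attr(rep, "sample_id") %||% "sample"

#' @rdname sample_id
#' @export
metadata <- function(rep) attr(rep, "metadata") %||% list()

#' @rdname sample_id
#' @export
total_count <- function(rep) sum(rep$count)

#' @rdname sample_id
#' @export
n_clonotypes <- function(rep) nrow(rep)

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "# TCR repertoire '%s': %d clonotypes, total count %d\n",
    sample_id(x), nrow(x), total_count(x)
  ))
  md <- metadata(x)
  if (length(md)) {
    cat("# metadata: ",
        paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  NextMethod()
}

# Repertoire frequency vector under either weighting scheme.
repertoire_freqs <- function(rep, weighting = c("count", "unique")) {
  weighting <- match.arg(weighting)
  if (nrow(rep) == 0) {
    abort("repertoire is empty.", class = "tcr_empty_error")
  }
  if (weighting == "count") {
    tot <- sum(rep$count)
    rep$count / tot
  } else {
    rep(1 / nrow(rep), nrow(rep))
  }
}
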