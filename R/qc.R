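# Quality control -----------------------------------------------------------
#
# Five pre-processing rules produce a reliable TRB CDR3 repertoire:
#   (1) identical CDR3s with different V/J genes are merged, keeping the
#       V/J of the most abundant record;
#   (2) alleles of the same V/J gene are collapsed to the gene symbol;
#   (3) records must carry both a V and a J gene (unless require_vj = FALSE);
#   (4) the CDR3 must start with C, end with F or W, and contain no stop
#       codon or frameshift marker (IMGT convention, amino-acid level);
#   (5) CDR3 length must be within 8..24 amino acids.

CDR3_MIN_LEN <- 8L
CDR3_MAX_LEN <- 24L

#' Collapse V/J allele designations to gene symbols
#'
#' Strips the allele suffix (everything from the first `*`) from both gene
#' columns, e.g. `TRBV12-3*01` becomes `TRBV12-3`. Records that become
#' identical are merged later by [merge_duplicate_cdr3()].
#'
#' @param rep A `tcr_repertoire`.
#' @return The repertoire with allele-free gene symbols.
#' @export
collapse_alleles <- function(rep) {
  rep$v_gene <- sub("\\*.*$", "", rep$v_gene)
  rep$j_gene <- sub("\\*.*$", "", rep$j_gene)
  rep
}

#' Merge clonotypes sharing a CDR3 sequence
#'
#' One clonotype per unique `cdr3_aa`: counts are summed and the V/J genes
#' are taken from the most abundant merged record (ties broken by the
#' lexicographically smallest gene symbols). Allele collapse is applied
#' first so that allelic variants of one gene never split a merge.
#'
#' @param rep A `tcr_repertoire`.
#' @return The merged repertoire with recomputed frequencies.
#' @export
merge_duplicate_cdr3 <- function(rep) {
  rep <- collapse_alleles(rep)
  tbl <- rep |>
    dplyr::arrange(dplyr::desc(.data$count), .data$v_gene, .data$j_gene) |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(
      v_gene = dplyr::first(.data$v_gene),
      j_gene = dplyr::first(.data$j_gene),
      count = sum(.data$count),
      .groups = "drop"
    )
  # preserve first-appearance order of the surviving CDR3s
  tbl <- tbl[match(unique(rep$cdr3_aa), tbl$cdr3_aa), , drop = FALSE]
  refresh_frequency(restore_repertoire(tbl, rep))
}

#' Validate CDR3 amino-acid sequences
#'
#' Verdicts, not exceptions: a sequence passes iff it starts with cysteine
#' (C), ends with phenylalanine (F) or tryptophan (W), contains no stop
#' codon (`*`) or frameshift marker (`_`), uses only the 20 standard
#' amino-acid letters, and has length 8..24.
#'
#' @param seq Character vector of sequences.
#' @return A tibble with columns `cdr3_aa`, `valid` (logical) and `reason`
#'   (comma-joined codes from `stop_codon`, `out_of_frame`,
#'   `invalid_alphabet`, `start_anchor`, `end_anchor`, `length`, `empty`;
#'   `NA` when valid).
#' @examples
#' validate_cdr3(c("CASSLGETQYF", "CASSF*", "CASSQYF"))
#' @export
validate_cdr3 <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  empty <- is.na(seq) | n == 0
  has_stop <- !empty & grepl("*", seq, fixed = TRUE)
  has_frameshift <- !empty & grepl("_", seq, fixed = TRUE)
  alphabet_ok <- !empty &
    !grepl(paste0("[^", paste(AA20, collapse = ""), "*_]"), seq)
  start_ok <- !empty & substr(seq, 1, 1) == "C"
  end_ok <- !empty & substr(seq, n, n) %in% c("F", "W")
  len_ok <- !empty & n >= CDR3_MIN_LEN & n <= CDR3_MAX_LEN

  reasons <- purrr::pmap_chr(
    list(empty, has_stop, has_frameshift, alphabet_ok, start_ok, end_ok, len_ok),
    function(e, st, fs, al, s, en, l) {
      if (e) return("empty")
      codes <- c(
        if (st) "stop_codon",
        if (fs) "out_of_frame",
        if (!al) "invalid_alphabet",
        if (!s) "start_anchor",
        if (!en) "end_anchor",
        if (!l) "length"
      )
      if (length(codes)) paste(codes, collapse = ",") else NA_character_
    }
  )
  tibble::tibble(cdr3_aa = seq, valid = is.na(reasons), reason = reasons)
}

#' Apply the full pre-processing pipeline
#'
#' In order: allele collapse, V/J-presence filter (rule 3; skipped when
#' `require_vj = FALSE`, e.g. for bare CDR3-list inputs), CDR3 validity
#' filter (rules 4-5), duplicate-CDR3 merge (rule 1), frequency
#' recomputation. Idempotent: applying it twice equals applying it once.
#'
#' @param rep A `tcr_repertoire`.
#' @param require_vj Drop records lacking a V or J gene (default `TRUE`).
#' @return The filtered repertoire; its QC bookkeeping is attached and
#'   retrievable with [qc_report()].
#' @export
apply_qc <- function(rep, require_vj = TRUE) {
  input_records <- nrow(rep)
  rep <- collapse_alleles(rep)

  dropped <- list()
  if (require_vj) {
    missing_vj <- rep$v_gene == "" | rep$j_gene == ""
    dropped$missing_vj <- rep[missing_vj, , drop = FALSE]
    rep <- restore_repertoire(rep[!missing_vj, , drop = FALSE], rep)
  } else {
    dropped$missing_vj <- rep[0, , drop = FALSE]
  }

  verdict <- validate_cdr3(rep$cdr3_aa)
  # a record failing any content rule counts under invalid_cdr3; records
  # failing only the length rule count under dropped_length
  length_only <- !verdict$valid & verdict$reason == "length"
  invalid <- !verdict$valid & !length_only
  dropped$invalid_cdr3 <- rep[invalid, , drop = FALSE]
  dropped$length <- rep[length_only, , drop = FALSE]
  rep <- restore_repertoire(rep[verdict$valid, , drop = FALSE], rep)

  before_merge <- nrow(rep)
  rep <- merge_duplicate_cdr3(rep)
  merged <- before_merge - nrow(rep)

  rep <- refresh_frequency(rep)
  if (nrow(rep) == 0 && input_records > 0) {
    warn("all records were removed by quality control.")
  }

  report <- structure(
    list(
      input_records = input_records,
      merged_duplicates = merged,
      dropped_missing_vj = nrow(dropped$missing_vj),
      dropped_invalid_cdr3 = nrow(dropped$invalid_cdr3),
      dropped_length = nrow(dropped$length),
      output_records = nrow(rep),
      dropped_records = lapply(dropped, function(d) {
        tibble::new_tibble(lapply(d, identity), nrow = nrow(d))
      })
    ),
    class = "qc_report"
  )
  attr(rep, "qc_report") <- report
  rep
}

#' Retrieve the QC report attached to a repertoire
#'
#' @param rep A repertoire returned by [apply_qc()].
#' @return A `qc_report` (list with per-rule counts), or `NULL` when QC has
#'   not been applied.
#' @export
qc_report <- function(rep) attr(rep, "qc_report")

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input records        %d\n", x$input_records))
  cat(sprintf("  dropped missing V/J  %d\n", x$dropped_missing_vj))
  cat(sprintf("  dropped invalid CDR3 %d\n", x$dropped_invalid_cdr3))
  cat(sprintf("  dropped length       %d\n", x$dropped_length))
  cat(sprintf("  merged duplicates    %d\n", x$merged_duplicates))
  cat(sprintf("  output records       %d\n", x$output_records))
  invisible(x)
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    input_records = x$input_records,
    merged_duplicates = x$merged_duplicates,
    dropped_missing_vj = x$dropped_missing_vj,
    dropped_invalid_cdr3 = x$dropped_invalid_cdr3,
    dropped_length = x$dropped_length,
    output_records = x$output_records
  )
}

# Serialize a QC report (without record lists) as JSON.
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    report[setdiff(names(report), "dropped_records")],
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
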