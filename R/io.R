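# Input dialects ------------------------------------------------------------
#
# Four clonotype-table dialects are supported:
#   caller_tsv  V(D)J-caller export (MiXCR-like), tab-delimited with
#               count/sequence columns under common alias names
#   cdr3_list   plain text, one CDR3 amino-acid sequence per line
#   airr        AIRR Rearrangement TSV (junction_aa, v_call, j_call,
#               duplicate_count)
#   csv         generic comma-separated file with a user-supplied column map

CALLER_COUNT_ALIASES <- c("cloneCount", "count", "reads")
CALLER_CDR3_ALIASES <- c("aaSeqCDR3", "cdr3aa", "CDR3.aa")
CALLER_V_ALIASES <- c("bestVHit", "allVHitsWithScore", "vGene", "v_gene", "v")
CALLER_J_ALIASES <- c("bestJHit", "allJHitsWithScore", "jGene", "j_gene", "j")

#' Read a clonotype table into a repertoire
#'
#' Parses one per-sample clonotype file into the canonical [repertoire()]
#' model. No quality control is applied; frequencies are computed from
#' counts as read. Rows with a missing or empty CDR3 are dropped with a
#' warning (caller exports routinely contain non-productive rows); missing
#' counts default to 1.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"caller_tsv"`, `"cdr3_list"`, `"airr"`,
#'   `"csv"`. `"auto"` calls [detect_format()].
#' @param column_map For `csv`: named character vector mapping canonical
#'   names (`cdr3`, `count`, `v_gene`, `j_gene`) to file column names; the
#'   `cdr3` entry is mandatory.
#' @param sample_id Sample identifier; defaults to the file base name.
#' @param metadata Named list of sample metadata strings.
#' @return A `tcr_repertoire` with one clonotype per parsable input row,
#'   in file order.
#' @export
read_repertoire <- function(path, format = "auto", column_map = NULL,
                            sample_id = NULL, metadata = list()) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file.", path),
          class = "tcr_io_error")
  }
  format <- match.arg(format, c("auto", "caller_tsv", "cdr3_list", "airr", "csv"))
  if (format == "auto") format <- detect_format(path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  tbl <- switch(format,
    airr = read_dialect_airr(path),
    caller_tsv = read_dialect_caller(path),
    cdr3_list = read_dialect_list(path),
    csv = read_dialect_csv(path, column_map)
  )

  missing_cdr3 <- is.na(tbl$cdr3_aa) | trimws(tbl$cdr3_aa) == ""
  if (any(missing_cdr3)) {
    warn(sprintf("dropped %d row(s) with missing CDR3 sequence.",
                 sum(missing_cdr3)))
    tbl <- tbl[!missing_cdr3, , drop = FALSE]
  }
  if (nrow(tbl) == 0) {
    abort(sprintf("'%s': no parsable clonotype rows.", path),
          class = "tcr_empty_error")
  }
  as_repertoire(tbl, sample_id = sample_id, metadata = metadata)
}

read_dialect_airr <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(tbl, "junction_aa", path)
  tibble::tibble(
    cdr3_aa = tbl$junction_aa,
    v_gene = if ("v_call" %in% names(tbl)) tbl$v_call else "",
    j_gene = if ("j_call" %in% names(tbl)) tbl$j_call else "",
    count = if ("duplicate_count" %in% names(tbl)) tbl$duplicate_count else 1L
  )
}

read_dialect_caller <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  cdr3_col <- first_alias(tbl, CALLER_CDR3_ALIASES)
  if (is.na(cdr3_col)) {
    abort(sprintf(
      "'%s': no CDR3 column found (looked for %s).",
      path, paste(CALLER_CDR3_ALIASES, collapse = ", ")
    ), class = "tcr_schema_error")
  }
  count_col <- first_alias(tbl, CALLER_COUNT_ALIASES)
  v_col <- first_alias(tbl, CALLER_V_ALIASES)
  j_col <- first_alias(tbl, CALLER_J_ALIASES)
  tibble::tibble(
    cdr3_aa = tbl[[cdr3_col]],
    v_gene = if (!is.na(v_col)) tbl[[v_col]] else "",
    j_gene = if (!is.na(j_col)) tbl[[j_col]] else "",
    count = if (!is.na(count_col)) tbl[[count_col]] else 1L
  )
}

read_dialect_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  tibble::tibble(cdr3_aa = lines[lines != ""], count = 1L)
}

read_dialect_csv <- function(path, column_map) {
  if (is.null(column_map) || !"cdr3" %in% names(column_map)) {
    abort("csv input requires `column_map` naming at least the `cdr3` column.",
          class = "tcr_schema_error")
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(tbl, unname(column_map), path)
  pick <- function(key, default) {
    if (key %in% names(column_map)) tbl[[column_map[[key]]]] else default
  }
  tibble::tibble(
    cdr3_aa = tbl[[column_map[["cdr3"]]]],
    v_gene = pick("v_gene", ""),
    j_gene = pick("j_gene", ""),
    count = pick("count", 1L)
  )
}

first_alias <- function(tbl, aliases) {
  hit <- aliases[aliases %in% names(tbl)]
  if (length(hit)) hit[[1]] else NA_character_
}

require_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort(sprintf("'%s': missing mandatory column(s): %s.",
                  path, paste(missing, collapse = ", ")),
          class = "tcr_schema_error")
  }
  invisible(tbl)
}

#' Guess the dialect of a clonotype file
#'
#' AIRR is recognised by a `junction_aa` header; a single-column file of
#' bare sequences (no tabs or commas) is a CDR3 list; a tab-delimited file
#' with recognised count and sequence headers is a caller export; anything
#' else falls back to `csv`.
#'
#' @param path File path (must exist and be non-empty).
#' @return One of `"airr"`, `"caller_tsv"`, `"cdr3_list"`, `"csv"`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file.", path),
          class = "tcr_io_error")
  }
  raw <- readBin(path, what = "raw", n = 4096)
  if (length(raw) == 0) {
    abort(sprintf("'%s' is empty.", path), class = "tcr_empty_error")
  }
  if (any(raw == as.raw(0))) {
    abort(sprintf("'%s' looks binary, not a clonotype table.", path),
          class = "tcr_format_error")
  }
  header <- readLines(path, n = 1, warn = FALSE)
  fields_tab <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if ("junction_aa" %in% fields_tab) {
    return("airr")
  }
  if (grepl("\t", header)) {
    has_count <- any(CALLER_COUNT_ALIASES %in% fields_tab)
    has_cdr3 <- any(CALLER_CDR3_ALIASES %in% fields_tab)
    return(if (has_count && has_cdr3) "caller_tsv" else "csv")
  }
  if (!grepl(",", header) && grepl("^[A-Za-z*_]+$", header)) {
    return("cdr3_list")
  }
  "csv"
}

#' Write a repertoire as AIRR-style TSV
#'
#' Columns `junction_aa`, `v_call`, `j_call`, `duplicate_count`,
#' `frequency`; UTF-8, tab-delimited, `\n` line endings. Empty gene symbols
#' are written as empty cells (not `"NA"`). The output round-trips through
#' `read_repertoire(format = "airr")` losslessly on the canonical fields.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  out <- tibble::tibble(
    junction_aa = rep$cdr3_aa,
    v_call = rep$v_gene,
    j_call = rep$j_gene,
    duplicate_count = rep$count,
    frequency = rep$frequency
  )
  tryCatch(
    readr::write_tsv(out, path, na = "", progress = FALSE),
    error = function(e) {
      abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
            class = "tcr_io_error")
    }
  )
  invisible(path)
}

#' Write a repertoire in any supported input dialect
#'
#' Round-trip fixture writer: emits `airr` (via [write_repertoire()]),
#' `caller_tsv` (cloneCount/aaSeqCDR3/bestVHit/bestJHit), `cdr3_list`
#' (one sequence per line; counts are not representable), or `csv`
#' (columns seq, reads, v, j; read back with
#' `column_map = c(cdr3 = "seq", count = "reads", v_gene = "v", j_gene = "j")`).
#'
#' @inheritParams write_repertoire
#' @param format Target dialect.
#' @return `path`, invisibly.
#' @export
write_repertoire_dialect <- function(rep, path,
                                     format = c("airr", "caller_tsv",
                                                "cdr3_list", "csv")) {
  format <- match.arg(format)
  switch(format,
    airr = write_repertoire(rep, path),
    caller_tsv = readr::write_tsv(
      tibble::tibble(
        cloneCount = rep$count, aaSeqCDR3 = rep$cdr3_aa,
        bestVHit = rep$v_gene, bestJHit = rep$j_gene
      ),
      path, na = "", progress = FALSE
    ),
    cdr3_list = writeLines(rep$cdr3_aa, path),
    csv = readr::write_csv(
      tibble::tibble(
        seq = rep$cdr3_aa, reads = rep$count,
        v = rep$v_gene, j = rep$j_gene
      ),
      path, na = "", progress = FALSE
    )
  )
  invisible(path)
}
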