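# Shared fixtures and independent oracles -----------------------------------

AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Independent Hamming oracle (raw byte comparison, no package code).
bf_hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Independent Levenshtein oracle: textbook dynamic program.
bf_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L,
        d[i + 1, j] + 1L,
        d[i, j] + (x[i] != y[j])
      )
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# Exhaustive Mann-Whitney oracle: enumerate every size-n subset of the
# pooled observations as the "x" group; two-sided P is the probability of
# a U at least as far from nm/2 as observed.
bf_mwu <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  m <- length(y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]) - n * (n + 1) / 2)
  dev <- abs(us - n * m / 2)
  list(u = u_obs, p = mean(dev >= abs(u_obs - n * m / 2) - 1e-9))
}

# Random valid CDR3 string (independent of the package generator).
rand_cdr3 <- function(len = 12) {
  paste0(
    "C",
    paste(sample(AA_LETTERS, len - 2, replace = TRUE), collapse = ""),
    sample(c("F", "W"), 1)
  )
}

# Families of near-identical sequences so Hamming networks have edges:
# each family is one base sequence plus variants at 1-3 substitutions.
make_family_seqs <- function(n_families = 10, family_size = 5, len = 12) {
  seqs <- character(0)
  for (f in seq_len(n_families)) {
    base <- rand_cdr3(len)
    fam <- base
    while (length(fam) < family_size) {
      v <- base
      for (k in seq_len(sample(1:3, 1))) {
        pos <- sample(2:(len - 1), 1)
        substr(v, pos, pos) <- sample(AA_LETTERS, 1)
      }
      fam <- unique(c(fam, v))
    }
    seqs <- c(seqs, fam)
  }
  unique(seqs)
}

# A deliberately dirty repertoire exercising every QC rule.
make_dirty_repertoire <- function(n = 60) {
  good <- replicate(n, rand_cdr3(sample(8:24, 1)))
  bad <- c(
    sub("F$", "*", good[1]), # stop codon
    sub("^C", "A", good[2]), # start anchor
    "CASSQYF", # too short
    paste0("C", strrep("A", 24), "F"), # too long
    sub("F$", "G", good[3]) # end anchor
  )
  cdr3 <- c(good, bad)
  k <- length(cdr3)
  tcrkit::repertoire(
    cdr3_aa = cdr3,
    v_gene = sample(c("TRBV1*01", "TRBV1", "TRBV2", "TRBV12-3*02", ""),
                    k, replace = TRUE),
    j_gene = sample(c("TRBJ1-1*01", "TRBJ2-7", ""), k, replace = TRUE),
    count = sample(1:50, k, replace = TRUE)
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
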