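# Small helper: motif matrix from explicit per-sample sequence lists.
mm_from_seqs <- function(seq_lists, labels = NULL) {
  reps <- purrr::imap(seq_lists, function(s, id) {
    as_repertoire(tibble::tibble(cdr3_aa = s), sample_id = id)
  })
  build_motif_matrix(reps, labels = labels)
}

test_that("k-mer counting slides a step-1 window", {
  rep <- repertoire("CASSF")
  ct <- count_kmers(rep)
  expect_equal(ct, tibble::tibble(motif = c("ASS", "CAS", "SSF"),
                                  count = c(1, 1, 1)))
  ct2 <- count_kmers(repertoire("CAAAF"))
  expect_setequal(ct2$motif, c("CAA", "AAA", "AAF"))
  expect_equal(sum(ct2$count), 3)

  # weighted counting multiplies by clone count
  w <- count_kmers(repertoire("CASSF", count = 4), weighted = TRUE)
  expect_equal(sum(w$count), 12)
})

test_that("total window count is conserved: sum over motifs = sum (L - 2)", {
  withr::with_seed(41, {
    for (i in 1:10) {
      n <- sample(5:40, 1)
      rep <- as_repertoire(tibble::tibble(
        cdr3_aa = unique(replicate(n, rand_cdr3(sample(8:20, 1))))
      ))
      ct <- count_kmers(rep)
      expect_equal(sum(ct$count), sum(nchar(rep$cdr3_aa) - 2))
    }
  })
})

test_that("motif matrices union motifs with zeros and track stage", {
  m <- mm_from_seqs(list(s1 = "CAAAAAAF", s2 = "CWWWWWWF"))
  expect_equal(motif_stage(m), "raw")
  vals <- motif_values(m)
  # disjoint motif blocks: each sample is zero on the other's motifs
  expect_true(all(vals["s1", grepl("W", colnames(vals))] == 0))
  expect_true(all(vals["s2", grepl("A", colnames(vals))] == 0))
  expect_equal(unname(rowSums(vals)), c(6, 6)) # L - 2 windows each
  expect_lte(ncol(vals), 8000)
  expect_true(all(colnames(vals) %in% kmer_universe(3)))

  reps <- list(as_repertoire(tibble::tibble(cdr3_aa = "CASSLGETQYF"),
                             sample_id = "dup"),
               as_repertoire(tibble::tibble(cdr3_aa = "CASRPDRGYTF"),
                             sample_id = "dup"))
  expect_error(build_motif_matrix(reps), class = "tcr_identity_error")
})

test_that("sample filtering trims quantile tails by total motif count", {
  # ten samples whose totals are exactly 1..10 windows (i 3-mers each)
  seq_lists <- purrr::map(1:10, function(i) {
    vapply(seq_len(i), function(j) {
      paste0(AA_LETTERS[i], AA_LETTERS[j], "G")
    }, character(1))
  })
  names(seq_lists) <- sprintf("s%02d", 1:10)
  m <- mm_from_seqs(seq_lists)
  expect_equal(unname(rowSums(motif_values(m))), 1:10)

  f <- filter_samples(m)
  expect_equal(motif_stage(f), "sample_filtered")
  expect_equal(f$sample_id, sprintf("s%02d", 3:8)) # drop {1,2} and {9,10}

  # zero quantiles are the identity
  f0 <- filter_samples(m, lower_q = 0, upper_q = 0)
  expect_equal(f0$sample_id, m$sample_id)

  # ceiling rule: 3 samples at 20% still lose the min and max
  m3 <- mm_from_seqs(seq_lists[c(1, 5, 10)])
  f3 <- filter_samples(m3)
  expect_equal(nrow(f3), 1)
  expect_equal(f3$sample_id, "s05")

  expect_error(filter_samples(m, 0.5, 0.5), class = "tcr_empty_error")
})

test_that("prevalence filtering keeps motifs in a strict group majority", {
  seqs <- list(
    d1 = c("CAAAF"), d2 = c("CAAAF"), d3 = c("CAAAF", "CWWWF"),
    d4 = c("CWWWF")
  )
  m <- mm_from_seqs(seqs, labels = setNames(rep("disease", 4), names(seqs)))
  m <- filter_samples(m, 0, 0)
  f <- filter_prevalence(m, group = "disease")
  # "CAA"/"AAF"/"AAA" in 3 of 4 (0.75 > 0.5) kept; "CWW" etc in 2 of 4 dropped
  expect_true(all(c("CAA", "AAF") %in% motif_names(f)))
  expect_false(any(c("CWW", "WWF") %in% motif_names(f)))
  expect_error(filter_prevalence(m, group = "no_such_group"),
               class = "tcr_label_error")
})

test_that("Mann-Whitney U matches the textbook separated case", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$method, "exact")
  # brute-force: 2 of the 20 arrangements are as extreme
  oracle <- bf_mwu(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, oracle$p)
  expect_equal(oracle$p, 0.1)
})

test_that("Mann-Whitney U agrees with exhaustive enumeration (ties included)", {
  withr::with_seed(50, {
    for (i in 1:60) {
      n <- sample(2:8, 1)
      m <- sample(2:8, 1)
      x <- sample(0:5, n, replace = TRUE) # heavy ties, like motif counts
      y <- sample(0:5, m, replace = TRUE)
      got <- tcrkit:::mwu_core(x, y)
      want <- bf_mwu(x, y)
      expect_equal(got$u, want$u)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney U symmetry and degeneracy properties hold", {
  x <- c(1, 5, 5, 9)
  y <- c(2, 5, 7)
  a <- tcrkit:::mwu_core(x, y)
  b <- tcrkit:::mwu_core(y, x)
  expect_equal(a$u, length(x) * length(y) - b$u)
  expect_equal(a$p, b$p)

  same <- tcrkit:::mwu_core(c(3, 1, 2), c(2, 3, 1))
  expect_equal(same$u, 4.5)
  expect_gt(same$p, 0.9)

  flat <- tcrkit:::mwu_core(rep(2, 5), rep(2, 7))
  expect_equal(flat$p, 1)

  # large-sample branch against R's own approximation (no ties)
  withr::with_seed(51, {
    x <- rnorm(25)
    y <- rnorm(25, mean = 1)
  })
  got <- tcrkit:::mwu_core(x, y)
  expect_equal(got$method, "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
})

test_that("the MWU filter keeps disease-specific motifs only", {
  withr::with_seed(52, {
    # disease: "AAA" always abundant; "GGG" identical in both groups
    dis <- purrr::map(1:10, ~ c(rep("CAAAAAAF", 3), "CGGGGGGF"))
    names(dis) <- paste0("d", 1:10)
    hea <- purrr::map(1:10, ~ "CGGGGGGF")
    names(hea) <- paste0("h", 1:10)
  })
  md <- mm_from_seqs(dis, labels = setNames(rep("disease", 10), names(dis)))
  mh <- mm_from_seqs(hea, labels = setNames(rep("healthy", 10), names(hea)))
  md <- filter_prevalence(filter_samples(md, 0, 0), "disease")
  mh <- filter_samples(mh, 0, 0)

  out <- filter_mwu(md, mh, alpha = 0.05)
  expect_equal(motif_stage(out), "mwu_filtered")
  expect_true("AAA" %in% motif_names(out)) # all-10 vs all-0: exact P tiny
  expect_false("GGG" %in% motif_names(out)) # identical distribution, P = 1
  pv <- attr(out, "mwu_p")
  # exact P for 10 constant-high vs 10 constant-low values: both one-sided
  # extremes of choose(20,10) arrangements
  expect_equal(unname(pv["AAA"]), 2 / choose(20, 10), tolerance = 1e-12)

  # alpha = 1 removes nothing
  all_kept <- filter_mwu(md, mh, alpha = 1)
  expect_equal(motif_names(all_kept), motif_names(md))
})

test_that("Z-score normalisation centres and scales per motif column", {
  seqs <- list(a = "CAAAF", b = c("CAAAF", "CAAAF"),
               c = c("CAAAF", "CAAAF", "CAAAF"))
  m <- mm_from_seqs(seqs)
  z <- zscore_normalize(m)
  expect_equal(motif_stage(z), "normalized")
  vals <- motif_values(z)
  # column (1,2,3) -> population z-scores (-1.2247, 0, 1.2247)
  expect_equal(unname(vals[, "CAA"]), c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-6)
  expect_equal(unname(round(vals[, "CAA"], 4)), c(-1.2247, 0, 1.2247))
  means <- colMeans(vals)
  sds <- apply(vals, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_true(all(abs(means) < 1e-9))
  expect_true(all(abs(sds - 1) < 1e-9 | sds == 0))

  cm <- mm_from_seqs(list(a = "CAAAF", b = "CAAAF"))
  zc <- zscore_normalize(cm)
  expect_true(all(motif_values(zc) == 0)) # constant columns -> zeros
})

test_that("filters never add rows or columns and stages only advance", {
  withr::with_seed(53, {
    seqs <- purrr::map(1:8, ~ unique(replicate(20, rand_cdr3(10))))
    names(seqs) <- paste0("s", 1:8)
  })
  m <- mm_from_seqs(seqs, labels = setNames(rep("g", 8), names(seqs)))
  f1 <- filter_samples(m)
  expect_lte(nrow(f1), nrow(m))
  expect_equal(motif_names(f1), motif_names(m))
  f2 <- filter_prevalence(f1, "g")
  expect_lte(length(motif_names(f2)), length(motif_names(f1)))
  expect_equal(nrow(f2), nrow(f1))
  # stage machinery refuses out-of-order application
  expect_error(filter_samples(f1), class = "tcr_state_error")
  expect_error(filter_prevalence(m, "g"), class = "tcr_state_error")
})
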