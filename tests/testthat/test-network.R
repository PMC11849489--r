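test_that("Hamming distance counts differing positions", {
  expect_equal(hamming_distance("CASSL", "CASSL"), 0L)
  expect_equal(hamming_distance("CASSL", "CASTL"), 1L)
  expect_equal(hamming_distance("CASSL", "CTTTL"), 3L)
  expect_equal(hamming_distance(c("AA", "AB"), c("AB", "AB")), c(1L, 0L))
  expect_error(hamming_distance("CASSL", "CASSLG"),
               class = "tcr_length_mismatch_error")
})

test_that("clustering is length-stratified single linkage", {
  seqs <- c("CASSLGETQYF", "CASTLGETQYF", "CWWWWGHIKLF") # d=1 pair + outlier
  cl <- cluster_cdr3(seqs, max_intra_distance = 2)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[1] == cl$cluster[3])

  # different lengths never co-cluster, even for near-identical strings
  mixed <- cluster_cdr3(c("CASSLGETQYF", "CASSLGETQYYF"))
  expect_equal(length(unique(mixed$cluster)), 2)

  # chaining: A-B at 2, B-C at 2, A-C at 4 still one cluster
  chain <- cluster_cdr3(c("CAAAAAAAAF", "CAACCAAAAF", "CAACCAACCF"))
  expect_equal(length(unique(chain$cluster)), 1)

  expect_equal(length(unique(cluster_cdr3(rep("CASSLGETQYF", 3))$cluster)), 1)
})

test_that("GIANA-style cluster tables import as a drop-in assignment", {
  f <- write_lines_tmp(c("CASSLGETQYF\tc1", "CASTLGETQYF\tc1",
                         "CWWWWGHIKLF\tc2"), ext = ".tsv")
  cl <- read_giana_clusters(f)
  expect_s3_class(cl, "tcr_clusters")
  expect_equal(cl$cluster, c(1L, 1L, 2L))
})

test_that("edges obey the strict Hamming < 3 rule within clusters", {
  # d(A,B) = 1, d(A,C) = 2, d(B,C) = 3: only A-B and A-C are linked
  seqs <- c("CAAAAAAAAF", "CATAAAAAAF", "CAACCAAAAF")
  rep <- repertoire(seqs, count = c(3, 2, 1))
  net <- build_network(rep)
  edges <- tidy(net, "edges")
  expect_equal(nrow(edges), 2)
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  expect_setequal(key, c(
    paste(pmin(seqs[1], seqs[2]), pmax(seqs[1], seqs[2])),
    paste(pmin(seqs[1], seqs[3]), pmax(seqs[1], seqs[3]))
  ))
  expect_true(all(edges$hamming_distance %in% 1:2))

  lone <- build_network(repertoire("CASSLGETQYF"))
  expect_equal(glance(lone)$n_nodes, 1)
  expect_equal(glance(lone)$n_edges, 0)
})

test_that("network edges equal brute-force Hamming thresholding", {
  withr::with_seed(21, {
    seqs <- make_family_seqs(n_families = 12, family_size = 6, len = 12)
  })
  rep <- as_repertoire(tibble::tibble(cdr3_aa = seqs))
  net <- build_network(rep)
  edges <- tidy(net, "edges")
  got <- sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to)))

  want <- character(0)
  for (i in seq_along(seqs)) {
    for (j in seq_len(i - 1)) {
      if (nchar(seqs[i]) == nchar(seqs[j]) &&
          bf_hamming(seqs[i], seqs[j]) < 3) {
        want <- c(want, paste(pmin(seqs[i], seqs[j]),
                              pmax(seqs[i], seqs[j])))
      }
    }
  }
  expect_equal(got, sort(want))
  expect_gt(length(want), 0) # the fixture actually exercises edges
})

test_that("node weights combine min-max scaled betweenness and degree", {
  # path A-B-C: B carries all shortest paths and the highest degree
  seqs <- c("CASSAAAAAF", "CASTAAAAAF", "CASTCCAAAF")
  expect_equal(hamming_distance(seqs[1], seqs[3]), 3L) # no A-C shortcut
  net <- node_weights(build_network(repertoire(seqs)))
  nodes <- tidy(net, "nodes")
  expect_equal(nodes$betweenness[nodes$cdr3_aa == seqs[2]], 1)
  expect_equal(nodes$betweenness[nodes$cdr3_aa != seqs[2]], c(0, 0))
  expect_equal(nodes$weight[nodes$cdr3_aa == seqs[2]], 1)
  expect_equal(nodes$weight[nodes$cdr3_aa != seqs[2]], c(0, 0))

  # complete graph: symmetry forces equal weights
  k4 <- c("CASAAAAAAF", "CASCAAAAAF", "CASDAAAAAF", "CASEAAAAAF")
  nodes <- tidy(node_weights(build_network(repertoire(k4))), "nodes")
  expect_equal(nodes$betweenness, rep(0, 4))
  expect_equal(nodes$weight, rep(0.5, 4)) # constant-component convention

  # isolated node
  iso <- tidy(node_weights(build_network(repertoire("CASSLGETQYF"))), "nodes")
  expect_equal(iso$weight, 0.5)
})

test_that("random-walk communities split clique-of-cliques graphs", {
  # two 5-cliques joined by one bridge edge (built directly as a graph)
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  net <- tcrkit:::new_tcr_network(g)
  net <- detect_communities(net, steps = 4, seed = 7)
  mem <- tidy(net, "nodes")$community
  expect_equal(length(unique(mem)), 2)
  expect_equal(length(unique(mem[1:5])), 1)
  expect_equal(length(unique(mem[6:10])), 1)

  # oracle: the clique split is the modularity-optimal bipartition
  best <- -Inf
  best_part <- NULL
  for (mask in 1:(2^9)) {
    part <- c(1L, as.integer(intToBits(mask))[1:9]) + 1L
    q <- igraph::modularity(g, part)
    if (q > best) {
      best <- q
      best_part <- part
    }
  }
  expect_equal(best_part, c(rep(best_part[1], 5), rep(best_part[6], 5)))
  expect_equal(igraph::modularity(g, mem), best)
})

test_that("edgeless graphs give singleton communities, seeds fix results", {
  withr::with_seed(30, {
    far <- replicate(6, rand_cdr3(18))
  })
  rep <- as_repertoire(tibble::tibble(cdr3_aa = far))
  net <- build_network(rep)
  if (glance(net)$n_edges == 0) {
    out <- detect_communities(net, seed = 1)
    expect_equal(sort(tidy(out, "nodes")$community), 1:6)
  }

  withr::with_seed(22, {
    seqs <- make_family_seqs(n_families = 8, family_size = 5, len = 11)
  })
  rep <- as_repertoire(tibble::tibble(cdr3_aa = seqs))
  run <- function() {
    tidy(detect_communities(build_network(rep), steps = 4, seed = 99),
         "nodes")$community
  }
  expect_identical(run(), run())
  # communities partition the node set
  mem <- run()
  expect_equal(length(mem), length(seqs))
  expect_true(all(!is.na(mem)))
})

test_that("community logos are frequency-weighted over shared-length members", {
  rep <- repertoire(c("CASSL", "CASTL"), count = c(1, 1))
  net <- detect_communities(build_network(rep), seed = 1)
  logos <- community_logos(net)
  expect_length(logos, 1)
  pwm <- logos[[1]]
  p4 <- pwm[pwm$position == 4, ]
  expect_equal(sort(p4$prob), c(0.5, 0.5))
  conserved <- pwm[pwm$position == 1, ]
  expect_equal(conserved$prob, 1)
  sums <- tapply(pwm$prob, pwm$position, sum)
  expect_equal(as.numeric(sums), rep(1, 5), tolerance = 1e-9)

  single <- detect_communities(build_network(repertoire("CASSLGETQYF")),
                               seed = 1)
  lone_pwm <- community_logos(single)[[1]]
  expect_true(all(lone_pwm$prob == 1))
})

test_that("networks export GraphML and TSV tables", {
  withr::with_seed(23, {
    seqs <- make_family_seqs(n_families = 4, family_size = 4, len = 10)
  })
  rep <- as_repertoire(tibble::tibble(cdr3_aa = seqs))
  net <- detect_communities(node_weights(build_network(rep)), seed = 1)
  dir <- withr::local_tempdir()
  write_network(net, dir)
  expect_setequal(list.files(dir),
                  c("network.graphml", "nodes.tsv", "edges.tsv"))
  back <- igraph::read_graph(file.path(dir, "network.graphml"),
                             format = "graphml")
  expect_equal(igraph::vcount(back), length(seqs))
})
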