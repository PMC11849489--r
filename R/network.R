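# CDR3 similarity network ---------------------------------------------------
#
# Workflow: cluster similar CDR3s (length-stratified single-linkage Hamming
# clustering; an import hook accepts externally produced cluster tables),
# link within-cluster pairs at Hamming distance < 3, weight nodes by
# betweenness + degree, detect random-walk (walktrap) communities, and emit
# a sequence logo per community.

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which the two strings differ. Vectorised over
#' pairs with recycling.
#'
#' @param a,b Character vectors of sequences.
#' @return Integer vector of distances.
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(nchar(a) != nchar(b))) {
    abort("Hamming distance requires equal-length sequences.",
          class = "tcr_length_mismatch_error")
  }
  purrr::map2_int(strsplit(a, "", fixed = TRUE), strsplit(b, "", fixed = TRUE),
                  ~ sum(.x != .y))
}

# Dense Hamming distance matrix for equal-length sequences.
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n)
  for (p in seq_len(ncol(chars))) {
    d <- d + outer(chars[, p], chars[, p], "!=")
  }
  dimnames(d) <- list(seqs, seqs)
  d
}

#' Cluster similar CDR3 sequences
#'
#' Length-stratified single-linkage clustering: sequences of one length are
#' joined into a cluster whenever a chain of pairs at Hamming distance
#' `<= max_intra_distance` connects them (connected components of the
#' thresholded distance graph). Sequences of different lengths never
#' co-cluster; singletons are allowed. Real external cluster assignments
#' can be substituted via [read_giana_clusters()].
#'
#' @param x A `tcr_repertoire` (unique CDR3s, e.g. QC-passed) or a
#'   character vector of sequences.
#' @param max_intra_distance Maximum Hamming distance for single-linkage
#'   joins (default 2, consistent with the downstream "< 3" link rule).
#' @return A `tcr_clusters` tibble (`cdr3_aa`, `length`, `cluster`) with a
#'   `parameters` attribute.
#' @export
cluster_cdr3 <- function(x, max_intra_distance = 2) {
  seqs <- unique(if (is.data.frame(x)) x$cdr3_aa else as.character(x))
  assignment <- integer(length(seqs))
  names(assignment) <- seqs
  next_id <- 1L
  for (len in sort(unique(nchar(seqs)))) {
    members <- seqs[nchar(seqs) == len]
    if (length(members) == 1) {
      comp <- 1L
    } else {
      adj <- hamming_matrix(members) <= max_intra_distance
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)$membership
    }
    assignment[members] <- next_id + comp - 1L
    next_id <- next_id + max(comp)
  }
  out <- tibble::tibble(
    cdr3_aa = seqs,
    length = nchar(seqs),
    cluster = unname(assignment[seqs])
  )
  structure(out,
    parameters = list(max_intra_distance = max_intra_distance,
                      length_stratified = TRUE),
    class = c("tcr_clusters", class(out))
  )
}

#' Import an externally produced cluster table
#'
#' Reads a GIANA-style two-column TSV (sequence, cluster id; no header or
#' with a header whose first field is non-sequence) as a `tcr_clusters`
#' object, so clusters computed by an external tool can replace the
#' built-in Hamming clustering.
#'
#' @param path TSV file path.
#' @return A `tcr_clusters` tibble.
#' @export
read_giana_clusters <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("cdr3_aa", "cluster"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tbl) && !grepl("^[A-Za-z*_]+$", tbl$cdr3_aa[1])) {
    tbl <- tbl[-1, , drop = FALSE] # header row
  }
  out <- tibble::tibble(
    cdr3_aa = toupper(tbl$cdr3_aa),
    length = nchar(tbl$cdr3_aa),
    cluster = as.integer(factor(tbl$cluster, levels = unique(tbl$cluster)))
  )
  structure(out,
    parameters = list(source = "import"),
    class = c("tcr_clusters", class(out))
  )
}

#' Build the CDR3 similarity network
#'
#' Within each cluster, every sequence pair at Hamming distance strictly
#' below `link_threshold` becomes an edge; cross-cluster edges are never
#' created. Nodes are the repertoire's unique CDR3s and carry their clone
#' frequency. An optional externally produced alignment (named character
#' vector: aligned sequence per CDR3) may replace the identity alignment
#' used for the length-stratified clusters.
#'
#' @param rep A `tcr_repertoire`.
#' @param clusters A `tcr_clusters` on `rep`'s sequences; computed with
#'   [cluster_cdr3()] defaults when omitted.
#' @param link_threshold Edges require Hamming distance `< link_threshold`
#'   (default 3).
#' @param alignment Optional named character vector of aligned sequences.
#' @return A `tcr_network`: igraph graph plus node and edge tibbles.
#' @export
build_network <- function(rep, clusters = NULL, link_threshold = 3,
                          alignment = NULL) {
  clusters <- clusters %||% cluster_cdr3(rep)
  nodes <- tibble::as_tibble(rep)[c("cdr3_aa", "frequency")] |>
    dplyr::distinct(.data$cdr3_aa, .keep_all = TRUE) |>
    dplyr::left_join(tibble::as_tibble(clusters)[c("cdr3_aa", "cluster")],
                     by = "cdr3_aa")
  aligned <- function(s) if (!is.null(alignment)) unname(alignment[s]) else s

  edges <- purrr::map_dfr(split(nodes$cdr3_aa, nodes$cluster), function(members) {
    if (length(members) < 2) {
      return(tibble::tibble(from = character(), to = character(),
                            hamming_distance = integer()))
    }
    d <- hamming_matrix(aligned(members))
    idx <- which(upper.tri(d) & d < link_threshold, arr.ind = TRUE)
    tibble::tibble(
      from = members[idx[, 1]],
      to = members[idx[, 2]],
      hamming_distance = d[idx]
    )
  })

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new_tcr_network(g, params = list(link_threshold = link_threshold,
                                   clusters = attr(clusters, "parameters")))
}

# Wrap an igraph graph (vertex attr `frequency` optional) as a tcr_network.
new_tcr_network <- function(g, params = list()) {
  structure(list(graph = g, params = params), class = "tcr_network")
}

#' @export
print.tcr_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "# CDR3 similarity network: %d nodes, %d edges%s\n",
    igraph::vcount(g), igraph::ecount(g),
    if (!is.null(igraph::V(g)$community)) {
      sprintf(", %d communities", length(unique(igraph::V(g)$community)))
    } else ""
  ))
  invisible(x)
}

#' Node weights from betweenness and degree
#'
#' Computes unweighted shortest-path betweenness centrality and degree for
#' every node, min-max scales each within its connected component (a
#' component where the statistic is constant scores 0.5), and combines
#' them as `weight = betweenness_coef * scaled_betweenness +
#' degree_coef * scaled_degree`.
#'
#' @param net A `tcr_network`.
#' @param betweenness_coef,degree_coef Combination coefficients
#'   (default 0.5 each).
#' @return The network with `degree`, `betweenness` and `weight` node
#'   attributes filled in.
#' @export
node_weights <- function(net, betweenness_coef = 0.5, degree_coef = 0.5) {
  g <- net$graph
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  comp <- igraph::components(g)$membership
  minmax <- function(x) {
    ave(x, comp, FUN = function(v) {
      if (max(v) == min(v)) rep(0.5, length(v)) else (v - min(v)) / (max(v) - min(v))
    })
  }
  igraph::V(g)$degree <- deg
  igraph::V(g)$betweenness <- btw
  igraph::V(g)$weight <- betweenness_coef * minmax(btw) + degree_coef * minmax(deg)
  net$graph <- g
  net$params$weight_coefs <- c(betweenness = betweenness_coef,
                               degree = degree_coef)
  net
}

#' Random-walk community detection
#'
#' Walktrap community detection (short random walks of length `steps`) on
#' the non-isolated part of the network; isolated nodes become singleton
#' communities. The result is a partition of all nodes and is
#' deterministic under a fixed seed.
#'
#' @param net A `tcr_network`.
#' @param steps Random-walk length (default 4).
#' @param seed Integer RNG seed.
#' @return The network with a `community` node attribute.
#' @export
detect_communities <- function(net, steps = 4, seed = 1) {
  g <- net$graph
  membership <- integer(igraph::vcount(g))
  isolated <- igraph::degree(g) == 0
  if (any(!isolated)) {
    sub <- igraph::induced_subgraph(g, which(!isolated))
    wt <- withr::with_seed(seed,
      igraph::cluster_walktrap(sub, steps = steps)
    )
    membership[!isolated] <- igraph::membership(wt)
  }
  n_conn <- if (any(!isolated)) max(membership[!isolated]) else 0L
  membership[isolated] <- n_conn + seq_len(sum(isolated))
  igraph::V(g)$community <- membership
  net$graph <- g
  net$params$walk_steps <- steps
  net$params$seed <- seed
  net
}

#' Per-community sequence logos
#'
#' Frequency-weighted position weight matrix of each community's member
#' sequences. Community members share one CDR3 length by construction
#' (clusters are length-stratified), so no alignment is needed; a position
#' is conserved when a single letter carries probability 1.
#'
#' @param net A `tcr_network` with communities assigned.
#' @return Named list of `tcr_pwm`, one per community id.
#' @export
community_logos <- function(net) {
  g <- net$graph
  if (is.null(igraph::V(g)$community)) {
    abort("run detect_communities() first.", class = "tcr_state_error")
  }
  nodes <- tibble::tibble(
    cdr3_aa = igraph::V(g)$name,
    frequency = igraph::V(g)$frequency %||% rep(1, igraph::vcount(g)),
    community = igraph::V(g)$community
  )
  split(nodes, nodes$community) |>
    purrr::map(~ position_weight_matrix(.x$cdr3_aa, weights = .x$frequency))
}

#' @export
tidy.tcr_network <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  g <- x$graph
  if (what == "nodes") {
    tibble::tibble(
      cdr3_aa = igraph::V(g)$name,
      frequency = igraph::V(g)$frequency %||% rep(NA_real_, igraph::vcount(g)),
      cluster = igraph::V(g)$cluster %||% rep(NA_integer_, igraph::vcount(g)),
      degree = igraph::V(g)$degree %||% igraph::degree(g),
      betweenness = igraph::V(g)$betweenness %||% rep(NA_real_, igraph::vcount(g)),
      weight = igraph::V(g)$weight %||% rep(NA_real_, igraph::vcount(g)),
      community = igraph::V(g)$community %||% rep(NA_integer_, igraph::vcount(g))
    )
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    tibble::as_tibble(el) |>
      dplyr::rename(hamming_distance = "hamming_distance")
  }
}

#' @export
glance.tcr_network <- function(x, ...) {
  g <- x$graph
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_communities = if (is.null(igraph::V(g)$community)) NA_integer_ else
      length(unique(igraph::V(g)$community))
  )
}

#' Export a network to disk
#'
#' Writes `network.graphml` (GraphML with all node attributes),
#' `nodes.tsv` and `edges.tsv` under `dir`.
#'
#' @param net A `tcr_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(net$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  readr::write_tsv(tidy(net, "nodes"), file.path(dir, "nodes.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(net, "edges"), file.path(dir, "edges.tsv"),
                   progress = FALSE)
  invisible(dir)
}
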