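# Low-dimensional embedding of motif profiles -------------------------------
#
# Default backend: diffusion map with potential distances. k-NN Gaussian
# affinities with adaptive bandwidth -> row-normalised diffusion operator ->
# t-step transition matrix -> log-potential coordinates -> classical metric
# scaling. A pluggable seam accepts any function(X, n_components) so an
# external embedding (e.g. a PHATE implementation) can be substituted.

#' Fit a low-dimensional embedding of a normalised motif matrix
#'
#' @param m A `motif_matrix` at stage `"normalized"` with at least 3
#'   samples.
#' @param n_components Output dimensionality (default 2).
#' @param backend `"diffusion"` (default) or a function
#'   `function(X, n_components)` returning a coordinates matrix, for
#'   plugging in an external embedding algorithm.
#' @param knn Neighbourhood size for the adaptive kernel bandwidth
#'   (default 5, capped at n - 1).
#' @param t Diffusion time: number of transition-matrix steps (default 3).
#' @param seed Integer seed, recorded with the model; the default backend
#'   is deterministic, the seed guards pluggable backends.
#' @return A `tcr_embedding` model: reference coordinates, the reference
#'   feature matrix, the normalisation constants inherited from `m`, and
#'   the fit parameters.
#' @export
fit_embedding <- function(m, n_components = 2, backend = "diffusion",
                          knn = 5, t = 3, seed = 1) {
  check_stage(m, "normalized")
  x <- motif_values(m)
  n <- nrow(x)
  if (n < max(3, n_components + 1)) {
    abort(sprintf("need at least %d samples to fit %d components.",
                  max(3, n_components + 1), n_components),
          class = "tcr_size_error")
  }
  coords <- withr::with_seed(seed, {
    if (is.function(backend)) {
      backend(x, n_components)
    } else {
      diffusion_coords(x, n_components, knn = knn, t = t)
    }
  })
  coords <- fix_signs(coords)
  colnames(coords) <- paste0("dim", seq_len(n_components))
  structure(
    list(
      coordinates = tibble::tibble(sample_id = m$sample_id,
                                   label = m$label) |>
        dplyr::bind_cols(tibble::as_tibble(coords)),
      features = x,
      motifs = motif_names(m),
      center = attr(m, "center"),
      scale = attr(m, "scale"),
      backend_tag = if (is.function(backend)) "custom" else "diffusion",
      params = list(n_components = n_components, knn = knn, t = t,
                    seed = seed)
    ),
    class = "tcr_embedding"
  )
}

diffusion_coords <- function(x, n_components, knn = 5, t = 3) {
  n <- nrow(x)
  knn <- max(2, min(knn, n - 1))
  d <- as.matrix(dist(x))
  # adaptive bandwidth: distance to the knn-th nearest neighbour
  eps <- apply(d, 1, function(row) sort(row[row >= 0])[knn + 1])
  eps[eps == 0] <- min(eps[eps > 0], 1)
  k <- exp(-(d / eps)^2)
  k <- (k + t(k)) / 2
  p <- k / rowSums(k)
  pt <- p
  if (t > 1) {
    for (i in seq_len(t - 1)) pt <- pt %*% p
  }
  pot <- -log(pt + 1e-12)
  cmdscale(dist(pot), k = n_components)
}

# Deterministic orientation: each axis has its largest-magnitude loading
# positive (classical scaling is sign-ambiguous).
fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Project a new sample into a fitted embedding
#'
#' Aligns the new sample's motif counts to the model's motif columns
#' (missing motifs become 0), applies the model's stored Z-score
#' constants, then places the sample by a Nystrom-style kernel
#' interpolation: an inverse-squared-distance weighted average of the
#' `n_neighbors` nearest reference samples' coordinates. Re-projecting a
#' reference sample reproduces its fitted position.
#'
#' @param model A `tcr_embedding`.
#' @param sample A named numeric vector of motif counts, or a
#'   `tcr_repertoire` (counted with the model's k first).
#' @param n_neighbors Number of reference neighbours (default 15).
#' @return One-row tibble with the embedded coordinates.
#' @export
embed_new <- function(model, sample, n_neighbors = 15) {
  if (inherits(sample, "tcr_repertoire")) {
    k <- nchar(model$motifs[1])
    ct <- count_kmers(sample, k = k)
    sample <- setNames(ct$count, ct$motif)
  }
  v <- setNames(numeric(length(model$motifs)), model$motifs)
  shared <- intersect(names(sample), model$motifs)
  v[shared] <- sample[shared]
  coords <- as.matrix(model$coordinates[paste0(
    "dim", seq_len(model$params$n_components))])

  if (all(v == 0)) {
    warn("aligned motif vector is all zero; returning the reference centroid.")
    ctr <- colMeans(coords)
    return(tibble::as_tibble(as.list(ctr)))
  }
  scale <- ifelse(model$scale > 0, model$scale, 1)
  z <- (v - model$center) / scale
  z[model$scale == 0] <- 0

  d <- sqrt(colSums((t(model$features) - z)^2))
  nn <- order(d)[seq_len(min(n_neighbors, length(d)))]
  w <- 1 / (d[nn]^2 + 1e-12)
  w <- w / sum(w)
  out <- colSums(coords[nn, , drop = FALSE] * w)
  tibble::as_tibble(as.list(out))
}

#' @export
print.tcr_embedding <- function(x, ...) {
  cat(sprintf(
    "# %s embedding: %d reference samples, %d motifs, %d components\n",
    x$backend_tag, nrow(x$coordinates), length(x$motifs),
    x$params$n_components
  ))
  invisible(x)
}

#' @export
tidy.tcr_embedding <- function(x, ...) x$coordinates

#' @export
glance.tcr_embedding <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_motifs = length(x$motifs),
    n_components = x$params$n_components,
    backend = x$backend_tag
  )
}

#' Persist and restore an embedding model
#'
#' Plain-text serialisation under `dir`: `coordinates.tsv`,
#' `features.tsv`, and `model.json` (motifs, Z-score constants,
#' parameters).
#'
#' @param model A `tcr_embedding`.
#' @param dir Directory path.
#' @return `write_embedding()` returns `dir` invisibly;
#'   `read_embedding()` the restored `tcr_embedding`.
#' @export
write_embedding <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(model$coordinates, file.path(dir, "coordinates.tsv"),
                   progress = FALSE)
  feat <- tibble::as_tibble(model$features) |>
    dplyr::mutate(sample_id = rownames(model$features), .before = 1)
  readr::write_tsv(feat, file.path(dir, "features.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(motifs = model$motifs, center = model$center, scale = model$scale,
         backend_tag = model$backend_tag, params = model$params),
    file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  coords <- readr::read_tsv(file.path(dir, "coordinates.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  feat <- readr::read_tsv(file.path(dir, "features.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  features <- as.matrix(feat[setdiff(names(feat), "sample_id")])
  rownames(features) <- feat$sample_id
  structure(
    list(
      coordinates = coords,
      features = features,
      motifs = meta$motifs,
      center = setNames(unlist(meta$center), meta$motifs),
      scale = setNames(unlist(meta$scale), meta$motifs),
      backend_tag = meta$backend_tag,
      params = meta$params
    ),
    class = "tcr_embedding"
  )
}
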