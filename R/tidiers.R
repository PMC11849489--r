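# broom-style generics -------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.tcr_repertoire <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @export
glance.tcr_repertoire <- function(x, ...) {
  tibble::tibble(
    sample_id = sample_id(x),
    n_clonotypes = nrow(x),
    total_count = total_count(x)
  )
}

#' @export
tidy.tcr_pwm <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @export
tidy.diversity_profile <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @export
glance.diversity_profile <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id"),
    base = attr(x, "base"),
    richness_entropy = x$entropy[x$alpha == 0][1],
    shannon_entropy = x$entropy[x$alpha == 1][1],
    min_entropy = x$entropy[is.infinite(x$alpha)][1]
  )
}

# Strip custom classes and attributes, leaving a plain tibble.
unclass_tbl <- function(x) {
  tibble::new_tibble(lapply(x, identity), nrow = nrow(x))
}
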