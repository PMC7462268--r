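# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a vascular network into a per-segment table
#'
#' @param x A [vascular_network()].
#' @param ... Unused.
#' @return Tibble: one row per segment with endpoint coordinates.
#' @export
tidy.vascular_network <- function(x, ...) {
  nod <- x$nodes
  seg <- x$segments
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  dplyr::mutate(seg,
    xa = nod$x[ia], ya = nod$y[ia], za = nod$z[ia],
    xb = nod$x[ib], yb = nod$y[ib], zb = nod$z[ib])
}

#' @rdname tidy.vascular_network
#' @export
glance.vascular_network <- function(x, ...) {
  v <- prod(x$domain) * 1e-9
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_segments = nrow(x$segments),
    n_arterial_roots = sum(x$nodes$kind == "arterial_root"),
    n_venous_roots = sum(x$nodes$kind == "venous_root"),
    total_length_mm = sum(x$segments$length) * 1e-3,
    mvd = sum(x$segments$length) * 1e-3 / v,
    rbv = sum(pi * x$segments$radius^2 * x$segments$length) /
      prod(x$domain))
}

#' Tidy a flow solution
#'
#' @param x A [solve_flow()] result.
#' @param ... Unused.
#' @return The per-segment tibble (`id`, `flow`, `hct`, `c_hboc`,
#'   `viscosity`, `shear`).
#' @export
tidy.flow_solution <- function(x, ...) x$segments

#' @rdname tidy.flow_solution
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    n_segments = nrow(x$segments),
    total_flow = sum(abs(x$segments$flow)) / 2,
    median_shear = stats::median(x$segments$shear),
    hct_min = min(x$segments$hct), hct_max = max(x$segments$hct))
}

#' Tidy an oxygen solution
#'
#' @param x A [solve_coupled()] result.
#' @param ... Unused.
#' @return The per-segment tibble (inlet/outlet/mean pO2, O2 transfer).
#' @export
tidy.oxygen_solution <- function(x, ...) x$segments

#' @rdname tidy.oxygen_solution
#' @export
glance.oxygen_solution <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, iterations = x$iterations,
    mean_tissue_po2 = mean(x$grid$po2),
    min_tissue_po2 = min(x$grid$po2),
    mean_outlet_po2 = mean(x$segments$outlet_po2),
    total_o2_transfer = sum(x$segments$o2_transfer))
}

#' Tidy a Sherwood-number fit
#'
#' @param x A [fit_sherwood()] result.
#' @param ... Unused.
#' @return Tibble of coefficient terms and estimates.
#' @export
tidy.sherwood_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.sherwood_fit
#' @export
glance.sherwood_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points)
}
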