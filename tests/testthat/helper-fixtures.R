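# Shared fixtures, built in code. Heavy objects are memoised for the session
# so several test files can reuse one converged simulation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# single straight tube between an arterial and a venous root
single_tube_network <- function(radius = 10, length = 200) {
  nodes <- tibble::tibble(
    id = 1:2, x = c(0, length), y = 0, z = 0,
    kind = c("arterial_root", "venous_root"))
  segments <- tibble::tibble(
    id = 1L, a = 1L, b = 2L, radius = radius, length = length,
    wall_type = "arteriole", region = "host")
  vascular_network(nodes, segments, domain = c(length, 100, 100))
}

# symmetric Y bifurcation: one parent, two identical daughters to venous roots
y_bifurcation_network <- function(r_parent = 12, r_daughter = 8,
                                  l = 100) {
  nodes <- tibble::tibble(
    id = 1:4,
    x = c(0, l, 2 * l, 2 * l), y = c(0, 0, 60, -60), z = 0,
    kind = c("arterial_root", "interior", "venous_root", "venous_root"))
  segments <- tibble::tibble(
    id = 1:3, a = c(1L, 2L, 2L), b = c(2L, 3L, 4L),
    radius = c(r_parent, r_daughter, r_daughter),
    length = c(l, sqrt(l^2 + 60^2), sqrt(l^2 + 60^2)),
    wall_type = c("arteriole", "capillary", "capillary"), region = "host")
  vascular_network(nodes, segments, domain = c(2 * l, 200, 100))
}

# small random spanning tree between roots, for linear-algebra oracles
random_tree_network <- function(n_nodes = 50, seed = 3) {
  set.seed(seed)
  pos <- matrix(runif(3 * n_nodes, 0, 500), ncol = 3)
  parent <- c(NA, vapply(2:n_nodes, function(i) {
    sample.int(i - 1, 1)
  }, integer(1)))
  kind <- rep("interior", n_nodes)
  kind[1] <- "arterial_root"
  leaves <- setdiff(seq_len(n_nodes), parent[-1])
  kind[leaves[seq_len(max(1, length(leaves) %/% 2))]] <- "venous_root"
  nodes <- tibble::tibble(id = seq_len(n_nodes), x = pos[, 1], y = pos[, 2],
                          z = pos[, 3], kind = kind)
  segments <- tibble::tibble(
    id = seq_len(n_nodes - 1), a = parent[-1], b = 2:n_nodes,
    radius = runif(n_nodes - 1, 3, 15),
    length = sqrt(rowSums((pos[-1, , drop = FALSE] -
                             pos[parent[-1], , drop = FALSE])^2)),
    wall_type = "capillary", region = "host")
  vascular_network(nodes, segments, domain = c(500, 500, 500))
}

# uniform consuming tissue grid with no tumor phases
host_only_grid <- function(shape = c(8, 8, 8), spacing = 30,
                           params = transport_params("mouse")) {
  tissue_grid(spacing, shape,
              phi_normal = array(1, shape),
              phi_tumor = array(0, shape),
              phi_necrotic = array(0, shape), params = params)
}

# zero-consumption grid (all phase fractions zero)
inert_grid <- function(shape = c(8, 8, 8), spacing = 30) {
  tissue_grid(spacing, shape,
              phi_normal = array(0, shape),
              phi_tumor = array(0, shape),
              phi_necrotic = array(0, shape))
}

# the standard desk-scale tumor fixture shared across heavy tests
standard_fixture <- function(seed = 7) {
  memo(paste0("fixture", seed), {
    net <- generate_av_network(480, 60, 4, 250, seed = seed)
    ph <- apply_tumor_phantom(net, radius = 150, necrotic_radius = 60,
                              dilation_factor = 1.3, prune_fraction = 0.3,
                              seed = seed + 1, grid_spacing = 30)
    ph
  })
}

standard_oxygen_run <- function(seed = 7) {
  memo(paste0("oxrun", seed), {
    ph <- standard_fixture(seed)
    comp <- host_blood("mouse")
    flow <- solve_flow(ph$network, comp, root_conductance = 12000)
    params <- transport_params("mouse", max_outer_iter = 150)
    ox <- solve_coupled(ph$network, ph$grid, flow, comp, boundary_model(),
                        params)
    list(network = ph$network, grid = ph$grid, flow = flow, ox = ox,
         comp = comp, params = params)
  })
}
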