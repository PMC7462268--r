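# Plain-text persistence: networks as paired CSV tables or one JSON
# document, tissue grids and field containers as JSON.

#' Write / read a vascular network as paired CSV tables
#'
#' `nodes.csv` holds `id,x,y,z,kind`; `segments.csv` holds
#' `id,a,b,radius,length,wall_type,region`.
#'
#' @param network A [vascular_network()].
#' @param dir Directory for the two files (created if missing).
#' @return `write_network_csv` the directory, invisibly;
#'   `read_network_csv` a [vascular_network()].
#' @export
write_network_csv <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(network$nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(network$segments, file.path(dir, "segments.csv"),
                   row.names = FALSE)
  meta <- list(domain = network$domain, lattice_pitch = network$lattice_pitch)
  jsonlite::write_json(meta, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"),
                           stringsAsFactors = FALSE)
  segments <- utils::read.csv(file.path(dir, "segments.csv"),
                              stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "network.json"),
                              simplifyVector = TRUE)
  vascular_network(nodes, segments, meta$domain, meta$lattice_pitch)
}

#' Write / read a vascular network as one JSON document
#'
#' @inheritParams write_network_csv
#' @param path JSON file path.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes, segments = network$segments,
         domain = network$domain, lattice_pitch = network$lattice_pitch),
    path, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vascular_network(tibble::as_tibble(obj$nodes),
                   tibble::as_tibble(obj$segments),
                   obj$domain, obj$lattice_pitch)
}

#' Write / read a tissue grid (JSON container)
#'
#' All per-voxel fields (phase fractions, consumption maps, the pO2 field)
#' are stored flattened in Fortran (column-major) order with the grid shape
#' and spacing as attributes, in a single JSON document.
#'
#' @param grid A [tissue_grid()].
#' @param path File path.
#' @export
write_tissue_grid <- function(grid, path) {
  jsonlite::write_json(list(
    spacing = grid$spacing, shape = grid$shape, origin = grid$origin,
    phi_normal = as.vector(grid$phi_normal),
    phi_tumor = as.vector(grid$phi_tumor),
    phi_necrotic = as.vector(grid$phi_necrotic),
    v_m = as.vector(grid$v_m), k_m = as.vector(grid$k_m),
    po2 = as.vector(grid$po2)), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tissue_grid
#' @export
read_tissue_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sh <- as.integer(obj$shape)
  g <- structure(list(
    spacing = obj$spacing, shape = sh, origin = obj$origin,
    phi_normal = array(obj$phi_normal, sh),
    phi_tumor = array(obj$phi_tumor, sh),
    phi_necrotic = array(obj$phi_necrotic, sh),
    v_m = array(obj$v_m, sh), k_m = array(obj$k_m, sh),
    po2 = array(obj$po2, sh)), class = "tissue_grid")
  g
}

# 32-bit FNV-1a over a deparsed object; stable across sessions, used only to
# stamp run manifests
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
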