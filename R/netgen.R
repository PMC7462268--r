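# Seeded generator of desk-scale synthetic arterio-venous networks on a cubic
# lattice, plus a parametric tumor phantom standing in for a full tumor-growth
# simulation. Networks are pure functions of (configuration, seed).

# Run `code` with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Construct a vascular network object
#'
#' Lower-level constructor used by [generate_av_network()] and by the
#' CSV/JSON readers. Nodes and segments are plain tibbles so they compose
#' with dplyr verbs.
#'
#' @param nodes Tibble with columns `id`, `x`, `y`, `z` (um) and `kind`
#'   (`"interior"`, `"arterial_root"`, `"venous_root"`).
#' @param segments Tibble with columns `id`, `a`, `b` (node ids), `radius`
#'   (um), `length` (um), `wall_type` (`artery`, `arteriole`, `capillary`,
#'   `venule`, `vein`) and `region` (`host` or `tumor`).
#' @param domain Domain edge lengths, um (length 3).
#' @param lattice_pitch Lattice pitch used at generation, um (or `NA`).
#' @return An object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, segments, domain,
                             lattice_pitch = NA_real_) {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("id", "x", "y", "z", "kind") %in% names(nodes)),
            all(c("id", "a", "b", "radius", "length", "wall_type", "region")
                %in% names(segments)))
  if (nrow(segments) && (any(segments$radius <= 0) || any(segments$length <= 0))) {
    stop("segment radii and lengths must be positive", call. = FALSE)
  }
  structure(list(nodes = nodes, segments = segments,
                 domain = rep_len(domain, 3), lattice_pitch = lattice_pitch),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf(
    "<vascular_network> %d nodes, %d segments in %g x %g x %g um domain\n",
    nrow(x$nodes), nrow(x$segments),
    x$domain[1], x$domain[2], x$domain[3]))
  tab <- table(x$segments$wall_type)
  cat("  segments:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

lattice_key <- function(i, j, k, dims) {
  (i - 1L) + dims[1] * ((j - 1L) + dims[2] * (k - 1L)) + 1L
}

lattice_coords <- function(key, dims) {
  key0 <- key - 1L
  i <- key0 %% dims[1]
  j <- (key0 %/% dims[1]) %% dims[2]
  k <- key0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

lattice_neighbors <- function(key, dims) {
  ijk <- lattice_coords(key, dims)
  out <- integer(0)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[d] <- nb[d] + s
      if (nb[d] >= 1L && nb[d] <= dims[d]) {
        out <- c(out, lattice_key(nb[1], nb[2], nb[3], dims))
      }
    }
  }
  out
}

# Root placement presets on the lattice boundary. Arterial and venous roots
# alternate over opposite corners (preset "corners") or face centers
# ("faces"), emulating peripheral vs proximal/distal supply configurations.
root_positions <- function(dims, n_roots, preset = c("corners", "faces")) {
  preset <- match.arg(preset)
  if (preset == "corners") {
    corners <- rbind(
      c(1L, 1L, 1L), dims,
      c(dims[1], 1L, 1L), c(1L, dims[2], dims[3]),
      c(1L, dims[2], 1L), c(dims[1], 1L, dims[3]),
      c(1L, 1L, dims[3]), c(dims[1], dims[2], 1L))
    picks <- corners[seq_len(min(n_roots, 8L)), , drop = FALSE]
  } else {
    mid <- pmax(1L, as.integer(round(dims / 2)))
    faces <- rbind(
      c(1L, mid[2], mid[3]), c(dims[1], mid[2], mid[3]),
      c(mid[1], 1L, mid[3]), c(mid[1], dims[2], mid[3]),
      c(mid[1], mid[2], 1L), c(mid[1], mid[2], dims[3]))
    picks <- faces[seq_len(min(n_roots, 6L)), , drop = FALSE]
  }
  if (nrow(picks) < n_roots) {
    stop("too many roots requested for preset '", preset, "'", call. = FALSE)
  }
  keys <- lattice_key(picks[, 1], picks[, 2], picks[, 3], dims)
  # odd positions arterial, even venous, so both kinds always present
  kind <- rep(c("arterial_root", "venous_root"), length.out = n_roots)
  list(keys = keys, kind = kind)
}

#' Generate a synthetic arterio-venous network
#'
#' Grows interpenetrating arterial and venous trees from boundary root nodes
#' over a cubic lattice by seeded randomized expansion, then joins them with
#' capillary segments on lattice edges whose endpoints belong to opposite
#' trees. Dead-end branches are pruned so every remaining capillary lies on an
#' arterial-root to venous-root path. Radii follow Murray's law up the trees
#' from a fixed capillary radius. The capillary count is adjusted so the
#' microvascular density (total vessel length per volume) approaches
#' `target_mvd`.
#'
#' Generation is a pure function of the arguments: identical calls give
#' byte-identical node and segment tables.
#'
#' @param domain_size Edge length of the cubic domain, um (scalar or length 3).
#' @param lattice_pitch Lattice pitch, um.
#' @param n_roots Total number of boundary roots (>= 2; alternating
#'   arterial/venous).
#' @param target_mvd Target microvascular density, mm/mm^3.
#' @param seed Integer RNG seed.
#' @param root_preset `"corners"` or `"faces"` (root placement on the domain
#'   boundary).
#' @param capillary_radius Capillary radius, um.
#' @return A [vascular_network()].
#' @export
generate_av_network <- function(domain_size = 640, lattice_pitch = 80,
                                n_roots = 2, target_mvd = 250, seed = 1,
                                root_preset = c("corners", "faces"),
                                capillary_radius = 3.5) {
  root_preset <- match.arg(root_preset)
  domain <- rep_len(domain_size, 3)
  dims <- as.integer(floor(domain / lattice_pitch)) + 1L
  if (any(dims < 3L)) {
    stop("domain must span at least 2 lattice cells per axis", call. = FALSE)
  }
  if (n_roots < 2L) stop("need at least 2 roots (1 arterial, 1 venous)",
                         call. = FALSE)
  n_lat <- prod(dims)
  vol_mm3 <- prod(domain) * 1e-9        # um^3 -> mm^3
  target_len_um <- target_mvd * vol_mm3 * 1e3   # mm -> um
  max_len_um <- 3 * n_lat * lattice_pitch       # all lattice edges, roughly
  if (target_len_um > max_len_um) {
    stop(sprintf(
      "target_mvd %.0f mm/mm^3 infeasible: needs %.0f um of vessel but the lattice holds at most ~%.0f um",
      target_mvd, target_len_um, max_len_um), call. = FALSE)
  }
  min_len_um <- (n_roots + 8) * lattice_pitch
  if (target_len_um < min_len_um) {
    stop(sprintf(
      "target_mvd %.0f mm/mm^3 infeasible: below the minimum connected network (~%.0f um of vessel)",
      target_mvd, min_len_um), call. = FALSE)
  }

  with_seed(seed, {
    roots <- root_positions(dims, n_roots, root_preset)
    # claim the entire lattice so the trees interdigitate maximally; the
    # final density is set by the capillary count and dead-end pruning
    n_claim <- n_lat
    claimed <- integer(n_lat)            # 0 none, 1 arterial, 2 venous
    tree_of <- integer(n_lat)            # root index owning the node
    parent <- integer(n_lat)             # parent lattice key within tree
    is_art <- roots$kind == "arterial_root"
    claimed[roots$keys] <- ifelse(is_art, 1L, 2L)
    tree_of[roots$keys] <- seq_along(roots$keys)
    # frontier edge pool per root: matrix cols (from, to)
    frontier <- lapply(roots$keys, function(k) {
      nb <- lattice_neighbors(k, dims)
      cbind(rep(k, length(nb)), nb)
    })
    n_claimed <- length(roots$keys)
    turn <- 0L
    stalled <- 0L
    grow_to <- function(goal) {
      stalled <<- 0L
      while (n_claimed < goal && stalled < 4 * length(frontier)) {
        turn <<- turn %% length(frontier) + 1L
        fr <- frontier[[turn]]
        grew <- FALSE
        while (nrow(fr) > 0L) {
          pick <- sample.int(nrow(fr), 1L)
          e <- fr[pick, ]
          fr <- fr[-pick, , drop = FALSE]
          if (claimed[e[2]] == 0L) {
            claimed[e[2]] <<- claimed[e[1]]
            tree_of[e[2]] <<- tree_of[e[1]]
            parent[e[2]] <<- e[1]
            nb <- lattice_neighbors(e[2], dims)
            nb <- nb[claimed[nb] == 0L]
            if (length(nb)) fr <- rbind(fr, cbind(rep(e[2], length(nb)), nb))
            n_claimed <<- n_claimed + 1L
            grew <- TRUE
            break
          }
        }
        frontier[[turn]] <<- fr
        stalled <<- if (grew) 0L else stalled + 1L
      }
    }
    grow_to(n_claim)

    # capillary candidates: lattice edges joining opposite tree types
    cand <- candidate_av_edges(claimed, dims)
    if (nrow(cand) == 0L) {
      stop("network generation failed: arterial and venous trees never meet; increase target_mvd or domain",
           call. = FALSE)
    }
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]   # seeded order

    # only root-to-capillary paths survive pruning, so the capillary count is
    # the density dial; the realised length grows monotonically with it, so
    # bisect the count against the target length
    lo <- 1L
    hi <- nrow(cand)
    build_with <- function(n_use) {
      assemble_network(claimed, tree_of, parent, dims, roots,
                       cand[seq_len(n_use), , drop = FALSE],
                       lattice_pitch, domain, capillary_radius)
    }
    n_use <- max(1L, min(hi, as.integer(round(0.4 * target_len_um /
                                                lattice_pitch))))
    build <- build_with(n_use)
    best <- build
    best_err <- abs(sum(build$segments$length) / target_len_um - 1)
    for (attempt in 1:12) {
      got_len <- sum(build$segments$length)
      ratio <- got_len / target_len_um
      err <- abs(ratio - 1)
      if (err < best_err) { best <- build; best_err <- err }
      if (err < 0.12 || (ratio < 1 && n_use == hi)) break
      if (ratio < 1) lo <- n_use else hi <- n_use
      n_next <- as.integer((lo + hi) %/% 2)
      if (n_next == n_use || hi - lo <= 1L) break
      n_use <- n_next
      build <- build_with(n_use)
    }
    build <- best
    got_mvd <- sum(build$segments$length) / (vol_mm3 * 1e3)
    if (abs(got_mvd - target_mvd) / target_mvd > 0.5) {
      stop(sprintf(
        "network generation failed: achieved MVD %.0f mm/mm^3 vs target %.0f (lattice too coarse or target infeasible)",
        got_mvd, target_mvd), call. = FALSE)
    }
    build
  })
}

candidate_av_edges <- function(claimed, dims) {
  n <- prod(dims)
  keys <- seq_len(n)
  ijk <- lattice_coords(keys, dims)
  out <- NULL
  for (d in 1:3) {
    ok <- ijk[, d] < dims[d]
    nb <- keys[ok] + c(1L, dims[1], dims[1] * dims[2])[d]
    a <- keys[ok]
    mix <- (claimed[a] == 1L & claimed[nb] == 2L) |
      (claimed[a] == 2L & claimed[nb] == 1L)
    if (any(mix)) out <- rbind(out, cbind(a[mix], nb[mix]))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  out
}

# Turn claimed lattice trees + chosen capillary edges into node/segment
# tibbles: prune dead ends, assign Murray-law radii and wall types.
assemble_network <- function(claimed, tree_of, parent, dims, roots, caps,
                             pitch, domain, capillary_radius) {
  tree_keys <- which(claimed > 0L)
  te_child <- tree_keys[parent[tree_keys] > 0L]
  edges <- rbind(
    cbind(parent[te_child], te_child, 0L),          # tree edges
    if (nrow(caps)) cbind(caps[, 1], caps[, 2], 1L) # capillary edges
  )
  colnames(edges) <- c("a", "b", "cap")

  root_set <- roots$keys
  keep <- rep(TRUE, nrow(edges))
  repeat {
    nodes_used <- c(edges[keep, 1], edges[keep, 2])
    deg <- table(nodes_used)
    dangling <- as.integer(names(deg)[deg == 1L])
    dangling <- setdiff(dangling, root_set)
    if (!length(dangling)) break
    drop <- keep & (edges[, 1] %in% dangling | edges[, 2] %in% dangling)
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("network generation failed: pruning removed all segments", call. = FALSE)
  }

  # downstream capillary-attachment counts per tree node (for Murray radii)
  cap_count <- integer(length(claimed))
  if (any(edges[, 3] == 1L)) {
    ce <- edges[edges[, 3] == 1L, , drop = FALSE]
    tab <- table(c(ce[, 1], ce[, 2]))
    cap_count[as.integer(names(tab))] <- as.integer(tab)
  }
  # accumulate counts rootward: order nodes by depth (deepest first)
  depth <- integer(length(claimed))
  alive <- sort(unique(c(edges[, 1], edges[, 2])))
  for (k in alive) {
    d <- 0L; u <- k
    while (parent[u] > 0L) { u <- parent[u]; d <- d + 1L }
    depth[k] <- d
  }
  subtree <- cap_count
  for (k in alive[order(depth[alive], decreasing = TRUE)]) {
    if (parent[k] > 0L) subtree[parent[k]] <- subtree[parent[k]] + subtree[k]
  }

  is_cap <- edges[, 3] == 1L
  radius <- numeric(nrow(edges))
  wall <- character(nrow(edges))
  radius[is_cap] <- capillary_radius
  wall[is_cap] <- "capillary"
  if (any(!is_cap)) {
    child <- edges[!is_cap, 2]
    w <- pmax(1L, subtree[child])
    arterial <- claimed[child] == 1L
    base <- ifelse(arterial, 4.5, 5.5)   # venous side runs wider
    r <- pmin(30, base * w^(1 / 3))
    radius[!is_cap] <- r
    wall[!is_cap] <- ifelse(arterial,
                            ifelse(r >= 15, "artery", "arteriole"),
                            ifelse(r >= 15, "vein", "venule"))
  }

  node_keys <- alive
  id_of <- integer(length(claimed))
  id_of[node_keys] <- seq_along(node_keys)
  ijk <- lattice_coords(node_keys, dims)
  kind <- rep("interior", length(node_keys))
  for (ri in seq_along(root_set)) {
    hit <- node_keys == root_set[ri]
    kind[hit] <- roots$kind[ri]
  }
  nodes <- tibble::tibble(
    id = seq_along(node_keys),
    x = (ijk[, 1] - 1) * pitch, y = (ijk[, 2] - 1) * pitch,
    z = (ijk[, 3] - 1) * pitch,
    kind = kind)
  segments <- tibble::tibble(
    id = seq_len(nrow(edges)),
    a = id_of[edges[, 1]], b = id_of[edges[, 2]],
    radius = radius, length = pitch,
    wall_type = wall, region = "host")
  vascular_network(nodes, segments, domain, pitch)
}

#' Validate a vascular network
#'
#' Structural report: connected components and whether each contains both an
#' arterial and a venous root, dangling (orphan) segments found by iterative
#' dead-end pruning, radius monotonicity violations (a segment wider than the
#' segment closer to its root), and boundary-node counts. Never raises.
#'
#' @param network A [vascular_network()].
#' @return A list with elements `n_components`, `components_ok`,
#'   `orphan_segments`, `radius_violations`, `n_arterial_roots`,
#'   `n_venous_roots`, `ok` (TRUE when no violations).
#' @export
validate_network <- function(network) {
  seg <- network$segments
  nod <- network$nodes
  n <- nrow(nod)
  comp <- components_of(match(seg$a, nod$id), match(seg$b, nod$id), n)
  comp_tab <- split(nod$kind, comp)
  components_ok <- vapply(comp_tab, function(k) {
    any(k == "arterial_root") && any(k == "venous_root")
  }, logical(1))

  keep <- rep(TRUE, nrow(seg))
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  root_idx <- which(nod$kind != "interior")
  repeat {
    deg <- tabulate(c(ia[keep], ib[keep]), nbins = n)
    dangle <- setdiff(which(deg == 1L), root_idx)
    drop <- keep & (ia %in% dangle | ib %in% dangle)
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  orphan <- seg$id[!keep]

  viol <- integer(0)
  # monotonicity: for each node, the widest incident segment should not be a
  # capillary while an artery hangs off a capillary-fed node; practical check:
  # capillary wider than any incident non-capillary segment
  for (i in which(seg$wall_type == "capillary")) {
    inc <- seg$radius[(seg$a %in% c(seg$a[i], seg$b[i]) |
                         seg$b %in% c(seg$a[i], seg$b[i])) &
                        seg$wall_type != "capillary"]
    if (length(inc) && seg$radius[i] > max(inc)) viol <- c(viol, seg$id[i])
  }

  list(n_components = length(comp_tab),
       components_ok = unname(components_ok),
       orphan_segments = orphan,
       radius_violations = viol,
       n_arterial_roots = sum(nod$kind == "arterial_root"),
       n_venous_roots = sum(nod$kind == "venous_root"),
       ok = all(components_ok) && !length(orphan) && !length(viol))
}

# remove segments (and then nodes) that are no longer in a component holding
# both an arterial and a venous root (regressed vessel debris)
drop_unrooted <- function(network) {
  nod <- network$nodes
  seg <- network$segments
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  comp <- components_of(ia, ib, nrow(nod))
  ok_comp <- intersect(unique(comp[nod$kind == "arterial_root"]),
                       unique(comp[nod$kind == "venous_root"]))
  keep_seg <- comp[ia] %in% ok_comp
  seg <- seg[keep_seg, , drop = FALSE]
  keep_nod <- nod$id %in% c(seg$a, seg$b) |
    (nod$kind != "interior" & comp %in% ok_comp)
  vascular_network(nod[keep_nod, , drop = FALSE], seg, network$domain,
                   network$lattice_pitch)
}

# union-find over node row indices (ia, ib are 1..n_nodes)
components_of <- function(ia, ib, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ia)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n_nodes), find, integer(1))
  match(roots, unique(roots))
}

segment_midpoints <- function(network) {
  nod <- network$nodes
  seg <- network$segments
  ia <- match(seg$a, nod$id); ib <- match(seg$b, nod$id)
  cbind(x = (nod$x[ia] + nod$x[ib]) / 2,
        y = (nod$y[ia] + nod$y[ib]) / 2,
        z = (nod$z[ia] + nod$z[ib]) / 2)
}

#' Apply a parametric tumor phantom to a network
#'
#' Emulates the vascular and tissue signature of a grown vascularized tumor
#' without running a growth simulation: segments inside a tumor sphere are
#' relabeled `region = "tumor"` and dilated; extra capillary connections are
#' sprouted between nearby tumor nodes (elevated tumor MVD); segments inside
#' the necrotic core are randomly pruned; and a tissue phase grid is built
#' with a necrotic core (`phi_necrotic = 1`), a viable tumor shell
#' (`phi_tumor = 1`) and normal host tissue outside. Maximum consumption and
#' Michaelis maps are assembled per voxel as
#' `v_m = phi_normal * v_m_host + phi_tumor * v_m_tumor` (necrotic tissue does
#' not consume oxygen) and analogously for `k_m`.
#'
#' @param network A [vascular_network()].
#' @param center Tumor center, um (length 3; default domain center).
#' @param radius Tumor radius, um.
#' @param necrotic_radius Necrotic core radius, um (< `radius`).
#' @param dilation_factor Multiplier on tumor segment radii (>= 1 emulates
#'   tumor vessel dilation).
#' @param prune_fraction Fraction of necrotic-core segments removed.
#' @param sprout_fraction Fraction of available unconnected lattice-adjacent
#'   node pairs inside the viable shell to connect as new tumor capillaries.
#' @param seed Integer RNG seed for pruning/sprouting.
#' @param grid_spacing Tissue voxel spacing, um.
#' @param params [transport_params()] supplying host/tumor consumption.
#' @return A list with elements `network` (modified) and `grid`
#'   (a [tissue_grid()]).
#' @export
apply_tumor_phantom <- function(network, center = NULL, radius,
                                necrotic_radius, dilation_factor = 1.3,
                                prune_fraction = 0.3, sprout_fraction = 0.25,
                                seed = 1, grid_spacing = 30,
                                params = transport_params("mouse")) {
  stopifnot(necrotic_radius < radius)
  if (is.null(center)) center <- network$domain / 2
  mid <- segment_midpoints(network)
  d_mid <- sqrt((mid[, 1] - center[1])^2 + (mid[, 2] - center[2])^2 +
                  (mid[, 3] - center[3])^2)
  seg <- network$segments
  in_tumor <- d_mid < radius
  in_core <- d_mid < necrotic_radius

  out <- with_seed(seed, {
    result <- NULL
    for (attempt in 1:5) {
      if (!is.null(result)) break
      keep <- rep(TRUE, nrow(seg))
      core_ids <- which(in_core)
      if (length(core_ids) && prune_fraction > 0) {
        n_drop <- round(prune_fraction * length(core_ids))
        if (n_drop > 0) keep[sample(core_ids, n_drop)] <- FALSE
      }
      seg2 <- seg[keep, , drop = FALSE]
      seg2$region[in_tumor[keep]] <- "tumor"
      seg2$radius[in_tumor[keep]] <- seg2$radius[in_tumor[keep]] * dilation_factor

      # sprout new tumor capillaries between shell nodes that are lattice
      # neighbors but not yet connected
      nod <- network$nodes
      d_nod <- sqrt((nod$x - center[1])^2 + (nod$y - center[2])^2 +
                      (nod$z - center[3])^2)
      shell_nodes <- nod$id[d_nod < radius & d_nod >= necrotic_radius]
      pitch <- network$lattice_pitch
      if (length(shell_nodes) > 1 && sprout_fraction > 0 && is.finite(pitch)) {
        idx <- match(shell_nodes, nod$id)
        pos <- cbind(nod$x[idx], nod$y[idx], nod$z[idx])
        pairs <- which(as.matrix(stats::dist(pos)) < pitch * 1.01 &
                         upper.tri(matrix(0, length(idx), length(idx))),
                       arr.ind = TRUE)
        if (nrow(pairs)) {
          pa <- shell_nodes[pairs[, 1]]; pb <- shell_nodes[pairs[, 2]]
          have <- paste(pmin(seg2$a, seg2$b), pmax(seg2$a, seg2$b))
          cand <- which(!(paste(pmin(pa, pb), pmax(pa, pb)) %in% have))
          n_new <- round(sprout_fraction * length(cand))
          if (n_new > 0) {
            pick <- sample(cand, n_new)
            dlen <- sqrt(rowSums((pos[pairs[pick, 1], , drop = FALSE] -
                                    pos[pairs[pick, 2], , drop = FALSE])^2))
            seg2 <- dplyr::bind_rows(seg2, tibble::tibble(
              id = max(seg$id) + seq_len(n_new),
              a = pa[pick], b = pb[pick],
              radius = 3.5 * dilation_factor, length = dlen,
              wall_type = "capillary", region = "tumor"))
          }
        }
      }
      net2 <- vascular_network(nod, seg2, network$domain, network$lattice_pitch)
      rep2 <- validate_network(net2)
      if (any(rep2$components_ok)) result <- net2
    }
    if (is.null(result)) {
      stop("tumor phantom pruning disconnected all root-to-root paths after 5 attempts; lower prune_fraction",
           call. = FALSE)
    }
    drop_unrooted(result)
  })

  grid <- phantom_tissue_grid(network$domain, grid_spacing, center, radius,
                              necrotic_radius, params)
  list(network = out, grid = grid)
}

phantom_tissue_grid <- function(domain, spacing, center, radius,
                                necrotic_radius, params) {
  shape <- pmax(2L, as.integer(round(domain / spacing)))
  ax <- lapply(1:3, function(d) ((seq_len(shape[d])) - 0.5) * spacing)
  dist <- sqrt(outer(outer((ax[[1]] - center[1])^2,
                           (ax[[2]] - center[2])^2, "+"),
                     (ax[[3]] - center[3])^2, "+"))
  phi_necrotic <- (dist < necrotic_radius) * 1
  phi_tumor <- (dist >= necrotic_radius & dist < radius) * 1
  phi_normal <- 1 - phi_necrotic - phi_tumor
  tissue_grid(spacing, shape,
              phi_normal = phi_normal, phi_tumor = phi_tumor,
              phi_necrotic = phi_necrotic, params = params)
}
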