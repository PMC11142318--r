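# Molecular-graph identity and symmetry, built on igraph.
#
# Vertex colors encode (element, formal charge); edge colors encode bond
# order. Canonicalization uses BLISS, which only understands vertex colors,
# so bond orders are folded in by subdividing every edge with a dummy vertex
# colored by its order before computing the canonical permutation.

lig_igraph <- function(ligand) {
  n <- nrow(ligand$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ligand$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(ligand$bonds$i, ligand$bonds$j))
  }
  g
}

atom_color_codes <- function(...) {
  # dense integer codes shared across the molecules passed in
  labs <- unlist(lapply(list(...), function(l)
    paste(l$atoms$element, l$atoms$formal_charge, sep = "/")))
  codes <- sort(unique(labs))
  lapply(list(...), function(l)
    match(paste(l$atoms$element, l$atoms$formal_charge, sep = "/"), codes))
}

bond_color <- function(order) match(as.character(order),
                                    c("1", "1.5", "2", "3"))

#' Canonical graph key of a ligand
#'
#' A string identifying the heavy-atom molecular graph — elements, formal
#' charges and bond orders, ignoring stereochemistry and 3D coordinates.
#' Invariant under any re-ordering of atoms in the input.
#'
#' @param ligand a `pv_ligand`.
#' @return A single character key.
#' @export
ligand_key <- function(ligand) {
  n <- nrow(ligand$atoms)
  m <- nrow(ligand$bonds)
  labs <- paste(ligand$atoms$element, ligand$atoms$formal_charge, sep = "/")
  if (m == 0) {
    return(paste0("atoms{", paste(sort(labs), collapse = ","), "}"))
  }
  # subdivide: vertices 1..n are atoms, n+1..n+m are bond dummies
  edges <- integer(0)
  for (b in seq_len(m)) {
    d <- n + b
    edges <- c(edges, ligand$bonds$i[b], d, d, ligand$bonds$j[b])
  }
  g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  atom_codes <- match(labs, sort(unique(labs)))
  bond_codes <- bond_color(ligand$bonds$order)
  colors <- c(atom_codes, max(atom_codes) + bond_codes)
  cp <- igraph::canonical_permutation(g, colors = as.integer(colors))
  gc <- igraph::permute(g, cp$labeling)
  lab_full <- c(labs, paste0("~", ligand$bonds$order))
  canon_labels <- character(n + m)
  canon_labels[cp$labeling] <- lab_full
  el <- igraph::as_edgelist(gc)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("v{", paste(canon_labels, collapse = ","), "}e{",
         paste(el[, 1], el[, 2], sep = "-", collapse = ","), "}")
}

#' Do two ligands share the same molecular graph?
#'
#' Compares element/charge/bond-order graphs up to isomorphism; stereo and
#' coordinates are ignored.
#'
#' @param a,b `pv_ligand` objects.
#' @return Logical scalar.
#' @export
same_graph <- function(a, b) {
  if (nrow(a$atoms) != nrow(b$atoms) || nrow(a$bonds) != nrow(b$bonds))
    return(FALSE)
  identical(ligand_key(a), ligand_key(b))
}

#' Graph isomorphisms from one ligand onto another
#'
#' Enumerates all mappings of `a`'s atoms onto `b`'s atoms preserving
#' elements, formal charges and bond orders (VF2). With `a = b` these are
#' the graph automorphisms, i.e. the molecular symmetry group used for
#' symmetry-corrected RMSD.
#'
#' @param a,b `pv_ligand` objects with matching graphs.
#' @param cap maximum number of mappings to enumerate; beyond the cap only
#'   the identity-like first match is returned, with attribute
#'   `capped = TRUE`.
#' @return List of integer vectors `perm` such that atom `i` of `a`
#'   corresponds to atom `perm[i]` of `b`.
#' @export
ligand_isomorphisms <- function(a, b = a, cap = 1e4) {
  cols <- atom_color_codes(a, b)
  ga <- lig_igraph(a); gb <- lig_igraph(b)
  ea <- bond_color(a$bonds$order); eb <- bond_color(b$bonds$order)
  n_iso <- igraph::count_isomorphisms(
    ga, gb, method = "vf2",
    vertex.color1 = as.integer(cols[[1]]), vertex.color2 = as.integer(cols[[2]]),
    edge.color1 = as.integer(ea), edge.color2 = as.integer(eb))
  if (n_iso == 0) return(list())
  if (n_iso > cap) {
    # symmetry group too large to enumerate; fall back to the single mapping
    # obtained by composing the two canonical labelings
    la <- canonical_atom_labeling(a); lb <- canonical_atom_labeling(b)
    maps <- list(match(la, lb))
    attr(maps, "capped") <- TRUE
    return(maps)
  }
  iso <- igraph::isomorphisms(
    ga, gb, method = "vf2",
    vertex.color1 = as.integer(cols[[1]]), vertex.color2 = as.integer(cols[[2]]),
    edge.color1 = as.integer(ea), edge.color2 = as.integer(eb))
  # igraph encodes each mapping from the second graph onto the first;
  # invert so perm[i] is the atom of `b` matching atom i of `a`
  maps <- lapply(iso, function(v) {
    v <- as.integer(v)
    inv <- integer(length(v)); inv[v] <- seq_along(v)
    inv
  })
  attr(maps, "capped") <- FALSE
  maps
}

# canonical position of each real atom within the subdivided colored graph
canonical_atom_labeling <- function(ligand) {
  n <- nrow(ligand$atoms); m <- nrow(ligand$bonds)
  labs <- paste(ligand$atoms$element, ligand$atoms$formal_charge, sep = "/")
  if (m == 0) return(order(order(labs)))
  edges <- integer(0)
  for (b in seq_len(m)) {
    d <- n + b
    edges <- c(edges, ligand$bonds$i[b], d, d, ligand$bonds$j[b])
  }
  g <- igraph::add_edges(igraph::make_empty_graph(n = n + m,
                                                  directed = FALSE), edges)
  atom_codes <- match(labs, sort(unique(labs)))
  colors <- c(atom_codes, max(atom_codes) + bond_color(ligand$bonds$order))
  cp <- igraph::canonical_permutation(g, colors = as.integer(colors))
  cp$labeling[seq_len(n)]
}

# degree-summed bond order per atom (aromatic counts 1.5); used by valence
# sanitization and donor/acceptor heuristics
atom_bond_order_sum <- function(ligand) {
  s <- numeric(nrow(ligand$atoms))
  if (nrow(ligand$bonds) > 0) {
    for (b in seq_len(nrow(ligand$bonds))) {
      s[ligand$bonds$i[b]] <- s[ligand$bonds$i[b]] + ligand$bonds$order[b]
      s[ligand$bonds$j[b]] <- s[ligand$bonds$j[b]] + ligand$bonds$order[b]
    }
  }
  s
}

atom_degree <- function(ligand) {
  d <- integer(nrow(ligand$atoms))
  if (nrow(ligand$bonds) > 0) {
    t_ <- table(factor(c(ligand$bonds$i, ligand$bonds$j),
                       levels = seq_len(nrow(ligand$atoms))))
    d <- as.integer(t_)
  }
  d
}

atom_neighbors <- function(ligand, i) {
  c(ligand$bonds$j[ligand$bonds$i == i], ligand$bonds$i[ligand$bonds$j == i])
}

# smallest rings (5-7 atoms) containing only aromatic (order 1.5) bonds:
# for each aromatic edge, the shortest alternative path between its
# endpoints closes the smallest ring through that edge
aromatic_rings <- function(ligand) {
  ar <- ligand$bonds[ligand$bonds$order == 1.5, , drop = FALSE]
  if (nrow(ar) < 3) return(list())
  g <- igraph::graph_from_edgelist(cbind(ar$i, ar$j), directed = FALSE)
  rings <- list()
  for (e in seq_len(nrow(ar))) {
    h <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(ar$i[e], ar$j[e])))
    path <- suppressWarnings(igraph::shortest_paths(
      h, from = ar$i[e], to = ar$j[e])$vpath[[1]])
    ids <- as.integer(path)
    if (length(ids) >= 5 && length(ids) <= 7)
      rings[[length(rings) + 1]] <- sort(ids)
  }
  unique(rings)
}
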