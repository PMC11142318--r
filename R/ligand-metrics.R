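#' Heavy-atom ligand RMSD, optionally symmetry-corrected
#'
#' Computes `sqrt(mean(||x_hat_i - x_i||^2))` over heavy atoms in the frame
#' the coordinates already live in — no re-superposition is performed, so in
#' the docking convention the pose must first be placed in the
#' pocket-aligned frame. With `symmetry = TRUE` the minimum over all graph
#' automorphisms (element/charge/bond-order preserving atom permutations)
#' is returned.
#'
#' @param pred,ref `pv_ligand` objects with identical molecular graphs.
#' @param symmetry correct for molecular graph symmetry (default `TRUE`)?
#' @param cap automorphism enumeration cap, see [ligand_isomorphisms()].
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(pred, ref, symmetry = TRUE, cap = 1e4) {
  if (nrow(pred$atoms) != nrow(ref$atoms))
    stop("atom-count mismatch: ", nrow(pred$atoms), " vs ",
         nrow(ref$atoms), call. = FALSE)
  P <- ligand_coords(pred); R <- ligand_coords(ref)
  if (!symmetry) {
    return(sqrt(mean(rowSums((P - R)^2))))
  }
  maps <- ligand_isomorphisms(pred, ref, cap = cap)
  if (length(maps) == 0)
    stop("molecular graphs do not match; cannot compute symmetry-corrected ",
         "RMSD", call. = FALSE)
  # mapping: atom i of pred corresponds to atom perm[i] of ref
  best <- Inf
  for (perm in maps) {
    v <- sqrt(mean(rowSums((P - R[perm, , drop = FALSE])^2)))
    if (v < best) best <- v
  }
  best
}

#' Centroid distance between two ligand poses (cRMSD)
#'
#' Euclidean distance between unweighted heavy-atom centroids; the
#' benchmark convention calls this "cRMSD" although it is a plain distance.
#' The molecular graphs need not match.
#'
#' @param pred,ref `pv_ligand` objects in a common frame.
#' @return Distance in Angstrom.
#' @export
centroid_rmsd <- function(pred, ref) {
  if (nrow(pred$atoms) == 0 || nrow(ref$atoms) == 0)
    stop("empty molecule", call. = FALSE)
  vnorm(ligand_centroid(pred) - ligand_centroid(ref))
}

#' Optimal assignment of predicted fragments to reference fragments
#'
#' Within each graph-identity class (fragments sharing a canonical graph
#' key), finds the one-to-one assignment minimizing the summed
#' symmetry-aware RMSD. Classes with up to `exhaustive_max` fragments on the
#' smaller side are solved by exhaustive permutation search; larger classes
#' use the Hungarian algorithm on the RMSD cost matrix (equivalent optimum,
#' via `clue::solve_LSAP`).
#'
#' @param pred_ligands,ref_ligands lists of `pv_ligand` in a common frame.
#' @param symmetry passed to [heavy_atom_rmsd()].
#' @param exhaustive_max class size up to which permutations are enumerated
#'   directly (default 6).
#' @return A tibble with one row per matched pair: `pred_index`,
#'   `ref_index`, `rmsd`; attribute `unmatched_pred` / `unmatched_ref` hold
#'   the indices left unassigned.
#' @export
assign_fragments <- function(pred_ligands, ref_ligands, symmetry = TRUE,
                             exhaustive_max = 6) {
  if (inherits(pred_ligands, "pv_ligand")) pred_ligands <- list(pred_ligands)
  if (inherits(ref_ligands, "pv_ligand")) ref_ligands <- list(ref_ligands)
  pred_keys <- vapply(pred_ligands, ligand_key, "")
  ref_keys <- vapply(ref_ligands, ligand_key, "")
  rows <- list()
  for (key in unique(ref_keys)) {
    pi_ <- which(pred_keys == key); ri <- which(ref_keys == key)
    if (length(pi_) == 0) next
    cost <- matrix(0, length(pi_), length(ri))
    for (a in seq_along(pi_)) for (b in seq_along(ri)) {
      cost[a, b] <- heavy_atom_rmsd(pred_ligands[[pi_[a]]],
                                    ref_ligands[[ri[b]]],
                                    symmetry = symmetry)
    }
    sel <- min_cost_assignment(cost, exhaustive_max)
    rows[[length(rows) + 1]] <- tibble::tibble(
      pred_index = pi_[sel$rows], ref_index = ri[sel$cols],
      rmsd = cost[cbind(sel$rows, sel$cols)])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble::tibble(pred_index = integer(),
                                            ref_index = integer(),
                                            rmsd = numeric())
  attr(out, "unmatched_pred") <- setdiff(seq_along(pred_ligands),
                                         out$pred_index)
  attr(out, "unmatched_ref") <- setdiff(seq_along(ref_ligands),
                                        out$ref_index)
  out
}

# minimum-cost one-to-one assignment covering the smaller dimension
min_cost_assignment <- function(cost, exhaustive_max = 6) {
  nr <- nrow(cost); nc <- ncol(cost)
  transposed <- FALSE
  if (nr > nc) { cost <- t(cost); nr <- nrow(cost); nc <- ncol(cost)
                 transposed <- TRUE }
  if (nr <= exhaustive_max && nc <= exhaustive_max) {
    perms <- permutations_of(nc)
    best <- NULL; best_cost <- Inf
    for (p in perms) {
      sel <- p[seq_len(nr)]
      tc <- sum(cost[cbind(seq_len(nr), sel)])
      if (tc < best_cost) { best_cost <- tc; best <- sel }
    }
    res <- list(rows = seq_len(nr), cols = best)
  } else {
    sol <- clue::solve_LSAP(cost)
    res <- list(rows = seq_len(nr), cols = as.integer(sol))
  }
  if (transposed) list(rows = res$cols, cols = res$rows) else res
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1)
  out <- list()
  for (p in sub) for (k in seq_len(n)) {
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  }
  out
}
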