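#' Define the binding pocket of a reference complex
#'
#' The pocket is the set of protein residues having at least one heavy atom
#' within `cutoff` of at least one ligand heavy atom, taken over all
#' ligands and cofactors.
#'
#' @param ref_protein a `pv_protein` (reference frame).
#' @param ref_ligands a `pv_ligand` or list of them, same frame.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return A tibble of pocket members (`chain_id`, `residue_index`) with
#'   attribute `cutoff`; zero rows is a valid (flagged) result.
#' @export
define_pocket <- function(ref_protein, ref_ligands, cutoff = 10) {
  stopifnot(inherits(ref_protein, "pv_protein"), cutoff >= 0)
  if (inherits(ref_ligands, "pv_ligand")) ref_ligands <- list(ref_ligands)
  lig_xyz <- do.call(rbind, lapply(ref_ligands, ligand_coords))
  pxyz <- protein_coords(ref_protein)
  within <- rep(FALSE, nrow(pxyz))
  if (cutoff > 0 && nrow(lig_xyz) > 0) {
    for (k in seq_len(nrow(lig_xyz))) {
      d2 <- (pxyz[, 1] - lig_xyz[k, 1])^2 + (pxyz[, 2] - lig_xyz[k, 2])^2 +
        (pxyz[, 3] - lig_xyz[k, 3])^2
      within <- within | d2 <= cutoff^2
    }
  }
  members <- as_plain_tibble(ref_protein)[within, ] |>
    dplyr::distinct(.data$chain_id, .data$residue_index) |>
    dplyr::arrange(.data$chain_id, .data$residue_index)
  attr(members, "cutoff") <- cutoff
  class(members) <- c("pv_pocket", class(members))
  members
}

#' Optimal chain mapping between predicted and reference structures
#'
#' Among sequence-compatible bijections from predicted chains onto reference
#' chains, returns the one minimizing the pocket C-alpha fit RMSD.
#' Enumeration is exhaustive for up to 6 interchangeable chains per sequence
#' class and greedy beyond.
#'
#' @param pred_protein,ref_protein `pv_protein` structures.
#' @param ref_pocket pocket tibble from [define_pocket()]; when `NULL`, all
#'   residues are used for the fit.
#' @param min_identity minimum sequence identity for two chains to be
#'   considered compatible (default 0.95).
#' @return A tibble with columns `pred_chain`, `ref_chain`, plus attribute
#'   `score` (the pocket fit RMSD achieved).
#' @export
map_chains <- function(pred_protein, ref_protein, ref_pocket = NULL,
                       min_identity = 0.95) {
  pred_seqs <- protein_sequences(pred_protein)
  ref_seqs <- protein_sequences(ref_protein)
  compat <- matrix(FALSE, length(pred_seqs), length(ref_seqs),
                   dimnames = list(names(pred_seqs), names(ref_seqs)))
  for (i in seq_along(pred_seqs)) for (j in seq_along(ref_seqs)) {
    compat[i, j] <- seq_identity(pred_seqs[i], ref_seqs[j]) >= min_identity
  }
  ref_chains <- names(ref_seqs)
  candidates <- enumerate_chain_bijections(compat)
  if (length(candidates) == 0)
    rlang::abort("no sequence-compatible chain bijection exists",
                 class = "poseval_chain_mapping_error")
  best <- NULL; best_rmsd <- Inf
  for (cand in candidates) {
    mapping <- tibble::tibble(pred_chain = names(cand),
                              ref_chain = unname(cand))
    rmsd <- tryCatch({
      pairs <- residue_ca_pairs(pred_protein, ref_protein, mapping,
                                ref_pocket)
      if (nrow(pairs) < 3) Inf else
        kabsch(as.matrix(pairs[, c("x_pred", "y_pred", "z_pred")]),
               as.matrix(pairs[, c("x_ref", "y_ref", "z_ref")]))$fit_rmsd
    }, error = function(e) Inf)
    if (rmsd < best_rmsd) { best <- mapping; best_rmsd <- rmsd }
  }
  if (is.null(best)) best <- tibble::tibble(
    pred_chain = names(candidates[[1]]),
    ref_chain = unname(candidates[[1]]))
  attr(best, "score") <- best_rmsd
  best
}

# all bijections consistent with the compatibility matrix; exhaustive while
# the running product of choices stays small, greedy (first-fit) afterwards
enumerate_chain_bijections <- function(compat, limit = 720) {
  preds <- rownames(compat); refs <- colnames(compat)
  n <- length(preds)
  if (n > length(refs)) return(list())
  results <- list(character(0))
  for (i in seq_len(n)) {
    nxt <- list()
    for (partial in results) {
      free <- setdiff(refs[compat[i, ]], partial)
      for (r in free) nxt[[length(nxt) + 1]] <- c(partial, r)
      if (length(nxt) > limit) break
    }
    if (length(nxt) == 0) return(list())
    if (length(nxt) > limit) nxt <- nxt[seq_len(limit)]
    results <- nxt
  }
  lapply(results, function(r) setNames(r, preds))
}

seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(al, type = "PID1") / 100
}

# C-alpha pairs between corresponding residues under a chain mapping;
# correspondence comes from global sequence alignment with affine gaps, and
# only aligned positions with identical residue types form pairs
residue_ca_pairs <- function(pred_protein, ref_protein, chain_mapping,
                             ref_pocket = NULL) {
  out <- list()
  pred_ca <- as_plain_tibble(pred_protein) |>
    dplyr::filter(.data$atom_name == "CA")
  ref_ca <- as_plain_tibble(ref_protein) |>
    dplyr::filter(.data$atom_name == "CA")
  for (r in seq_len(nrow(chain_mapping))) {
    pc <- chain_mapping$pred_chain[r]; rc <- chain_mapping$ref_chain[r]
    ps <- protein_sequences(pred_protein)[[pc]]
    rs <- protein_sequences(ref_protein)[[rc]]
    corr <- aligned_positions(ps, rs)
    pca <- pred_ca[pred_ca$chain_id == pc, ]
    rca <- ref_ca[ref_ca$chain_id == rc, ]
    pi_ <- match(corr$pos_a, pca$residue_index)
    ri <- match(corr$pos_b, rca$residue_index)
    ok <- !is.na(pi_) & !is.na(ri)
    if (!any(ok)) next
    out[[length(out) + 1]] <- tibble::tibble(
      pred_chain = pc, ref_chain = rc,
      pred_residue = corr$pos_a[ok], ref_residue = corr$pos_b[ok],
      x_pred = pca$x[pi_[ok]], y_pred = pca$y[pi_[ok]],
      z_pred = pca$z[pi_[ok]],
      x_ref = rca$x[ri[ok]], y_ref = rca$y[ri[ok]], z_ref = rca$z[ri[ok]])
  }
  pairs <- dplyr::bind_rows(out)
  if (!is.null(ref_pocket) && nrow(pairs) > 0) {
    key <- paste(pairs$ref_chain, pairs$ref_residue)
    pocket_key <- paste(ref_pocket$chain_id, ref_pocket$residue_index)
    pairs <- pairs[key %in% pocket_key, , drop = FALSE]
  }
  pairs
}

aligned_positions <- function(seq_a, seq_b) {
  if (identical(seq_a, seq_b)) {
    n <- nchar(seq_a)
    return(tibble::tibble(pos_a = seq_len(n), pos_b = seq_len(n)))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-" & pa == sa
  tibble::tibble(pos_a = ia[keep], pos_b = ib[keep])
}

#' Pocket-focused superposition of a mobile structure onto a reference
#'
#' Kabsch fit restricted to the C-alpha atoms of the pocket residues; the
#' resulting transform is applied to the whole mobile structure (callers
#' scoring ligands apply it to those too).
#'
#' @param mobile_protein,ref_protein `pv_protein` structures.
#' @param pocket pocket tibble from [define_pocket()] (reference residues).
#' @param chain_mapping tibble from [map_chains()]; identity mapping by
#'   default when chain sets coincide.
#' @param trim_cycles optional iterative outlier trimming: number of cycles
#'   in which the worst 10 percent of pairs are dropped and the fit redone
#'   (default 0, plain Kabsch).
#' @param atoms `"calpha"` (default) or `"heavy"`: which pocket atoms enter
#'   the fit.
#' @return List with `protein` (transformed mobile), `transform`, and
#'   `fit_rmsd` (Angstrom, over the pairs used in the final cycle).
#' @export
align_to_pocket <- function(mobile_protein, ref_protein, pocket,
                            chain_mapping = NULL, trim_cycles = 0,
                            atoms = c("calpha", "heavy")) {
  atoms <- match.arg(atoms)
  if (is.null(chain_mapping)) {
    shared <- intersect(unique(mobile_protein$chain_id),
                        unique(ref_protein$chain_id))
    chain_mapping <- tibble::tibble(pred_chain = shared, ref_chain = shared)
  }
  pairs <- residue_ca_pairs(mobile_protein, ref_protein, chain_mapping,
                            pocket)
  pocket_keys <- paste(pocket$chain_id, pocket$residue_index)
  seen <- paste(pairs$ref_chain, pairs$ref_residue)
  missing <- setdiff(pocket_keys, seen)
  if (length(missing) > 0)
    stop_degenerate(paste0("pocket residues unresolved in mobile structure: ",
                           paste(missing, collapse = ", ")))
  if (atoms == "heavy") {
    pairs <- heavy_atom_pairs(mobile_protein, ref_protein, pairs)
  }
  if (nrow(pairs) < 3)
    stop_degenerate("fewer than 3 resolvable pocket atom pairs")
  A <- as.matrix(pairs[, c("x_pred", "y_pred", "z_pred")])
  B <- as.matrix(pairs[, c("x_ref", "y_ref", "z_ref")])
  fit <- kabsch(A, B)
  cycles <- 0
  while (trim_cycles > 0 && cycles < trim_cycles && nrow(A) > 4) {
    resid <- rowSums((apply_transform(A, fit$transform) - B)^2)
    keep <- resid <= stats::quantile(resid, 0.9)
    if (all(keep)) break
    A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
    fit <- kabsch(A, B)
    cycles <- cycles + 1
  }
  list(protein = apply_transform(mobile_protein, fit$transform),
       transform = fit$transform, fit_rmsd = fit$fit_rmsd)
}

# expand residue-level CA pairs to all shared heavy atoms (matched by name)
heavy_atom_pairs <- function(mobile_protein, ref_protein, ca_pairs) {
  mp <- as_plain_tibble(mobile_protein); rp <- as_plain_tibble(ref_protein)
  out <- list()
  for (r in seq_len(nrow(ca_pairs))) {
    ma <- mp[mp$chain_id == ca_pairs$pred_chain[r] &
               mp$residue_index == ca_pairs$pred_residue[r], ]
    ra <- rp[rp$chain_id == ca_pairs$ref_chain[r] &
               rp$residue_index == ca_pairs$ref_residue[r], ]
    shared <- intersect(ma$atom_name, ra$atom_name)
    mi <- match(shared, ma$atom_name); ri <- match(shared, ra$atom_name)
    out[[r]] <- tibble::tibble(
      x_pred = ma$x[mi], y_pred = ma$y[mi], z_pred = ma$z[mi],
      x_ref = ra$x[ri], y_ref = ra$y[ri], z_ref = ra$z[ri])
  }
  dplyr::bind_rows(out)
}
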