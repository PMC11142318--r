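# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# all element/charge/bond-preserving atom permutations by exhaustive search
# (feasible for <= 8 heavy atoms)
oracle_automorphisms <- function(lig) {
  n <- nrow(lig$atoms)
  stopifnot(n <= 8)
  bond_key <- function(i, j, ord) paste(min(i, j), max(i, j), ord)
  ref_bonds <- sort(mapply(bond_key, lig$bonds$i, lig$bonds$j,
                           lig$bonds$order))
  labels <- paste(lig$atoms$element, lig$atoms$formal_charge)
  perms <- gtools_perms(n)
  keep <- list()
  for (r in seq_len(nrow(perms))) {
    p <- unname(perms[r, ])
    if (!all(labels == labels[p])) next
    mapped <- sort(mapply(bond_key, p[lig$bonds$i], p[lig$bonds$j],
                          lig$bonds$order))
    if (identical(mapped, ref_bonds)) keep[[length(keep) + 1]] <- p
  }
  keep
}

gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- unname(cbind(k, sub + (sub >= k)))
    out <- rbind(out, block)
  }
  unname(out)
}

# O(n^2) literal transcription of the four-threshold distance test
oracle_lddt <- function(pred, ref, residue_id, ro = 15,
                        thresholds = c(0.5, 1, 2, 4)) {
  n <- nrow(ref)
  scores <- c()
  for (i in seq_len(n)) {
    hits <- 0; tot <- 0
    for (j in seq_len(n)) {
      if (i == j || residue_id[i] == residue_id[j]) next
      dref <- sqrt(sum((ref[i, ] - ref[j, ])^2))
      if (dref > ro) next
      dpred <- sqrt(sum((pred[i, ] - pred[j, ])^2))
      for (dk in thresholds) {
        tot <- tot + 1
        if (abs(dpred - dref) < dk) hits <- hits + 1
      }
    }
    if (tot > 0) scores <- c(scores, hits / tot)
  }
  mean(scores)
}

# all-pairs pocket membership
oracle_pocket <- function(protein, ligands, cutoff) {
  if (inherits(ligands, "pv_ligand")) ligands <- list(ligands)
  lxyz <- do.call(rbind, lapply(ligands, function(l)
    as.matrix(l$atoms[, c("x", "y", "z")])))
  keys <- character(0)
  for (r in seq_len(nrow(protein))) {
    for (k in seq_len(nrow(lxyz))) {
      d <- sqrt(sum((c(protein$x[r], protein$y[r], protein$z[r]) -
                       lxyz[k, ])^2))
      if (d <= cutoff) {
        keys <- c(keys, paste(protein$chain_id[r], protein$residue_index[r]))
        break
      }
    }
  }
  sort(unique(keys))
}

# greedy northwest-corner transport on the 1-D line: provably optimal for
# sorted unit-spaced supports, and algorithmically independent of the CDF
# difference formula
oracle_transport_1d <- function(u, v) {
  u <- u / sum(u); v <- v / sum(v)
  i <- 1; j <- 1; cost <- 0
  ui <- u; vj <- v
  while (i <= length(u) && j <= length(v)) {
    m <- min(ui[i], vj[j])
    cost <- cost + m * abs(i - j)
    ui[i] <- ui[i] - m; vj[j] <- vj[j] - m
    advanced <- FALSE
    if (ui[i] <= 1e-15) { i <- i + 1; advanced <- TRUE }
    if (j <= length(v) && vj[j] <= 1e-15) { j <- j + 1; advanced <- TRUE }
    if (!advanced) stop("transport oracle stalled")
  }
  cost
}

# all-pairs clash count between two coordinate/element sets
oracle_clashes <- function(xyz_a, el_a, xyz_b, el_b, factor = 0.75) {
  vdw <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, Mg = 1.73,
           P = 1.8, Cl = 1.75)
  rad <- function(e) { r <- vdw[e]; ifelse(is.na(r), 2.0, r) }
  cnt <- 0
  for (a in seq_len(nrow(xyz_a))) for (b in seq_len(nrow(xyz_b))) {
    d <- sqrt(sum((xyz_a[a, ] - xyz_b[b, ])^2))
    if (d < factor * (rad(el_a[a]) + rad(el_b[b]))) cnt <- cnt + 1
  }
  cnt
}

random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M); Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  rigid_transform(Q, rnorm(3, sd = 10))
}

# a small two-chain protein fixture with a ligand nestled against chain A
two_chain_fixture <- function(seed = 7) {
  make_toy_complex(seed, templates = "benzene", n_residues = 8,
                   n_chains = 2)
}
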