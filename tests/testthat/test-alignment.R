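test_that("pocket membership matches the all-pairs oracle and the 10 A rule", {
  cx <- make_toy_complex(seed = 4, templates = "acetate", n_residues = 10)
  for (cutoff in c(5, 7, 10)) {
    pocket <- define_pocket(cx$protein, cx$ligands, cutoff)
    got <- sort(paste(pocket$chain_id, pocket$residue_index))
    want <- oracle_pocket(cx$protein, cx$ligands, cutoff)
    expect_identical(got, want)
  }
  expect_equal(attr(define_pocket(cx$protein, cx$ligands), "cutoff"), 10)
})

test_that("pocket is empty for distant ligands and zero cutoff", {
  cx <- make_toy_complex(seed = 4, templates = "benzene")
  far <- perturb_pose(cx, "eject", seed = 2)
  expect_equal(nrow(define_pocket(far$protein, far$ligands)), 0)
  expect_equal(nrow(define_pocket(cx$protein, cx$ligands, cutoff = 0)), 0)
})

test_that("pocket definition is invariant to ligand order and rigid motion", {
  cx <- make_toy_complex(seed = 5, templates = c("benzene", "ion"))
  p1 <- define_pocket(cx$protein, cx$ligands)
  p2 <- define_pocket(cx$protein, rev(cx$ligands))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  set.seed(1)
  moved <- apply_transform(cx, random_rigid())
  p3 <- define_pocket(moved$protein, moved$ligands)
  expect_identical(as.data.frame(p1), as.data.frame(p3))
})

test_that("pocket alignment recovers a random rigid motion exactly", {
  cx <- make_toy_complex(seed = 6, templates = "benzene")
  pocket <- define_pocket(cx$protein, cx$ligands)
  set.seed(2)
  tf <- random_rigid()
  mobile <- apply_transform(cx$protein, tf)
  ali <- align_to_pocket(mobile, cx$protein, pocket)
  expect_lt(ali$fit_rmsd, 1e-8)
  expect_lt(max(abs(poseval:::protein_coords(ali$protein) -
                      poseval:::protein_coords(cx$protein))), 1e-7)
  # self-alignment is the identity
  ali0 <- align_to_pocket(cx$protein, cx$protein, pocket)
  expect_equal(ali0$transform$rotation, diag(3), tolerance = 1e-8)
})

test_that("pocket fit ignores a displaced distal domain, global fit does not", {
  cx <- make_toy_complex(seed = 8, templates = "benzene", n_residues = 12,
                         radius = 14)
  pocket <- define_pocket(cx$protein, cx$ligands, cutoff = 8)
  pocket_keys <- paste(pocket$chain_id, pocket$residue_index)
  expect_gt(nrow(pocket), 2)
  expect_lt(nrow(pocket), 12)  # some residues are outside: a distal domain
  mobile <- cx$protein
  distal <- !(paste(mobile$chain_id, mobile$residue_index) %in% pocket_keys)
  mobile$x[distal] <- mobile$x[distal] + 20
  ali <- align_to_pocket(mobile, cx$protein, pocket)
  expect_lt(ali$fit_rmsd, 1e-8)
  ca_m <- mobile[mobile$atom_name == "CA", ]
  ca_r <- cx$protein[cx$protein$atom_name == "CA", ]
  global <- kabsch(as.matrix(ca_m[, c("x", "y", "z")]),
                   as.matrix(ca_r[, c("x", "y", "z")]))
  expect_gt(global$fit_rmsd, 1)
})

test_that("missing pocket residues are reported by name", {
  cx <- make_toy_complex(seed = 6, templates = "benzene")
  pocket <- define_pocket(cx$protein, cx$ligands)
  mobile <- cx$protein[cx$protein$residue_index != pocket$residue_index[1], ]
  mobile <- protein_structure(mobile)
  expect_error(align_to_pocket(mobile, cx$protein, pocket),
               class = "poseval_degenerate_alignment")
})

test_that("chain mapping: identity, homodimer swap, incompatible chains", {
  cx <- two_chain_fixture(seed = 7)
  pocket <- define_pocket(cx$protein, cx$ligands)
  m <- map_chains(cx$protein, cx$protein, pocket)
  expect_equal(m$pred_chain, m$ref_chain)

  # relabel chains A<->B; the mapping must undo the swap (verified against
  # both bijections explicitly)
  swapped <- cx$protein
  swapped$chain_id <- ifelse(swapped$chain_id == "A", "B", "A")
  swapped <- protein_structure(swapped[order(swapped$chain_id,
                                             swapped$residue_index), ])
  m2 <- map_chains(swapped, cx$protein, pocket)
  got <- setNames(m2$ref_chain, m2$pred_chain)
  expect_equal(got[["A"]], "B")
  expect_equal(got[["B"]], "A")

  # exhaustive check: the chosen bijection has the lower pocket RMSD
  rmsd_of <- function(mapping) {
    pr <- poseval:::residue_ca_pairs(swapped, cx$protein, mapping, pocket)
    kabsch(as.matrix(pr[, c("x_pred", "y_pred", "z_pred")]),
           as.matrix(pr[, c("x_ref", "y_ref", "z_ref")]))$fit_rmsd
  }
  chosen <- rmsd_of(m2)
  ident <- tryCatch(rmsd_of(tibble::tibble(pred_chain = c("A", "B"),
                                           ref_chain = c("A", "B"))),
                    error = function(e) Inf)
  expect_lte(chosen, ident)

  # sequence-incompatible chains
  other <- make_toy_pocket(3, 6, 12,
                           residue_names = c("GLY", "GLY", "GLY"))
  expect_error(map_chains(other, cx$protein, pocket),
               class = "poseval_chain_mapping_error")
})

test_that("homodimer with swapped labels agrees with exhaustive search", {
  # two chains with identical sequences: a translated copy 30 A away
  cx <- make_toy_complex(seed = 9, templates = "benzene", n_residues = 6)
  a <- as.data.frame(cx$protein)
  b <- a; b$chain_id <- "B"; b$x <- b$x + 30
  dimer <- protein_structure(rbind(a, b))
  pocket <- define_pocket(dimer, cx$ligands)  # pocket sits on chain A only
  expect_true(all(pocket$chain_id == "A"))
  # prediction with labels swapped: chain "B" is the one near the pocket
  swapped <- as.data.frame(dimer)
  swapped$chain_id <- ifelse(swapped$chain_id == "A", "B", "A")
  swapped <- protein_structure(swapped[order(swapped$chain_id), ])
  m <- map_chains(swapped, dimer, pocket)
  got <- setNames(m$ref_chain, m$pred_chain)
  # exhaustive enumeration of both bijections
  rmsd_of <- function(pred_chains, ref_chains) {
    mp <- tibble::tibble(pred_chain = pred_chains, ref_chain = ref_chains)
    pr <- poseval:::residue_ca_pairs(swapped, dimer, mp, pocket)
    if (nrow(pr) < 3) return(Inf)
    kabsch(as.matrix(pr[, c("x_pred", "y_pred", "z_pred")]),
           as.matrix(pr[, c("x_ref", "y_ref", "z_ref")]))$fit_rmsd
  }
  r_swap <- rmsd_of(c("A", "B"), c("B", "A"))
  r_ident <- rmsd_of(c("A", "B"), c("A", "B"))
  best <- if (r_swap <= r_ident) c(A = "B", B = "A") else c(A = "A", B = "B")
  expect_equal(got[["A"]], best[["A"]])
  expect_equal(got[["B"]], best[["B"]])
  expect_lt(min(r_swap, r_ident), 1e-8)
})
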