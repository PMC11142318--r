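test_that("rigid translation gives RMSD and centroid distance equal to |d|", {
  for (tmpl in c("benzene", "ethanol", "ion")) {
    lig <- make_toy_ligand(tmpl)
    moved <- apply_transform(lig, rigid_transform(diag(3), c(3, 4, 0)))
    expect_equal(heavy_atom_rmsd(moved, lig), 5, tolerance = 1e-12)
    expect_equal(heavy_atom_rmsd(moved, lig, symmetry = FALSE), 5,
                 tolerance = 1e-12)
    expect_equal(centroid_rmsd(moved, lig), 5, tolerance = 1e-12)
  }
})

test_that("self-comparison gives exactly zero", {
  lig <- make_toy_ligand("acetate")
  expect_identical(heavy_atom_rmsd(lig, lig), 0)
  expect_identical(centroid_rmsd(lig, lig), 0)
})

test_that("benzene C6 rotation: symmetry-aware 0, naive > 1.3, matching the
           automorphism-enumeration oracle", {
  benz <- make_toy_ligand("benzene")
  ctr <- poseval:::ligand_centroid(benz)
  normal <- poseval:::fit_plane(poseval:::ligand_coords(benz))$normal
  R <- rotation_about_axis(normal, pi / 3)
  xyz <- poseval:::ligand_coords(benz)
  rot <- poseval:::set_ligand_coords(
    benz, sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+"))
  expect_equal(heavy_atom_rmsd(rot, benz, symmetry = TRUE), 0,
               tolerance = 1e-9)
  naive <- heavy_atom_rmsd(rot, benz, symmetry = FALSE)
  expect_gt(naive, 1.3)
  # oracle: minimum over the exhaustively enumerated automorphism group
  P <- poseval:::ligand_coords(rot)
  Q <- poseval:::ligand_coords(benz)
  autos <- oracle_automorphisms(benz)
  expect_length(autos, 12)
  oracle_min <- min(vapply(autos, function(p)
    sqrt(mean(rowSums((P - Q[p, ])^2))), 0))
  expect_equal(heavy_atom_rmsd(rot, benz), oracle_min, tolerance = 1e-12)
})

test_that("symmetry-aware RMSD never exceeds the naive RMSD", {
  set.seed(21)
  for (tmpl in c("benzene", "imidazole", "acetate")) {
    lig <- make_toy_ligand(tmpl)
    for (rep in 1:10) {
      noisy <- poseval:::set_ligand_coords(
        lig, poseval:::ligand_coords(lig) +
          matrix(rnorm(3 * nrow(lig$atoms), sd = 1), ncol = 3))
      expect_lte(heavy_atom_rmsd(noisy, lig),
                 heavy_atom_rmsd(noisy, lig, symmetry = FALSE) + 1e-12)
    }
  }
})

test_that("both RMSDs are invariant under simultaneous rigid motion", {
  set.seed(31)
  lig <- make_toy_ligand("imidazole")
  moved <- apply_transform(lig, rigid_transform(diag(3), c(1, -2, 0.5)))
  base_rmsd <- heavy_atom_rmsd(moved, lig)
  base_cd <- centroid_rmsd(moved, lig)
  for (rep in 1:5) {
    tf <- random_rigid()
    expect_equal(heavy_atom_rmsd(apply_transform(moved, tf),
                                 apply_transform(lig, tf)), base_rmsd,
                 tolerance = 1e-9)
    expect_equal(centroid_rmsd(apply_transform(moved, tf),
                               apply_transform(lig, tf)), base_cd,
                 tolerance = 1e-9)
  }
})

test_that("rotation about the centroid leaves the centroid fixed", {
  lig <- make_toy_ligand("ethanol")
  ctr <- poseval:::ligand_centroid(lig)
  xyz <- poseval:::ligand_coords(lig)
  R <- rotation_about_axis(c(0, 0, 1), 1.1)
  rot <- poseval:::set_ligand_coords(
    lig, sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+"))
  expect_equal(centroid_rmsd(rot, lig), 0, tolerance = 1e-12)
})

test_that("graph mismatches are refused", {
  expect_error(heavy_atom_rmsd(make_toy_ligand("benzene"),
                               make_toy_ligand("imidazole")),
               "mismatch")
})

test_that("fragment assignment: identity, crossed ions, partial classes", {
  benz <- make_toy_ligand("benzene")
  ion <- make_toy_ligand("ion")
  shift <- function(l, d) apply_transform(l, rigid_transform(diag(3), d))
  # unpermuted identical lists: identity mapping at zero cost
  preds <- list(benz, shift(ion, c(5, 0, 0)))
  a <- assign_fragments(preds, preds)
  expect_equal(a$pred_index, a$ref_index)
  expect_equal(a$rmsd, c(0, 0), tolerance = 1e-12)
  # two identical ions with crossed labels: the crossing assignment wins
  ion1 <- shift(ion, c(0, 0, 0)); ion2 <- shift(ion, c(4, 0, 0))
  a2 <- assign_fragments(list(ion2, ion1), list(ion1, ion2))
  expect_equal(a2$ref_index[order(a2$pred_index)], c(2L, 1L))
  expect_equal(sum(a2$rmsd), 0, tolerance = 1e-12)
  # 2 predicted vs 3 reference copies: size-2 mapping, one ref unmatched
  a3 <- assign_fragments(list(ion1, ion2),
                         list(ion1, ion2, shift(ion, c(8, 0, 0))))
  expect_equal(nrow(a3), 2)
  expect_length(attr(a3, "unmatched_ref"), 1)
})

test_that("assignment cost equals exhaustive permutation search", {
  set.seed(5)
  ion <- make_toy_ligand("ion")
  shift <- function(l, d) apply_transform(l, rigid_transform(diag(3), d))
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    preds <- lapply(seq_len(n), function(i) shift(ion, rnorm(3, sd = 4)))
    refs <- lapply(seq_len(n), function(i) shift(ion, rnorm(3, sd = 4)))
    got <- sum(assign_fragments(preds, refs)$rmsd)
    cost <- outer(seq_len(n), seq_len(n),
                  Vectorize(function(i, j)
                    heavy_atom_rmsd(preds[[i]], refs[[j]])))
    perms <- gtools_perms(n)
    want <- min(apply(perms, 1, function(p)
      sum(cost[cbind(seq_len(n), p)])))
    expect_equal(got, want, tolerance = 1e-9)
  }
})
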