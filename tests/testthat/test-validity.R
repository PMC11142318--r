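test_that("idealized template ligands pass every geometric check", {
  for (tmpl in c("benzene", "ethanol", "acetate", "methylammonium",
                 "imidazole", "ion")) {
    rep_ <- check_ligand_geometry(make_toy_ligand(tmpl))
    expect_true(rep_$sanitizable, info = tmpl)
    expect_true(rep_$bond_lengths_ok, info = tmpl)
    expect_true(rep_$bond_angles_ok, info = tmpl)
    expect_true(rep_$internal_clash_free, info = tmpl)
    expect_true(rep_$aromatic_rings_flat, info = tmpl)
    expect_true(rep_$double_bonds_flat, info = tmpl)
    expect_equal(nrow(rep_$violations), 0, info = tmpl)
  }
  # benzene ring is flat to machine precision
  mr <- poseval:::fit_plane(
    poseval:::ligand_coords(make_toy_ligand("benzene")))$max_residual
  expect_lt(mr, 1e-6)
})

test_that("each planted violation flips exactly its own flag", {
  benz <- make_toy_ligand("benzene")
  # stretched bond: one C-C at twice the reference length
  stretched <- benz
  xyz <- poseval:::ligand_coords(benz)
  dir_ <- xyz[2, ] - xyz[1, ]
  xyz2 <- xyz; xyz2[1, ] <- xyz[2, ] - 2 * dir_
  stretched <- poseval:::set_ligand_coords(stretched, xyz2)
  r1 <- check_ligand_geometry(stretched)
  expect_false(r1$bond_lengths_ok)
  expect_equal(sum(r1$violations$check == "bond_lengths"), 1)
  # puckered ring: one carbon lifted 1 A out of plane
  lifted <- benz
  xyz3 <- poseval:::ligand_coords(benz); xyz3[1, 3] <- 1
  lifted <- poseval:::set_ligand_coords(lifted, xyz3)
  r2 <- check_ligand_geometry(lifted)
  expect_false(r2$aromatic_rings_flat)
  expect_true(r2$bond_lengths_ok == FALSE || r2$aromatic_rings_flat == FALSE)
  expect_true(any(r2$violations$check == "aromatic_flat"))
  # internal clash: fold a para carbon of benzene onto its opposite atom
  # (a 1-4 pair, not excluded by the bonded/1-3 rule)
  benz2 <- make_toy_ligand("benzene")
  xyz4 <- poseval:::ligand_coords(benz2); xyz4[4, ] <- xyz4[1, ] + 0.3
  clashed <- poseval:::set_ligand_coords(benz2, xyz4)
  r3 <- check_ligand_geometry(clashed)
  expect_false(r3$internal_clash_free)
  # twisted carboxylate: rotate one acetate oxygen well out of the sp2
  # plane (a 1.5 A lift leaves a ~0.36 A best-plane residual)
  act <- make_toy_ligand("acetate")
  xyz5 <- poseval:::ligand_coords(act); xyz5[4, 3] <- xyz5[4, 3] + 1.5
  twisted <- poseval:::set_ligand_coords(act, xyz5)
  r4 <- check_ligand_geometry(twisted)
  expect_false(r4$double_bonds_flat)
})

test_that("unsanitizable graphs short-circuit the remaining checks", {
  bad <- ligand_mol(
    tibble::tibble(element = c("O", "O", "O"), formal_charge = 0L,
                   x = c(0, 1.4, 0.7), y = c(0, 0, 1.2), z = 0),
    tibble::tibble(i = c(1, 1), j = c(2, 3), order = c(2, 2)))
  r <- check_ligand_geometry(bad)
  expect_false(r$sanitizable)
  expect_true(is.na(r$bond_lengths_ok))
})

test_that("clash counts equal the all-pairs oracle", {
  cx <- make_toy_complex(seed = 17, templates = c("benzene", "ion"))
  got <- check_intermolecular(cx)
  pxyz <- poseval:::protein_coords(cx$protein)
  pel <- cx$protein$element
  want_pl <- 0
  for (l in cx$ligands) {
    want_pl <- want_pl + oracle_clashes(poseval:::ligand_coords(l),
                                        l$atoms$element, pxyz, pel)
  }
  l1 <- cx$ligands[[1]]; l2 <- cx$ligands[[2]]
  want_ll <- oracle_clashes(poseval:::ligand_coords(l1), l1$atoms$element,
                            poseval:::ligand_coords(l2), l2$atoms$element)
  expect_equal(got$protein_ligand_clashes, want_pl)
  expect_equal(got$inter_ligand_clashes, want_ll)
  # two superposed benzene copies: every atom-on-atom pair clashes
  b2 <- cx
  b2$ligands <- list(l1, l1)
  got2 <- check_intermolecular(b2)
  want2 <- oracle_clashes(poseval:::ligand_coords(l1), l1$atoms$element,
                          poseval:::ligand_coords(l1), l1$atoms$element)
  expect_equal(got2$inter_ligand_clashes, want2)
  expect_gte(got2$inter_ligand_clashes, 6)
  # a ligand atom dropped onto a protein C-alpha clashes
  ca <- as.matrix(cx$protein[cx$protein$atom_name == "CA",
                             c("x", "y", "z")])[1, ]
  moved <- poseval:::set_ligand_coords(
    l2, matrix(ca, 1, 3))
  got3 <- check_intermolecular(complex_pose(cx$protein, moved))
  expect_gte(got3$protein_ligand_clashes, 1)
})

test_that("pb_valid aggregates, is monotone, and flags planted defects", {
  cx <- make_toy_complex(seed = 18, templates = "benzene")
  v0 <- pb_valid(cx)
  expect_true(v0$pb_valid)
  expect_true(is.na(v0$energy_ratio_ok))  # deliberately not evaluated
  # plant a protein-ligand clash by moving the ligand onto a residue atom
  target <- poseval:::protein_coords(cx$protein)[1, ]
  lig <- cx$ligands[[1]]
  xyz <- poseval:::ligand_coords(lig)
  shift <- target - xyz[1, ]
  clashed <- cx
  clashed$ligands[[1]] <- poseval:::set_ligand_coords(
    lig, sweep(xyz, 2, shift, "+"))
  v1 <- pb_valid(clashed)
  expect_false(v1$pb_valid)
  expect_false(v1$protein_ligand_clash_free)
  # only the clash flag flipped among the geometry flags
  expect_true(v1$bond_lengths_ok && v1$bond_angles_ok &&
                v1$aromatic_rings_flat)
  # monotonicity: additionally puckering the ring cannot restore validity
  xyz2 <- poseval:::ligand_coords(clashed$ligands[[1]]); xyz2[1, 3] <-
    xyz2[1, 3] + 1
  worse <- clashed
  worse$ligands[[1]] <- poseval:::set_ligand_coords(clashed$ligands[[1]],
                                                    xyz2)
  v2 <- pb_valid(worse)
  expect_false(v2$pb_valid)
  expect_error(pb_valid(complex_pose(cx$protein, list())), "ligand")
})

test_that("validity checks are invariant under global rigid motion", {
  cx <- make_toy_complex(seed = 19, templates = "acetate")
  set.seed(6)
  moved <- apply_transform(cx, random_rigid())
  g0 <- glance(pb_valid(cx)); g1 <- glance(pb_valid(moved))
  expect_equal(as.data.frame(g1), as.data.frame(g0))
})

test_that("stereo flips are caught when a reference is supplied", {
  # build a chiral center: C bonded to four distinct substituents
  chiral <- ligand_mol(
    tibble::tibble(element = c("C", "N", "O", "S", "C"),
                   formal_charge = 0L,
                   x = c(0, 1.47, -0.49, -0.49, -0.49),
                   y = c(0, 0, 1.39, -0.70, -0.70),
                   z = c(0, 0, 0, 1.20, -1.20)),
    tibble::tibble(i = 1L, j = 2:5, order = 1))
  mirror <- chiral
  xyz <- poseval:::ligand_coords(chiral); xyz[, 3] <- -xyz[, 3]
  mirror <- poseval:::set_ligand_coords(mirror, xyz)
  prot <- make_toy_pocket(1, 6, 14)
  ok <- pb_valid(complex_pose(prot, chiral), ref = complex_pose(prot, chiral))
  expect_true(ok$stereo_preserved)
  flipped <- pb_valid(complex_pose(prot, mirror),
                      ref = complex_pose(prot, chiral))
  expect_false(flipped$stereo_preserved)
  expect_false(flipped$pb_valid)
})
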