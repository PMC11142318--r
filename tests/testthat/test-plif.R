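# helpers to build single-residue proteins at controlled geometry

residue_at <- function(resname, ca_pos, inward) {
  res <- poseval:::place_residue(resname, ca_pos, inward)
  res$chain_id <- "A"; res$residue_index <- 1L; res$residue_number <- 1L
  res$residue_name <- resname; res$is_hetero <- FALSE
  protein_structure(res)
}

test_that("a distant ligand yields an empty histogram", {
  prot <- residue_at("SER", c(0, 0, 0), c(0, 0, 1))
  lig <- apply_transform(make_toy_ligand("benzene"),
                         rigid_transform(diag(3), c(50, 0, 0)))
  h <- detect_plifs(complex_pose(prot, lig))
  expect_s3_class(h, "pv_plif")
  expect_equal(nrow(h), 0)
})

test_that("an ideal serine hydroxyl donating to a carbonyl oxygen is detected", {
  # build the serine first, then drop the acetate carbonyl oxygen 2.9 A
  # from OG at the tetrahedral angle off the CB-OG bond — the geometry of a
  # linear (180 degree) O-H...O=C hydrogen bond for a rotatable hydroxyl
  prot <- residue_at("SER", c(0, 0, 0), c(0, 0, -1))
  m <- as.matrix(as.data.frame(prot)[, c("x", "y", "z")])
  og <- m[which(prot$atom_name == "OG"), ]
  cb <- m[which(prot$atom_name == "CB"), ]
  axis <- (og - cb) / sqrt(sum((og - cb)^2))
  perp <- c(axis[2], -axis[1], 0)
  perp <- perp - sum(perp * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  d <- cos(70.5 * pi / 180) * axis + sin(70.5 * pi / 180) * perp
  act <- make_toy_ligand("acetate")
  o1 <- poseval:::ligand_coords(act)[3, ]  # the C=O oxygen
  act <- apply_transform(act, rigid_transform(diag(3), og + 2.9 * d - o1))
  h <- detect_plifs(complex_pose(prot, act))
  expect_true(any(h$ligand_code == "ACT" & h$residue_name == "SER" &
                    h$interaction == "HBond-acceptor"))
})

test_that("acetate near an arginine guanidinium gives an ionic (anion) hit", {
  act <- make_toy_ligand("acetate")
  # anion center: the charged carboxylate oxygen
  an <- poseval:::ligand_coords(act)[4, ]
  prot0 <- residue_at("ARG", c(0, 0, 20), c(0, 0, -1))
  cz <- colMeans(as.matrix(
    prot0[prot0$atom_name %in% c("NE", "NH1", "NH2"), c("x", "y", "z")]))
  target <- an + c(0, 0, 3.5)
  prot <- apply_transform(prot0, rigid_transform(diag(3), target - cz))
  h <- detect_plifs(complex_pose(prot, act))
  expect_true(any(h$ligand_code == "ACT" & h$residue_name == "ARG" &
                    h$interaction == "Ionic-anion"))
})

test_that("stacked phenylalanine over benzene gives pi stacking", {
  benz <- make_toy_ligand("benzene")  # ring in the z = 0 plane
  prot0 <- residue_at("PHE", c(0, 0, 10), c(0, 0, -1))
  ring <- colMeans(as.matrix(
    prot0[prot0$atom_name %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
          c("x", "y", "z")]))
  prot <- apply_transform(prot0, rigid_transform(diag(3),
                                                 c(0, 0, 3.6) - ring))
  h <- detect_plifs(complex_pose(prot, benz))
  expect_true(any(h$interaction == "PiStacking"))
})

test_that("a lone metal ion coordinating an aspartate oxygen is detected", {
  ion <- make_toy_ligand("ion")
  prot0 <- residue_at("ASP", c(0, 0, 10), c(0, 0, -1))
  od2 <- as.matrix(prot0[prot0$atom_name == "OD2", c("x", "y", "z")])[1, ]
  prot <- apply_transform(prot0, rigid_transform(diag(3),
                                                 c(0, 0, 2.5) - od2))
  h <- detect_plifs(complex_pose(prot, ion))
  expect_true(any(h$interaction == "MetalCoordination"))
})

test_that("detection is invariant under global rigid motion of the complex", {
  cx <- make_toy_complex(seed = 16, templates = "imidazole")
  h0 <- detect_plifs(cx)
  expect_gt(nrow(h0), 0)
  set.seed(4)
  for (rep in 1:3) {
    moved <- apply_transform(cx, random_rigid())
    expect_identical(as.data.frame(detect_plifs(moved)), as.data.frame(h0))
  }
})

test_that("unify_support unions keys in canonical order with zero fill", {
  k <- function(lig, res, int, n)
    poseval:::plif_histogram(tibble::tibble(
      ligand_code = rep(lig, n), residue_name = rep(res, n),
      interaction = rep(int, n)))
  u <- k("LIG", "SER", "HBond-donor", 3)
  s <- unify_support(u, u)
  expect_equal(s$u_weights, 3)
  expect_equal(s$v_weights, 3)
  u2 <- k("LIG", "ALA", "Hydrophobic", 1)
  v2 <- k("LIG", "SER", "HBond-donor", 2)
  s2 <- unify_support(u2, v2)
  expect_equal(s2$keys$residue_name, c("ALA", "SER"))  # lexicographic
  expect_equal(s2$u_weights, c(1, 0))
  expect_equal(s2$v_weights, c(0, 2))
  # three-key overlap matches a set-union oracle
  u3 <- dplyr::bind_rows(k("LIG", "SER", "HBond-donor", 1),
                         k("LIG", "ALA", "Hydrophobic", 2))
  v3 <- dplyr::bind_rows(k("LIG", "SER", "HBond-donor", 4),
                         k("LIG", "ARG", "Ionic-anion", 1))
  s3 <- unify_support(poseval:::plif_histogram(NULL), v3)
  expect_equal(nrow(s3$keys), 2)
  s4 <- unify_support(u3, v3)
  want <- sort(unique(c(paste(u3$residue_name, u3$interaction),
                        paste(v3$residue_name, v3$interaction))))
  expect_equal(sort(paste(s4$keys$residue_name, s4$keys$interaction)), want)
  expect_error(unify_support(poseval:::plif_histogram(NULL),
                             poseval:::plif_histogram(NULL)),
               class = "poseval_empty_histograms")
})

hist_of <- function(weights) {
  poseval:::plif_histogram(tibble::tibble(
    ligand_code = "LIG",
    residue_name = sprintf("R%02d", rep(seq_along(weights), weights)),
    interaction = "Hydrophobic"))
}

test_that("PLIF-EMD closed forms: identity and separated point masses", {
  u <- hist_of(c(2, 3, 1))
  expect_equal(plif_emd(u, u), 0)
  # all mass at position 0 vs all mass at position 2 on a 3-key support:
  # the point masses are |0 - 2| = 2 apart
  three <- function(counts) as_plif(tibble::tibble(
    ligand_code = "LIG", residue_name = c("R01", "R02", "R03"),
    interaction = "Hydrophobic", count = counts))
  expect_equal(plif_emd(three(c(5, 0, 0)), three(c(0, 0, 5))), 2)
  # split target mass: W1 = 0.5*|1-0| + 0.5*|2-0| = 1.5, symmetric
  expect_equal(plif_emd(three(c(4, 0, 0)), three(c(0, 1, 1))), 1.5)
  expect_equal(plif_emd(three(c(0, 1, 1)), three(c(4, 0, 0))), 1.5)
})

test_that("PLIF-EMD equals the greedy-transport oracle on random histograms", {
  set.seed(55)
  for (rep in 1:50) {
    m <- sample(2:7, 1)
    uw <- rpois(m, 3); vw <- rpois(m, 3)
    if (sum(uw) == 0) uw[1] <- 1
    if (sum(vw) == 0) vw[m] <- 1
    # build histograms sharing the full support so positions line up
    u <- hist_of(uw + 0L); v <- hist_of(vw + 0L)
    s <- unify_support(u, v)
    got <- plif_emd(u, v)
    want <- oracle_transport_1d(s$u_weights, s$v_weights)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("PLIF-EMD is a metric on random triples", {
  set.seed(66)
  for (rep in 1:60) {
    m <- sample(2:6, 1)
    mk <- function() {
      w <- rpois(m, 2); if (sum(w) == 0) w[sample(m, 1)] <- 1
      hist_of(w)
    }
    a <- mk(); b <- mk(); c_ <- mk()
    dab <- plif_emd(a, b); dbc <- plif_emd(b, c_); dac <- plif_emd(a, c_)
    expect_gte(dab, 0)
    expect_equal(dab, plif_emd(b, a), tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-9)  # triangle inequality
  }
})

test_that("empty-histogram policy: error by default, max-distance fallback", {
  u <- hist_of(c(1, 2, 1))
  e <- poseval:::plif_histogram(NULL)
  expect_error(plif_emd(u, e), class = "poseval_empty_histograms")
  expect_equal(plif_emd(u, e, empty_policy = "max"), 2)
})

test_that("PLIF-WM arithmetic, endpoints and degenerate collections", {
  wm <- plif_wm(c(A = 0.2, B = 0.5, C = 0.8))
  expect_equal(unname(wm), c(1, 0.5, 0), tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:10) {
    emds <- setNames(runif(sample(2:6, 1)), NULL)
    names(emds) <- paste0("m", seq_along(emds))
    wm <- plif_wm(emds)
    expect_equal(unname(wm[which.min(emds)]), 1)
    expect_equal(unname(wm[which.max(emds)]), 0)
    expect_true(all(wm >= 0 & wm <= 1))
  }
  expect_warning(wm2 <- plif_wm(c(A = 0.3, B = 0.3)), "degenerate")
  expect_equal(unname(wm2), c(1, 1))
})
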