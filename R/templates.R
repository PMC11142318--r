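# Idealized heavy-atom residue and small-molecule templates, built in code
# from standard internal coordinates (NeRF placement; aromatic rings are
# exact regular polygons so flatness holds to machine precision).

zrow <- function(name, element, ref1 = 0L, ref2 = 0L, ref3 = 0L,
                 dist = 0, angle = 0, dihedral = 0) {
  tibble::tibble(name = name, element = element, ref1 = ref1, ref2 = ref2,
                 ref3 = ref3, dist = dist, angle = angle, dihedral = dihedral)
}

backbone_zmat <- function() {
  dplyr::bind_rows(
    zrow("N", "N"),
    zrow("CA", "C", 1L, dist = 1.458),
    zrow("C", "C", 2L, 1L, dist = 1.525, angle = 111.0),
    zrow("O", "O", 3L, 2L, 1L, dist = 1.231, angle = 120.5, dihedral = 150),
    zrow("CB", "C", 2L, 1L, 3L, dist = 1.530, angle = 110.5, dihedral = 122))
}

# regular planar ring attached at an anchor atom, extending away from its
# bonded substituent; returns coordinates for the remaining ring vertices in
# ring order starting after the anchor
attach_ring <- function(anchor, substituent, other, side, n_vertices) {
  xhat <- unit(anchor - substituent)
  yraw <- other - anchor
  yhat <- unit(yraw - sum(yraw * xhat) * xhat)
  R <- side / (2 * sin(pi / n_vertices))
  center <- anchor + R * xhat
  theta0 <- pi  # anchor sits at 180 degrees
  step <- 2 * pi / n_vertices
  t(vapply(seq_len(n_vertices - 1), function(k) {
    th <- theta0 - k * step
    center + R * (cos(th) * xhat + sin(th) * yhat)
  }, numeric(3)))
}

residue_template_impl <- function(resname) {
  z <- backbone_zmat()
  if (resname == "GLY") z <- z[1:4, ]
  extra <- switch(resname,
    GLY = , ALA = NULL,
    SER = zrow("OG", "O", 5L, 2L, 1L, dist = 1.417, angle = 110.8,
               dihedral = 180),
    ASP = dplyr::bind_rows(
      zrow("CG", "C", 5L, 2L, 1L, dist = 1.516, angle = 113.0, dihedral = 180),
      zrow("OD1", "O", 6L, 5L, 2L, dist = 1.249, angle = 118.4, dihedral = 0),
      zrow("OD2", "O", 6L, 5L, 2L, dist = 1.249, angle = 118.4,
           dihedral = 180)),
    ARG = dplyr::bind_rows(
      zrow("CG", "C", 5L, 2L, 1L, dist = 1.520, angle = 111.3, dihedral = 180),
      zrow("CD", "C", 6L, 5L, 2L, dist = 1.520, angle = 111.3, dihedral = 180),
      zrow("NE", "N", 7L, 6L, 5L, dist = 1.461, angle = 112.0, dihedral = 180),
      zrow("CZ", "C", 8L, 7L, 6L, dist = 1.329, angle = 124.2, dihedral = 180),
      zrow("NH1", "N", 9L, 8L, 7L, dist = 1.326, angle = 120.0, dihedral = 0),
      zrow("NH2", "N", 9L, 8L, 7L, dist = 1.326, angle = 120.0,
           dihedral = 180)),
    PHE = zrow("CG", "C", 5L, 2L, 1L, dist = 1.500, angle = 113.8,
               dihedral = 180),
    HIS = zrow("CG", "C", 5L, 2L, 1L, dist = 1.500, angle = 113.8,
               dihedral = 180),
    stop("no template for residue ", resname, call. = FALSE))
  z <- dplyr::bind_rows(z, extra)
  xyz <- build_zmat(z)
  atoms <- tibble::tibble(atom_name = z$name, element = z$element,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (resname == "PHE") {
    ring <- attach_ring(xyz[6, ], xyz[5, ], xyz[2, ], 1.39, 6)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      atom_name = c("CD1", "CE1", "CZ", "CE2", "CD2"),
      element = "C", x = ring[, 1], y = ring[, 2], z = ring[, 3]))
  }
  if (resname == "HIS") {
    ring <- attach_ring(xyz[6, ], xyz[5, ], xyz[2, ], 1.37, 5)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      atom_name = c("ND1", "CE1", "NE2", "CD2"),
      element = c("N", "C", "N", "C"),
      x = ring[, 1], y = ring[, 2], z = ring[, 3]))
  }
  atoms
}

RESIDUE_TEMPLATE_SET <- c("GLY", "ALA", "SER", "ARG", "ASP", "PHE", "HIS")

.template_cache <- new.env(parent = emptyenv())

#' Idealized heavy-atom template for a residue
#'
#' @param resname one of `GLY, ALA, SER, ARG, ASP, PHE, HIS` — a curated set
#'   sufficient to plant every interaction type the fingerprint detector
#'   knows.
#' @return Tibble with `atom_name`, `element`, `x`, `y`, `z`.
#' @export
residue_template <- function(resname) {
  key <- paste0("res_", resname)
  if (is.null(.template_cache[[key]]))
    .template_cache[[key]] <- residue_template_impl(resname)
  .template_cache[[key]]
}

ligand_template_impl <- function(template) {
  hexagon <- function(side) {
    th <- (0:5) * pi / 3
    cbind(side * cos(th), side * sin(th), 0)
  }
  pentagon <- function(side) {
    R <- side / (2 * sin(pi / 5))
    th <- pi / 2 - (0:4) * 2 * pi / 5
    cbind(R * cos(th), R * sin(th), 0)
  }
  ring_bonds <- function(n, order = 1.5) {
    tibble::tibble(i = seq_len(n), j = c(2:n, 1L), order = order)
  }
  switch(template,
    benzene = {
      xyz <- hexagon(1.39)
      ligand_mol(tibble::tibble(atom_name = paste0("C", 1:6), element = "C",
                                formal_charge = 0L,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                 ring_bonds(6), "BNZ")
    },
    ethanol = {
      z <- dplyr::bind_rows(zrow("C1", "C"),
                            zrow("C2", "C", 1L, dist = 1.526),
                            zrow("O1", "O", 2L, 1L, dist = 1.417,
                                 angle = 108.7))
      xyz <- build_zmat(z)
      ligand_mol(tibble::tibble(atom_name = z$name, element = z$element,
                                formal_charge = 0L, x = xyz[, 1],
                                y = xyz[, 2], z = xyz[, 3]),
                 tibble::tibble(i = c(1L, 2L), j = c(2L, 3L), order = 1),
                 "EOH")
    },
    acetate = {
      z <- dplyr::bind_rows(
        zrow("C1", "C"),
        zrow("C2", "C", 1L, dist = 1.520),
        zrow("O1", "O", 2L, 1L, dist = 1.250, angle = 117.0),
        zrow("O2", "O", 2L, 1L, 3L, dist = 1.250, angle = 117.0,
             dihedral = 180))
      xyz <- build_zmat(z)
      ligand_mol(tibble::tibble(atom_name = z$name, element = z$element,
                                formal_charge = c(0L, 0L, 0L, -1L),
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                 tibble::tibble(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                                order = c(1, 2, 1)),
                 "ACT")
    },
    methylammonium = {
      ligand_mol(tibble::tibble(atom_name = c("C1", "N1"),
                                element = c("C", "N"),
                                formal_charge = c(0L, 1L),
                                x = c(0, 1.50), y = 0, z = 0),
                 tibble::tibble(i = 1L, j = 2L, order = 1), "MAM")
    },
    imidazole = {
      xyz <- pentagon(1.36)
      ligand_mol(tibble::tibble(atom_name = c("N1", "C2", "N3", "C4", "C5"),
                                element = c("N", "C", "N", "C", "C"),
                                formal_charge = 0L,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                 ring_bonds(5), "IMD")
    },
    ion = {
      ligand_mol(tibble::tibble(atom_name = "MG", element = "Mg",
                                formal_charge = 2L, x = 0, y = 0, z = 0),
                 NULL, "MG")
    },
    stop("unknown ligand template: ", template, call. = FALSE))
}

LIGAND_TEMPLATE_SET <- c("benzene", "ethanol", "acetate", "methylammonium",
                         "imidazole", "ion")

#' Idealized toy ligand
#'
#' Returns a small molecule with literature bond lengths and angles that
#' passes every geometric validity check; aromatic rings are flat to
#' machine precision.
#'
#' @param template one of `benzene`, `ethanol`, `acetate`,
#'   `methylammonium`, `imidazole`, `ion`.
#' @return A `pv_ligand`.
#' @export
make_toy_ligand <- function(template = LIGAND_TEMPLATE_SET) {
  template <- match.arg(template)
  key <- paste0("lig_", template)
  if (is.null(.template_cache[[key]]))
    .template_cache[[key]] <- ligand_template_impl(template)
  .template_cache[[key]]
}
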