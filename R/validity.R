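#' Tolerances for pose validity checks
#'
#' The defaults follow the published PoseBusters geometric defaults: bond
#' lengths and angles within 0.75-1.25 of reference, non-bonded
#' intramolecular pairs at >= 0.8 of the vdW-radius sum, intermolecular
#' clashes below 0.75 of the vdW-radius sum, and at most 0.25 Angstrom
#' out-of-plane deviation for aromatic rings and double bonds.
#'
#' @param bond_ratio length-2 allowed bond-length ratio window.
#' @param angle_ratio length-2 allowed bond-angle ratio window.
#' @param intra_vdw_factor minimum allowed non-bonded intramolecular
#'   distance as a fraction of the vdW sum.
#' @param inter_vdw_factor clash threshold fraction for intermolecular
#'   pairs.
#' @param flatness_max max out-of-plane deviation (Angstrom).
#' @return List of class `pv_tolerances`.
#' @export
validity_tolerances <- function(bond_ratio = c(0.75, 1.25),
                                angle_ratio = c(0.75, 1.25),
                                intra_vdw_factor = 0.8,
                                inter_vdw_factor = 0.75,
                                flatness_max = 0.25) {
  structure(list(bond_ratio = bond_ratio, angle_ratio = angle_ratio,
                 intra_vdw_factor = intra_vdw_factor,
                 inter_vdw_factor = inter_vdw_factor,
                 flatness_max = flatness_max),
            class = "pv_tolerances")
}

# sp hybridization from the incident bonds: any triple or two doubles ->
# 180 degrees; any double/aromatic -> 120; else tetrahedral
ideal_angle_at <- function(ligand, center) {
  b <- ligand$bonds[ligand$bonds$i == center | ligand$bonds$j == center, ]
  if (any(b$order == 3) || sum(b$order == 2) >= 2) return(180)
  if (any(b$order >= 1.5)) return(120)
  109.47
}

#' Geometric and chemical sanity checks for a ligand conformer
#'
#' @param ligand a `pv_ligand`.
#' @param tolerances a [validity_tolerances()] object.
#' @return A list (partial validity report) with logical flags
#'   `sanitizable`, `bond_lengths_ok`, `bond_angles_ok`,
#'   `internal_clash_free`, `aromatic_rings_flat`, `double_bonds_flat`, and
#'   a `violations` tibble describing each failure.
#' @export
check_ligand_geometry <- function(ligand, tolerances = validity_tolerances()) {
  viol <- list()
  note <- function(check, detail, value) {
    viol[[length(viol) + 1]] <<- tibble::tibble(check = check,
                                                detail = detail,
                                                value = value)
  }
  sanitizable <- tryCatch({ check_valences(ligand); TRUE },
                          error = function(e) { note("sanitizable",
                                                     conditionMessage(e),
                                                     NA_real_); FALSE })
  report <- list(sanitizable = sanitizable, bond_lengths_ok = NA,
                 bond_angles_ok = NA, internal_clash_free = NA,
                 aromatic_rings_flat = NA, double_bonds_flat = NA)
  if (!sanitizable) {
    report$violations <- dplyr::bind_rows(viol)
    return(report)
  }
  xyz <- ligand_coords(ligand)
  el <- ligand$atoms$element
  # bond lengths against order-adjusted covalent reference
  bond_ok <- TRUE
  for (b in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[b]; j <- ligand$bonds$j[b]
    d <- vnorm(xyz[i, ] - xyz[j, ])
    ref <- reference_bond_length(el[i], el[j], ligand$bonds$order[b])
    ratio <- d / ref
    if (ratio < tolerances$bond_ratio[1] || ratio > tolerances$bond_ratio[2]) {
      bond_ok <- FALSE
      note("bond_lengths", sprintf("bond %d-%d (%s-%s)", i, j, el[i], el[j]),
           ratio)
    }
  }
  report$bond_lengths_ok <- bond_ok
  # bond angles against hybridization ideal
  angle_ok <- TRUE
  for (ctr in seq_len(nrow(ligand$atoms))) {
    nb <- atom_neighbors(ligand, ctr)
    if (length(nb) < 2) next
    ideal <- ideal_angle_at(ligand, ctr)
    combs <- utils::combn(nb, 2)
    for (k in seq_len(ncol(combs))) {
      a <- angle_deg(xyz[combs[1, k], ], xyz[ctr, ], xyz[combs[2, k], ])
      ratio <- a / ideal
      if (ratio < tolerances$angle_ratio[1] ||
          ratio > tolerances$angle_ratio[2]) {
        angle_ok <- FALSE
        note("bond_angles", sprintf("angle %d-%d-%d", combs[1, k], ctr,
                                    combs[2, k]), ratio)
      }
    }
  }
  report$bond_angles_ok <- angle_ok
  # non-bonded intramolecular pairs (excluding 1-2 and 1-3)
  excl <- bonded_and_13_pairs(ligand)
  clash_free <- TRUE
  n <- nrow(xyz)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (paste(i, j) %in% excl) next
      d <- vnorm(xyz[i, ] - xyz[j, ])
      lim <- tolerances$intra_vdw_factor * (vdw_radius(el[i]) +
                                              vdw_radius(el[j]))
      if (d < lim) {
        clash_free <- FALSE
        note("internal_clash", sprintf("pair %d-%d", i, j), d / lim)
      }
    }
  }
  report$internal_clash_free <- clash_free
  # aromatic ring flatness
  flat_ok <- TRUE
  for (ring in aromatic_rings(ligand)) {
    mr <- fit_plane(xyz[ring, , drop = FALSE])$max_residual
    if (mr > tolerances$flatness_max) {
      flat_ok <- FALSE
      note("aromatic_flat", paste("ring", paste(ring, collapse = "-")), mr)
    }
  }
  report$aromatic_rings_flat <- flat_ok
  # double-bond planarity: the two sp2 atoms and their substituents
  dbl_ok <- TRUE
  dbl <- ligand$bonds[ligand$bonds$order == 2, , drop = FALSE]
  for (b in seq_len(nrow(dbl))) {
    atoms_ <- unique(c(dbl$i[b], dbl$j[b], atom_neighbors(ligand, dbl$i[b]),
                       atom_neighbors(ligand, dbl$j[b])))
    if (length(atoms_) < 4) next
    mr <- fit_plane(xyz[atoms_, , drop = FALSE])$max_residual
    if (mr > tolerances$flatness_max) {
      dbl_ok <- FALSE
      note("double_bond_flat", sprintf("bond %d=%d", dbl$i[b], dbl$j[b]), mr)
    }
  }
  report$double_bonds_flat <- dbl_ok
  report$violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(check = character(), detail = character(),
                   value = numeric())
  report
}

bonded_and_13_pairs <- function(ligand) {
  keys <- character(0)
  add <- function(i, j) paste(min(i, j), max(i, j))
  for (b in seq_len(nrow(ligand$bonds)))
    keys <- c(keys, add(ligand$bonds$i[b], ligand$bonds$j[b]))
  for (ctr in seq_len(nrow(ligand$atoms))) {
    nb <- atom_neighbors(ligand, ctr)
    if (length(nb) >= 2) {
      combs <- utils::combn(nb, 2)
      for (k in seq_len(ncol(combs)))
        keys <- c(keys, add(combs[1, k], combs[2, k]))
    }
  }
  unique(keys)
}

#' Intermolecular steric-clash counts
#'
#' A clash is a non-bonded heavy-atom pair closer than
#' `inter_vdw_factor` times the sum of the two van der Waals radii.
#' Protein-ligand and ligand-ligand clashes are counted separately.
#'
#' @param complex a `pv_complex` in one frame.
#' @param tolerances a [validity_tolerances()].
#' @return List with `protein_ligand_clashes` and `inter_ligand_clashes`
#'   (integer counts).
#' @export
check_intermolecular <- function(complex,
                                 tolerances = validity_tolerances()) {
  stopifnot(inherits(complex, "pv_complex"))
  f <- tolerances$inter_vdw_factor
  P <- protein_coords(complex$protein)
  pr <- vdw_radius(complex$protein$element)
  pl <- 0L
  for (lig in complex$ligands) {
    L <- ligand_coords(lig)
    lr <- vdw_radius(lig$atoms$element)
    D <- cross_dist(L, P)
    lim <- f * outer(lr, pr, "+")
    pl <- pl + sum(D < lim)
  }
  ll <- 0L
  nlig <- length(complex$ligands)
  if (nlig >= 2) {
    for (a in seq_len(nlig - 1)) for (b in (a + 1):nlig) {
      La <- ligand_coords(complex$ligands[[a]])
      Lb <- ligand_coords(complex$ligands[[b]])
      ra <- vdw_radius(complex$ligands[[a]]$atoms$element)
      rb <- vdw_radius(complex$ligands[[b]]$atoms$element)
      D <- cross_dist(La, Lb)
      lim <- f * outer(ra, rb, "+")
      ll <- ll + sum(D < lim)
    }
  }
  list(protein_ligand_clashes = as.integer(pl),
       inter_ligand_clashes = as.integer(ll))
}

#' PoseBusters-style validity verdict for a complex pose
#'
#' Aggregates the per-fragment geometry checks and the intermolecular clash
#' checks into one verdict per complex (for multi-ligand complexes the
#' verdict is calculated once for the whole complex). The force-field
#' energy-ratio inspection of the original suite is deliberately not
#' evaluated (recorded as `NA`) to keep the verdict deterministic and
#' dependency-light; stereo preservation is checked only when a reference
#' set is supplied.
#'
#' @param complex a `pv_complex`.
#' @param tolerances a [validity_tolerances()].
#' @param ref optional reference `pv_complex` for the stereo-preservation
#'   check (fragments matched by graph).
#' @return List of class `pv_validity`: logical `pb_valid`, the individual
#'   flags, clash counts, `energy_ratio_ok = NA` (not evaluated), and a
#'   `violations` tibble.
#' @export
pb_valid <- function(complex, tolerances = validity_tolerances(),
                     ref = NULL) {
  stopifnot(inherits(complex, "pv_complex"))
  if (length(complex$ligands) == 0)
    stop("complex has no ligands", call. = FALSE)
  flags <- list(sanitizable = TRUE, bond_lengths_ok = TRUE,
                bond_angles_ok = TRUE, internal_clash_free = TRUE,
                aromatic_rings_flat = TRUE, double_bonds_flat = TRUE)
  violations <- list()
  for (k in seq_along(complex$ligands)) {
    rep_k <- check_ligand_geometry(complex$ligands[[k]], tolerances)
    for (f in names(flags)) {
      flags[[f]] <- flags[[f]] && isTRUE(rep_k[[f]] | is.na(rep_k[[f]]))
    }
    if (nrow(rep_k$violations) > 0) {
      v <- rep_k$violations; v$fragment <- k
      violations[[length(violations) + 1]] <- v
    }
  }
  inter <- check_intermolecular(complex, tolerances)
  flags$protein_ligand_clash_free <- inter$protein_ligand_clashes == 0
  flags$inter_ligand_clash_free <- inter$inter_ligand_clashes == 0
  if (!is.null(ref)) {
    flags$stereo_preserved <- stereo_preserved(complex, ref)
  }
  verdict <- all(vapply(flags, isTRUE, TRUE))
  structure(c(list(pb_valid = verdict), flags,
              inter,
              list(energy_ratio_ok = NA,
                   violations = if (length(violations))
                     dplyr::bind_rows(violations) else
                       tibble::tibble(check = character(),
                                      detail = character(),
                                      value = numeric(),
                                      fragment = integer()))),
            class = "pv_validity")
}

# tetrahedral-center parity comparison: signed volume of the first three
# neighbors around each stereocenter candidate, matched through the graph
stereo_preserved <- function(complex, ref) {
  assign <- assign_fragments(complex$ligands, ref$ligands)
  if (nrow(assign) == 0) return(TRUE)
  for (r in seq_len(nrow(assign))) {
    pl <- complex$ligands[[assign$pred_index[r]]]
    rl <- ref$ligands[[assign$ref_index[r]]]
    maps <- ligand_isomorphisms(pl, rl)
    if (length(maps) == 0) next
    ok_any <- FALSE
    for (perm in maps) {
      if (parities_match(pl, rl, perm)) { ok_any <- TRUE; break }
    }
    if (!ok_any) return(FALSE)
  }
  TRUE
}

parities_match <- function(pl, rl, perm) {
  xyzp <- ligand_coords(pl); xyzr <- ligand_coords(rl)
  for (ctr in seq_len(nrow(pl$atoms))) {
    nb <- atom_neighbors(pl, ctr)
    if (length(nb) < 4) next
    nb <- sort(nb)[1:4]
    sp <- signed_volume(xyzp[nb[1], ] - xyzp[nb[4], ],
                        xyzp[nb[2], ] - xyzp[nb[4], ],
                        xyzp[nb[3], ] - xyzp[nb[4], ])
    rb <- perm[nb]
    sr <- signed_volume(xyzr[rb[1], ] - xyzr[rb[4], ],
                        xyzr[rb[2], ] - xyzr[rb[4], ],
                        xyzr[rb[3], ] - xyzr[rb[4], ])
    if (sign(sp) != sign(sr)) return(FALSE)
  }
  TRUE
}

signed_volume <- function(a, b, c_) sum(a * vcross(b, c_))
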