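#' Geometric criteria for interaction detection
#'
#' Distance cutoffs in Angstrom, angle windows in degrees. Defaults mirror
#' the published defaults of the standard fingerprinting tools.
#'
#' @param hbond_dist donor-acceptor heavy-atom distance cutoff.
#' @param hbond_angle minimum idealized D-H...A angle.
#' @param hydrophobic_dist apolar carbon/sulfur contact cutoff.
#' @param ionic_dist opposite formal-charge group-center cutoff.
#' @param pi_dist aromatic ring-centroid distance cutoff.
#' @param pi_face_angle maximum inter-plane angle for face-to-face stacking.
#' @param pi_edge_window inter-plane angle window for edge-to-face stacking.
#' @param cation_pi_dist charge-to-ring-centroid cutoff.
#' @param halogen_dist halogen-acceptor distance cutoff.
#' @param halogen_angle minimum C-X...A angle.
#' @param metal_dist metal to N/O/S coordination cutoff.
#' @param include_vdw also emit generic van der Waals contacts (off by
#'   default, like the reference tool)?
#' @param vdw_tolerance added to the vdW-radius sum when `include_vdw`.
#' @return List of class `pv_criteria`.
#' @export
geometric_criteria <- function(hbond_dist = 3.5, hbond_angle = 130,
                               hydrophobic_dist = 4.5, ionic_dist = 4.5,
                               pi_dist = 5.5, pi_face_angle = 35,
                               pi_edge_window = c(50, 90),
                               cation_pi_dist = 4.5, halogen_dist = 3.5,
                               halogen_angle = 130, metal_dist = 2.8,
                               include_vdw = FALSE, vdw_tolerance = 0) {
  crit <- as.list(environment())
  stopifnot(all(vapply(crit[c("hbond_dist", "hydrophobic_dist", "ionic_dist",
                              "pi_dist", "cation_pi_dist", "halogen_dist",
                              "metal_dist")], function(x) x > 0, TRUE)))
  structure(crit, class = "pv_criteria")
}

INTERACTION_TYPES <- c("HBond-donor", "HBond-acceptor", "Hydrophobic",
                       "Ionic-cation", "Ionic-anion", "PiStacking",
                       "CationPi", "PiCation", "HalogenBond",
                       "MetalCoordination", "VdWContact")

# --- ligand-side chemistry heuristics (heavy atoms only) -------------------

ligand_atom_roles <- function(ligand) {
  el <- ligand$atoms$element
  chg <- ligand$atoms$formal_charge
  deg <- atom_degree(ligand)
  bosum <- atom_bond_order_sum(ligand)
  n <- nrow(ligand$atoms)
  has_double <- logical(n); aromatic <- logical(n)
  for (b in seq_len(nrow(ligand$bonds))) {
    if (ligand$bonds$order[b] == 2) {
      has_double[ligand$bonds$i[b]] <- TRUE
      has_double[ligand$bonds$j[b]] <- TRUE
    }
    if (ligand$bonds$order[b] == 1.5) {
      aromatic[ligand$bonds$i[b]] <- TRUE
      aromatic[ligand$bonds$j[b]] <- TRUE
    }
  }
  # implicit hydrogen count from standard valences
  std_val <- c(C = 4, N = 3, O = 2, S = 2)[el]
  implied_h <- pmax(0, ifelse(is.na(std_val), 0, std_val) + chg - bosum)
  donor <- (el %in% c("N", "O", "S")) & implied_h > 0 & chg >= 0
  acceptor <- ((el == "O") & chg <= 0) |
    ((el == "N") & chg <= 0 & implied_h == 0 & bosum <= 3)
  hydrophobic <- el %in% c("C", "S") & chg == 0
  cation <- chg > 0
  anion <- chg < 0
  halogen <- el %in% c("Cl", "Br", "I")
  metal <- is_metal(el)
  tibble::tibble(donor = donor, acceptor = acceptor,
                 hydrophobic = hydrophobic, cation = cation, anion = anion,
                 halogen = halogen, metal = metal, implied_h = implied_h)
}

# idealized hydrogen direction for a donor heavy atom: on the cone at the
# hybridization angle around the bond axis (single neighbor), steered toward
# the acceptor; or opposite the mean neighbor direction (several neighbors)
ideal_hbond_angle <- function(donor_pos, neighbor_pos, acceptor_pos,
                              cone_deg = 109.5) {
  if (is.null(neighbor_pos) || nrow(neighbor_pos) == 0) return(180)
  to_acc <- acceptor_pos - donor_pos
  if (nrow(neighbor_pos) == 1) {
    axis <- unit(donor_pos - neighbor_pos[1, ])
    half <- (180 - cone_deg) * pi / 180
    perp <- to_acc - sum(to_acc * axis) * axis
    if (vnorm(perp) < 1e-9) {
      h_dir <- axis
    } else {
      h_dir <- cos(half) * axis + sin(half) * unit(perp)
    }
  } else {
    away <- donor_pos - colMeans(neighbor_pos)
    if (vnorm(away) < 1e-9) return(0)
    h_dir <- unit(away)
  }
  h_pos <- donor_pos + 1.0 * h_dir
  angle_deg(donor_pos, h_pos, acceptor_pos)
}

# --- protein-side tables ---------------------------------------------------

protein_residue_features <- function(protein) {
  pt <- as_plain_tibble(protein)
  split(pt, paste(pt$chain_id, pt$residue_index))
}

residue_donor_atoms <- function(res) {
  nm <- res$atom_name
  sel <- nm == "N" | nm %in% PROTEIN_DONORS[[res$residue_name[1]]]
  which(sel)
}

residue_acceptor_atoms <- function(res) {
  nm <- res$atom_name
  sel <- nm == "O" | nm == "OXT" |
    nm %in% PROTEIN_ACCEPTORS[[res$residue_name[1]]]
  which(sel)
}

#' Detect protein-ligand interaction fingerprints
#'
#' Scans every ligand x residue pair against geometric interaction rules
#' and counts satisfied rules as fingerprint tuples
#' `<ligand code, residue name, interaction type>`. Interaction direction
#' names take the ligand's perspective: `HBond-donor` means the ligand
#' donates, `Ionic-anion` means the ligand carries the negative charge,
#' `CationPi` a ligand cation over a protein ring, `PiCation` a ligand ring
#' under a protein cation. Idealized hydrogen positions are constructed
#' geometrically from heavy-atom frames for the hydrogen-bond angle test.
#'
#' @param complex a `pv_complex`, protein and ligands in one frame.
#' @param criteria a [geometric_criteria()] object.
#' @return A `pv_plif` tibble: `ligand_code`, `residue_name`, `interaction`,
#'   `count`. Zero rows is a valid (empty) histogram.
#' @export
detect_plifs <- function(complex, criteria = geometric_criteria()) {
  stopifnot(inherits(complex, "pv_complex"))
  residues <- protein_residue_features(complex$protein)
  rows <- list()
  emit <- function(lig_code, res_name, type) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      ligand_code = lig_code, residue_name = res_name, interaction = type)
  }
  for (lig in complex$ligands) {
    roles <- ligand_atom_roles(lig)
    L <- ligand_coords(lig)
    lig_rings <- aromatic_rings(lig)
    for (res in residues) {
      R <- unname(as.matrix(res[, c("x", "y", "z")]))
      D <- cross_dist(L, R)
      if (min(D) > max(criteria$hydrophobic_dist, criteria$pi_dist,
                       criteria$ionic_dist, criteria$hbond_dist) + 4) next
      resname <- res$residue_name[1]
      detect_pair(lig, roles, L, res, R, D, resname, criteria, emit,
                  lig_rings)
    }
  }
  hist_rows <- dplyr::bind_rows(rows)
  plif_histogram(hist_rows)
}

plif_histogram <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) {
    out <- tibble::tibble(ligand_code = character(),
                          residue_name = character(),
                          interaction = character(), count = integer())
  } else {
    out <- rows |>
      dplyr::count(.data$ligand_code, .data$residue_name,
                   .data$interaction, name = "count") |>
      dplyr::arrange(.data$ligand_code, .data$residue_name,
                     .data$interaction)
  }
  class(out) <- c("pv_plif", class(tibble::tibble()))
  out
}

detect_pair <- function(lig, roles, L, res, R, D, resname, criteria, emit,
                        lig_rings) {
  code <- lig$ligand_code
  nm <- res$atom_name
  res_el <- res$element
  # hydrogen bonds: ligand donor -> protein acceptor
  don <- which(roles$donor)
  acc_res <- residue_acceptor_atoms(res)
  for (i in don) for (j in acc_res) {
    if (D[i, j] <= criteria$hbond_dist) {
      nb <- atom_neighbors(lig, i)
      ang <- ideal_hbond_angle(L[i, ], L[nb, , drop = FALSE], R[j, ])
      if (ang >= criteria$hbond_angle) emit(code, resname, "HBond-donor")
    }
  }
  # hydrogen bonds: protein donor -> ligand acceptor
  acc <- which(roles$acceptor)
  don_res <- residue_donor_atoms(res)
  for (j in don_res) for (i in acc) {
    if (D[i, j] <= criteria$hbond_dist) {
      nb <- which(cross_dist(R[j, , drop = FALSE], R)[1, ] < 1.8 &
                    seq_len(nrow(R)) != j)
      ang <- ideal_hbond_angle(R[j, ], R[nb, , drop = FALSE], L[i, ])
      if (ang >= criteria$hbond_angle) emit(code, resname, "HBond-acceptor")
    }
  }
  # hydrophobic: apolar C/S within cutoff of apolar side-chain C/S
  hyd <- which(roles$hydrophobic)
  hyd_res <- which(res_el %in% c("C", "S") & !backbone_atom(nm))
  if (length(hyd) && length(hyd_res) &&
      any(D[hyd, hyd_res, drop = FALSE] <= criteria$hydrophobic_dist))
    emit(code, resname, "Hydrophobic")
  # ionic: group-center distances between opposite formal charges
  cat_center <- charged_group_center(res, PROTEIN_CATIONS)
  an_center <- charged_group_center(res, PROTEIN_ANIONS)
  if (any(roles$anion) && !is.null(cat_center)) {
    lc <- colMeans(L[roles$anion, , drop = FALSE])
    if (vnorm(lc - cat_center) <= criteria$ionic_dist)
      emit(code, resname, "Ionic-anion")
  }
  if (any(roles$cation) && !is.null(an_center)) {
    lc <- colMeans(L[roles$cation, , drop = FALSE])
    if (vnorm(lc - an_center) <= criteria$ionic_dist)
      emit(code, resname, "Ionic-cation")
  }
  # pi stacking between aromatic rings
  res_rings <- PROTEIN_RINGS[[resname]]
  if (!is.null(res_rings) && length(lig_rings)) {
    for (lr in lig_rings) {
      pl_l <- fit_plane(L[lr, , drop = FALSE])
      for (rr in res_rings) {
        idx <- match(rr, nm)
        if (anyNA(idx)) next
        pl_r <- fit_plane(R[idx, , drop = FALSE])
        dctr <- vnorm(pl_l$centroid - pl_r$centroid)
        if (dctr > criteria$pi_dist) next
        ang <- plane_angle(pl_l$normal, pl_r$normal)
        if (ang <= criteria$pi_face_angle ||
            (ang >= criteria$pi_edge_window[1] &&
             ang <= criteria$pi_edge_window[2]))
          emit(code, resname, "PiStacking")
      }
    }
  }
  # ligand cation over protein aromatic ring
  if (any(roles$cation) && !is.null(res_rings)) {
    lc <- colMeans(L[roles$cation, , drop = FALSE])
    for (rr in res_rings) {
      idx <- match(rr, nm)
      if (anyNA(idx)) next
      ctr <- colMeans(R[idx, , drop = FALSE])
      if (vnorm(lc - ctr) <= criteria$cation_pi_dist) {
        emit(code, resname, "CationPi"); break
      }
    }
  }
  # ligand ring under protein cationic group
  if (length(lig_rings) && !is.null(cat_center)) {
    for (lr in lig_rings) {
      ctr <- colMeans(L[lr, , drop = FALSE])
      if (vnorm(ctr - cat_center) <= criteria$cation_pi_dist) {
        emit(code, resname, "PiCation"); break
      }
    }
  }
  # halogen bonds: C-X ... acceptor
  hal <- which(roles$halogen)
  for (i in hal) for (j in residue_acceptor_atoms(res)) {
    if (D[i, j] <= criteria$halogen_dist) {
      nb <- atom_neighbors(lig, i)
      if (length(nb) == 1) {
        # angle at X between the carbon antecedent and the acceptor
        ang_cxa <- angle_deg(L[nb[1], ], L[i, ], R[j, ])
        if (ang_cxa >= criteria$halogen_angle)
          emit(code, resname, "HalogenBond")
      }
    }
  }
  # metal coordination: ligand metal to protein N/O/S
  met <- which(roles$metal)
  coord_res <- which(res_el %in% c("N", "O", "S"))
  if (length(met) && length(coord_res) &&
      any(D[met, coord_res, drop = FALSE] <= criteria$metal_dist))
    emit(code, resname, "MetalCoordination")
  # optional generic vdW contacts
  if (isTRUE(criteria$include_vdw)) {
    vsum <- outer(vdw_radius(lig$atoms$element), vdw_radius(res_el), "+")
    if (any(D <= vsum + criteria$vdw_tolerance))
      emit(code, resname, "VdWContact")
  }
  invisible(NULL)
}

plane_angle <- function(n1, n2) {
  a <- acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
  a
}

charged_group_center <- function(res, table) {
  atoms <- table[[res$residue_name[1]]]
  if (is.null(atoms)) return(NULL)
  idx <- match(atoms, res$atom_name)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(NULL)
  colMeans(as.matrix(res[idx, c("x", "y", "z")]))
}

#' Unify the supports of two fingerprint histograms
#'
#' @param u,v `pv_plif` histograms.
#' @return List with `keys` (tibble of the union support, sorted
#'   lexicographically by ligand code, residue name, interaction),
#'   `u_weights`, `v_weights` (counts aligned to it, zeros where absent).
#' @export
unify_support <- function(u, v) {
  if (nrow(u) == 0 && nrow(v) == 0)
    rlang::abort("both histograms are empty",
                 class = "poseval_empty_histograms")
  keys <- dplyr::bind_rows(u[, 1:3], v[, 1:3]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$ligand_code, .data$residue_name, .data$interaction)
  key_str <- function(h) paste(h$ligand_code, h$residue_name, h$interaction,
                               sep = "\r")
  ks <- key_str(keys)
  uw <- numeric(nrow(keys)); vw <- numeric(nrow(keys))
  uw[match(key_str(u), ks)] <- u$count
  vw[match(key_str(v), ks)] <- v$count
  list(keys = keys, u_weights = uw, v_weights = vw)
}

#' PLIF-EMD: 1-D Wasserstein distance between fingerprint histograms
#'
#' The two histograms are placed on the unified support (bins at integer
#' positions 0..m-1 in canonical lexicographic order), normalized to
#' probability mass by default, and compared with the 1-D Wasserstein
#' distance `sum(|CDF_u - CDF_v|)` over the unit-spaced positions.
#'
#' @param u,v `pv_plif` histograms.
#' @param normalize divide each histogram by its total count (default
#'   `TRUE`; when `FALSE`, raw counts are compared and mass differences
#'   accumulate into the distance at the last bin).
#' @param empty_policy `"error"` (default) raises when exactly one histogram
#'   is empty; `"max"` returns the maximum distance `m - 1` on the other's
#'   support instead.
#' @return Non-negative distance.
#' @export
plif_emd <- function(u, v, normalize = TRUE,
                     empty_policy = c("error", "max")) {
  empty_policy <- match.arg(empty_policy)
  # a table whose counts are all zero carries no mass: treat as empty
  if (nrow(u) > 0 && sum(u$count) == 0) u <- u[0, ]
  if (nrow(v) > 0 && sum(v$count) == 0) v <- v[0, ]
  if (nrow(u) == 0 && nrow(v) == 0)
    rlang::abort("both histograms are empty",
                 class = "poseval_empty_histograms")
  if (xor(nrow(u) == 0, nrow(v) == 0)) {
    if (empty_policy == "error")
      rlang::abort("one histogram is empty; PLIF-EMD undefined",
                   class = "poseval_empty_histograms")
    other <- if (nrow(u) == 0) v else u
    return(max(nrow(other) - 1, 0))
  }
  s <- unify_support(u, v)
  uw <- s$u_weights; vw <- s$v_weights
  if (normalize) { uw <- uw / sum(uw); vw <- vw / sum(vw) }
  sum(abs(cumsum(uw) - cumsum(vw)))
}

#' PLIF-WM: min-max normalized Wasserstein matching score
#'
#' Rescales a collection of per-method mean PLIF-EMD values to `[0, 1]`
#' with higher better: the collection's best (lowest EMD) method scores 1,
#' the worst scores 0.
#'
#' @param method_emds named numeric vector of mean PLIF-EMD per method.
#' @return Named numeric vector of scores in `[0, 1]`. A degenerate
#'   collection (all equal, or a single method) scores 1 everywhere with a
#'   warning.
#' @export
plif_wm <- function(method_emds) {
  stopifnot(length(method_emds) >= 1, !is.null(names(method_emds)))
  lo <- min(method_emds); hi <- max(method_emds)
  if (hi - lo < .Machine$double.eps) {
    warning("degenerate collection: all PLIF-EMD values equal; ",
            "every method scores 1", call. = FALSE)
    return(setNames(rep(1, length(method_emds)), names(method_emds)))
  }
  1 - (method_emds - lo) / (hi - lo)
}

#' Coerce a data frame to a fingerprint histogram
#'
#' Unlike [detect_plifs()], which only emits observed tuples, this keeps
#' explicit zero-count bins, which is occasionally useful to pin down a
#' support.
#'
#' @param df data frame with columns `ligand_code`, `residue_name`,
#'   `interaction`, `count`.
#' @return A `pv_plif` tibble sorted in canonical order.
#' @export
as_plif <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("ligand_code", "residue_name", "interaction", "count")
  stopifnot(all(req %in% names(df)), all(df$count >= 0))
  out <- df[, req] |>
    dplyr::arrange(.data$ligand_code, .data$residue_name, .data$interaction)
  out$count <- as.integer(out$count)
  class(out) <- c("pv_plif", class(tibble::tibble()))
  out
}
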