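# Deterministic synthetic complexes with planted, closed-form ground-truth
# metric values: the package's entire test surface.

# counter-based sub-seed stream: per-item seeds independent of generation
# order, kept below 2^31
sub_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + index * 104729 + stream * 7907) %%
               2147483629)
}

#' Toy binding pocket on a sphere
#'
#' Places idealized residues (full heavy-atom templates) on a Fibonacci
#' sphere of the given radius around the origin, side chains pointing
#' inward, each residue spun by a seeded random angle about its inward
#' axis. The construction is deterministic in `seed`.
#'
#' @param seed integer seed.
#' @param n_residues number of residues (>= 4).
#' @param radius sphere radius in Angstrom (C-alpha distance from origin).
#' @param residue_names recycled vector of template names (subset of
#'   `GLY, ALA, SER, ARG, ASP, PHE, HIS`); default cycles through the set.
#' @param n_chains split residues evenly into this many chains.
#' @param min_separation inter-residue heavy-atom distance below which the
#'   sphere is deemed too small (error).
#' @return A `pv_protein`.
#' @export
make_toy_pocket <- function(seed = 1, n_residues = 8, radius = 12,
                            residue_names = NULL, n_chains = 1,
                            min_separation = 2.2) {
  if (n_residues < 4) stop("need at least 4 residues", call. = FALSE)
  if (is.null(residue_names))
    residue_names <- c("ALA", "SER", "PHE", "ASP", "ARG", "HIS", "GLY")
  residue_names <- rep_len(residue_names, n_residues)
  dirs <- fibonacci_sphere(n_residues)
  chains <- LETTERS[ceiling(seq_len(n_residues) / ceiling(n_residues /
                                                            n_chains))]
  atoms <- withr::with_seed(sub_seed(seed, 0L), {
    rows <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      spin <- stats::runif(1, 0, 2 * pi)
      rows[[i]] <- place_residue(residue_names[i], dirs[i, ] * radius,
                                 -dirs[i, ], spin)
    }
    rows
  })
  res_index <- stats::ave(seq_len(n_residues), chains, FUN = seq_along)
  for (i in seq_len(n_residues)) {
    atoms[[i]]$chain_id <- chains[i]
    atoms[[i]]$residue_index <- res_index[i]
    atoms[[i]]$residue_number <- res_index[i]
    atoms[[i]]$residue_name <- residue_names[i]
  }
  tab <- dplyr::bind_rows(atoms)
  tab$is_hetero <- FALSE
  prot <- protein_structure(tab)
  check_pocket_separation(prot, min_separation)
  prot
}

check_pocket_separation <- function(prot, min_separation) {
  pt <- as_plain_tibble(prot)
  key <- paste(pt$chain_id, pt$residue_index)
  xyz <- protein_coords(prot)
  for (k in unique(key)) {
    a <- xyz[key == k, , drop = FALSE]
    b <- xyz[key != k, , drop = FALSE]
    if (nrow(b) && min(cross_dist(a, b)) < min_separation)
      stop("radius too small: inter-residue contacts below ",
           min_separation, " A", call. = FALSE)
  }
  invisible(prot)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# orient a residue template: CA lands on `ca_pos`, the side-chain direction
# maps onto `inward`, then spin about the inward axis
place_residue <- function(resname, ca_pos, inward, spin = 0) {
  tmpl <- residue_template(resname)
  xyz <- as.matrix(tmpl[, c("x", "y", "z")])
  ca <- xyz[tmpl$atom_name == "CA", ]
  side <- setdiff(tmpl$atom_name, c("N", "CA", "C", "O"))
  tip <- if (length(side)) colMeans(xyz[tmpl$atom_name %in% side, ,
                                        drop = FALSE]) else
    2 * ca - colMeans(xyz[tmpl$atom_name %in% c("N", "C", "O"), ,
                          drop = FALSE])
  v <- unit(tip - ca)
  R1 <- rotation_between(v, unit(inward))
  R2 <- rotation_about_axis(unit(inward), spin)
  xyz2 <- sweep((sweep(xyz, 2, ca) %*% t(R1)) %*% t(R2), 2, ca_pos, "+")
  tibble::tibble(atom_name = tmpl$atom_name, element = tmpl$element,
                 x = xyz2[, 1], y = xyz2[, 2], z = xyz2[, 3])
}

rotation_between <- function(a, b) {
  # minimal rotation taking unit vector a onto unit vector b
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    axis <- vcross(a, c(1, 0, 0))
    if (vnorm(axis) < 1e-6) axis <- vcross(a, c(0, 1, 0))
    return(rotation_about_axis(axis, pi))
  }
  axis <- vcross(a, b)
  rotation_about_axis(axis, acos(c_))
}

#' Toy protein-ligand complex with guaranteed detectable interactions
#'
#' Builds a pocket around the origin, centers the requested ligand(s) in
#' the cavity, and plants one deterministic contact (a hydrophobic
#' side-chain contact, or a coordinating aspartate for a lone metal ion) so
#' every generated reference complex carries at least one fingerprint,
#' passes the validity checks and has a non-empty 10 Angstrom pocket.
#'
#' @param seed integer seed.
#' @param templates ligand template name(s); first is the primary ligand.
#' @param n_residues,radius pocket geometry, see [make_toy_pocket()].
#' @param n_chains number of protein chains.
#' @param validate re-check the generator guarantees and error on violation
#'   (default `TRUE`).
#' @return A `pv_complex`.
#' @export
make_toy_complex <- function(seed = 1, templates = "benzene",
                             n_residues = 8, radius = NULL, n_chains = 1,
                             validate = TRUE) {
  # default cavity widens with the number of fragments so laterally offset
  # cofactors stay clear of the side chains; when the radius is automatic
  # the builder retries with a wider sphere if the seeded side-chain spins
  # happen to graze a fragment
  auto <- is.null(radius)
  if (auto) radius <- 12 + 1.5 * (length(templates) - 1)
  radii <- if (auto) radius + c(0, 2.5, 5) else radius
  last_err <- NULL
  for (r in radii) {
    pose <- tryCatch(build_toy_complex(seed, templates, n_residues, r,
                                       n_chains, validate),
                     error = function(e) { last_err <<- e; NULL })
    if (!is.null(pose)) return(pose)
  }
  stop(last_err)
}

build_toy_complex <- function(seed, templates, n_residues, radius,
                              n_chains, validate) {
  protein <- make_toy_pocket(seed, n_residues, radius, n_chains = n_chains)
  ligands <- list()
  dirs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1))
  extent <- function(xyz) if (nrow(xyz) == 1) 0 else
    max(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  prim_extent <- NA_real_
  for (k in seq_along(templates)) {
    lig <- make_toy_ligand(templates[k])
    xyz <- ligand_coords(lig)
    xyz <- sweep(xyz, 2, colMeans(xyz))  # center on its centroid
    rot <- withr::with_seed(sub_seed(seed, k, 1L), random_rotation())
    xyz <- xyz %*% t(rot)
    if (k == 1) {
      prim_extent <- extent(xyz)
    } else {
      # lateral offset large enough that the fragment clears the primary
      # ligand by a comfortable van der Waals margin in any orientation
      off <- prim_extent + extent(xyz) + 2.8
      xyz <- sweep(xyz, 2, dirs[min(k, nrow(dirs)), ] * off, "+")
    }
    ligands[[k]] <- set_ligand_coords(lig, xyz)
  }
  pose <- complex_pose(protein, ligands,
                       c("primary", rep("fragment", length(ligands) - 1)))
  pose <- plant_contact(pose)
  if (validate) {
    stopifnot(nrow(define_pocket(pose$protein, pose$ligands)) > 0)
    val <- pb_valid(pose)
    if (!val$pb_valid)
      stop("generator produced an invalid complex (seed ", seed, ")",
           call. = FALSE)
    if (nrow(detect_plifs(pose)) == 0)
      stop("generator produced a complex with no detectable interaction",
           call. = FALSE)
  }
  pose
}

# replace the first residue with a deterministically placed contact
# partner: an ALA whose CB sits 4.0 A from the nearest apolar ligand atom,
# or an ASP whose OD2 coordinates a lone metal at 2.6 A
plant_contact <- function(pose) {
  prim <- primary_ligand(pose)
  roles <- ligand_atom_roles(prim)
  L <- ligand_coords(prim)
  metal_only <- all(roles$metal)
  if (metal_only) {
    resname <- "ASP"; contact_atom <- "OD2"; gap <- 2.6
    anchor_idx <- 1L
  } else {
    resname <- "ALA"; contact_atom <- "CB"; gap <- 4.0
    anchor_idx <- if (any(roles$hydrophobic)) which(roles$hydrophobic)[1]
      else 1L
  }
  anchor <- L[anchor_idx, ]
  pt <- as_plain_tibble(pose$protein)
  first_key <- pt$chain_id == pt$chain_id[1] & pt$residue_index == 1
  # direction: away from the complex center through the anchor atom
  dir_out <- anchor - c(0, 0, 0)
  if (vnorm(dir_out) < 1e-6) dir_out <- c(1, 0, 0)
  dir_out <- unit(dir_out)
  res <- place_residue(resname, anchor + dir_out * (gap + 1.53), -dir_out)
  # shift so the contact atom sits exactly at `gap` from the anchor
  cpos <- as.matrix(res[res$atom_name == contact_atom, c("x", "y", "z")])[1, ]
  shift <- (anchor + dir_out * gap) - cpos
  res$x <- res$x + shift[1]; res$y <- res$y + shift[2]
  res$z <- res$z + shift[3]
  res$chain_id <- pt$chain_id[1]
  res$residue_index <- 1L
  res$residue_number <- 1L
  res$residue_name <- resname
  res$is_hetero <- FALSE
  newtab <- dplyr::bind_rows(res[, names(pt)], pt[!first_key, ])
  pose$protein <- protein_structure(newtab)
  pose
}

#' Perturb a complex pose with known ground-truth metric effects
#'
#' Operates on the ligands (the protein is untouched):
#' `translate` moves every ligand by a seeded random direction times
#' `magnitude`, so heavy-atom RMSD and centroid distance both equal
#' `magnitude` exactly; `rotate_about_centroid` spins each ligand about its
#' own centroid by `magnitude` degrees (centroid distance exactly 0);
#' `jitter` adds i.i.d. Gaussian noise with sd `magnitude` per coordinate;
#' `automorphism_permute` relabels atoms by a seeded graph automorphism
#' (symmetry-aware RMSD exactly 0); `eject` moves the ligands out of the
#' pocket, at least `magnitude` (default 25) Angstrom from every residue.
#'
#' @param pose a `pv_complex`.
#' @param mode one of `translate`, `rotate_about_centroid`, `jitter`,
#'   `automorphism_permute`, `eject`.
#' @param magnitude mode-specific magnitude (Angstrom, degrees, or sd).
#' @param seed integer seed.
#' @param which `"all"` (default) or `"primary"`.
#' @return The perturbed `pv_complex`.
#' @export
perturb_pose <- function(pose, mode = c("translate", "rotate_about_centroid",
                                        "jitter", "automorphism_permute",
                                        "eject"),
                         magnitude = 1, seed = 1, which = "all") {
  mode <- match.arg(mode)
  stopifnot(inherits(pose, "pv_complex"))
  idx <- if (which == "primary") which(pose$roles == "primary") else
    seq_along(pose$ligands)
  withr::with_seed(sub_seed(seed, 0L, 2L), {
    for (k in idx) {
      lig <- pose$ligands[[k]]
      xyz <- ligand_coords(lig)
      xyz <- switch(mode,
        translate = sweep(xyz, 2, random_unit_vector() * magnitude, "+"),
        rotate_about_centroid = {
          ctr <- colMeans(xyz)
          R <- rotation_about_axis(random_unit_vector(),
                                   magnitude * pi / 180)
          sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
        },
        jitter = xyz + matrix(stats::rnorm(length(xyz), sd = magnitude),
                              nrow(xyz), 3),
        automorphism_permute = {
          # an automorphism preserves adjacency and colors, so permuting
          # the coordinate rows alone leaves the molecule identical while
          # shuffling which atom sits where
          maps <- ligand_isomorphisms(lig)
          nontrivial <- Filter(function(p) !all(p == seq_along(p)), maps)
          perm <- if (length(nontrivial))
            nontrivial[[sample(length(nontrivial), 1)]] else
              seq_len(nrow(xyz))
          xyz[perm, , drop = FALSE]
        },
        eject = {
          pxyz <- protein_coords(pose$protein)
          dir_ <- random_unit_vector()
          shift <- dir_ * (max(cross_dist(xyz, pxyz)) +
                             max(magnitude, 25))
          sweep(xyz, 2, shift, "+")
        })
      pose$ligands[[k]] <- set_ligand_coords(lig, xyz)
    }
  })
  pose
}
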