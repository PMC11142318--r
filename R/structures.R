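#' Build a protein structure from an atom table
#'
#' A protein structure is a tibble of heavy-atom records with one row per
#' atom, carrying class `pv_protein`. Atoms are grouped by
#' `(chain_id, residue_index)` where `residue_index` is a 1-based sequential
#' index within each chain; the depositor's residue numbering is kept in
#' `residue_number` as metadata only.
#'
#' @param atoms a data frame with columns `chain_id`, `residue_index`,
#'   `residue_name`, `residue_number`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `is_hetero`. `residue_index` and `residue_number` may be omitted, in
#'   which case they are derived from record order.
#' @return A `pv_protein` tibble.
#' @export
protein_structure <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  if (!"is_hetero" %in% names(atoms)) atoms$is_hetero <- FALSE
  if (!"residue_number" %in% names(atoms)) {
    atoms$residue_number <- atoms$residue_index
  }
  if (!"residue_index" %in% names(atoms)) {
    # sequential 1-based index: order of first appearance within each chain
    atoms <- atoms |>
      dplyr::group_by(.data$chain_id) |>
      dplyr::mutate(residue_index = match(.data$residue_number,
                                          unique(.data$residue_number))) |>
      dplyr::ungroup()
  }
  req <- c("chain_id", "residue_index", "residue_name", "residue_number",
           "atom_name", "element", "x", "y", "z", "is_hetero")
  missing <- setdiff(req, names(atoms))
  if (length(missing))
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0) stop("empty structure", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  atoms <- atoms[, req]
  atoms$residue_index <- as.integer(atoms$residue_index)
  class(atoms) <- c("pv_protein", class(tibble::tibble()))
  atoms
}

#' @export
print.pv_protein <- function(x, ...) {
  nres <- nrow(dplyr::distinct(as_plain_tibble(x), .data$chain_id,
                               .data$residue_index))
  cat(sprintf("<pv_protein> %d atoms, %d residues, %d chain(s)\n",
              nrow(x), nres, dplyr::n_distinct(x$chain_id)))
  NextMethod()
}

as_plain_tibble <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}

protein_coords <- function(protein) {
  unname(as.matrix(protein[, c("x", "y", "z")]))
}

#' Per-chain one-letter sequences of a protein
#'
#' @param protein a `pv_protein`.
#' @return Named character vector, one sequence per chain; non-standard
#'   residues become `X`.
#' @export
protein_sequences <- function(protein) {
  res <- as_plain_tibble(protein) |>
    dplyr::distinct(.data$chain_id, .data$residue_index, .data$residue_name) |>
    dplyr::arrange(.data$chain_id, .data$residue_index)
  out <- res |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(seq = paste(aa_one_letter(.data$residue_name),
                                 collapse = ""), .groups = "drop")
  setNames(out$seq, out$chain_id)
}

#' @export
apply_transform.pv_protein <- function(x, tf) {
  out <- apply_transform.data.frame(as_plain_tibble(x), tf)
  class(out) <- class(x)
  out
}

#' Build a ligand molecule
#'
#' A ligand couples a heavy-atom molecular graph (elements, formal charges,
#' bonds with orders) with one 3D conformer. Aromatic bonds use order 1.5.
#'
#' @param atoms data frame with columns `element`, `formal_charge`, `x`, `y`,
#'   `z` and optionally `atom_name`.
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 1.5 for aromatic). May have zero rows.
#' @param ligand_code short label, e.g. the PDB chemical component code.
#' @return A `pv_ligand` object.
#' @export
ligand_mol <- function(atoms, bonds = NULL, ligand_code = "LIG") {
  atoms <- tibble::as_tibble(atoms)
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  if (!"atom_name" %in% names(atoms)) {
    atoms$atom_name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  if (nrow(atoms) < 1) stop("ligand must have at least one heavy atom",
                            call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite ligand coordinates", call. = FALSE)
  if (is.null(bonds)) bonds <- tibble::tibble(i = integer(), j = integer(),
                                              order = numeric())
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
            bonds$j < 1 | bonds$j > nrow(atoms)))
      stop("bond endpoints index invalid atoms", call. = FALSE)
    if (any(bonds$i == bonds$j)) stop("self-bond", call. = FALSE)
  }
  obj <- structure(list(atoms = atoms[, c("atom_name", "element",
                                          "formal_charge", "x", "y", "z")],
                        bonds = bonds[, c("i", "j", "order")],
                        ligand_code = ligand_code),
                   class = "pv_ligand")
  obj
}

#' @export
print.pv_ligand <- function(x, ...) {
  cat(sprintf("<pv_ligand> %s: %d heavy atoms, %d bonds, net charge %+d\n",
              x$ligand_code, nrow(x$atoms), nrow(x$bonds),
              sum(x$atoms$formal_charge)))
  invisible(x)
}

ligand_coords <- function(ligand) {
  unname(as.matrix(ligand$atoms[, c("x", "y", "z")]))
}

set_ligand_coords <- function(ligand, xyz) {
  ligand$atoms$x <- xyz[, 1]; ligand$atoms$y <- xyz[, 2]
  ligand$atoms$z <- xyz[, 3]
  ligand
}

#' Heavy-atom centroid of a ligand
#'
#' @param ligand a `pv_ligand`.
#' @return Numeric length-3 centroid (unweighted mean of heavy atoms).
#' @export
ligand_centroid <- function(ligand) {
  colMeans(ligand_coords(ligand))
}

#' @export
apply_transform.pv_ligand <- function(x, tf) {
  set_ligand_coords(x, apply_transform(ligand_coords(x), tf))
}

#' Assemble a protein-ligand complex pose
#'
#' @param protein a `pv_protein`.
#' @param ligands list of `pv_ligand` (or a single ligand).
#' @param roles character vector, one of `"primary"`/`"fragment"` per ligand.
#'   Defaults to the first ligand primary, the rest fragments.
#' @return A `pv_complex` object. Protein and ligand coordinates are taken to
#'   live in the same frame.
#' @export
complex_pose <- function(protein, ligands, roles = NULL) {
  stopifnot(inherits(protein, "pv_protein"))
  if (inherits(ligands, "pv_ligand")) ligands <- list(ligands)
  stopifnot(length(ligands) >= 1,
            all(vapply(ligands, inherits, TRUE, "pv_ligand")))
  if (is.null(roles))
    roles <- c("primary", rep("fragment", length(ligands) - 1))
  stopifnot(length(roles) == length(ligands),
            all(roles %in% c("primary", "fragment")))
  structure(list(protein = protein, ligands = ligands, roles = roles),
            class = "pv_complex")
}

#' @export
print.pv_complex <- function(x, ...) {
  cat(sprintf("<pv_complex> %d protein atoms, %d ligand(s): %s\n",
              nrow(x$protein), length(x$ligands),
              paste(sprintf("%s[%s]",
                            vapply(x$ligands, `[[`, "", "ligand_code"),
                            x$roles), collapse = ", ")))
  invisible(x)
}

#' @export
apply_transform.pv_complex <- function(x, tf) {
  x$protein <- apply_transform(x$protein, tf)
  x$ligands <- lapply(x$ligands, apply_transform, tf = tf)
  x
}

#' Primary ligand of a complex
#' @param pose a `pv_complex`.
#' @return The `pv_ligand` tagged primary.
#' @export
primary_ligand <- function(pose) {
  idx <- which(pose$roles == "primary")
  if (length(idx) != 1)
    stop("complex must have exactly one primary ligand", call. = FALSE)
  pose$ligands[[idx]]
}
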