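#' Read a protein structure from PDB or mmCIF
#'
#' Heavy atoms only; hydrogens are dropped, waters are dropped by default,
#' and alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by altloc label).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keep_waters keep HOH/WAT residues?
#' @param keep_hetero keep non-water HETATM records (they are flagged in
#'   `is_hetero`)?
#' @return A `pv_protein` tibble.
#' @export
read_protein <- function(path, format = c("auto", "pdb", "cif"),
                         keep_waters = FALSE, keep_hetero = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                       rm.alt = FALSE)),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- tibble::as_tibble(parsed$atom)
  if (nrow(at) == 0) stop("empty structure: ", path, call. = FALSE)
  at$element <- normalize_element(at$elesy, at$elety)
  at <- at[at$element != "H" & at$element != "D", ]
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), ]
  if (!keep_hetero) at <- at[at$type == "ATOM", ]
  if (nrow(at) == 0) stop("no heavy atoms after filtering: ", path,
                          call. = FALSE)
  # altloc resolution: highest occupancy, ties by altloc label
  at$alt[is.na(at$alt) | at$alt == ""] <- ""
  at$o[is.na(at$o)] <- 1
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$eleno)
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  protein_structure(tibble::tibble(
    chain_id = at$chain,
    residue_name = at$resid,
    residue_number = at$resno,
    atom_name = at$elety,
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    is_hetero = at$type != "ATOM"))
}

normalize_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy) | elesy == "", "", elesy)))
  # fall back to the atom-name convention when the element column is absent
  guess <- toupper(substr(gsub("[^A-Za-z].*", "",
                               sub("^[0-9]*", "", trimws(elety))), 1, 2))
  two_letter <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA", "SE", "CU",
                  "NI", "CO")
  guess <- ifelse(guess %in% two_letter & nchar(guess) == 2, guess,
                  substr(guess, 1, 1))
  el[el == ""] <- guess[el == ""]
  # title case
  paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
}

#' Write a protein structure to PDB
#'
#' @param protein a `pv_protein`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein <- function(protein, path) {
  stopifnot(inherits(protein, "pv_protein"))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(protein_coords(protein))),
                   type = ifelse(protein$is_hetero, "HETATM", "ATOM"),
                   resno = protein$residue_number,
                   resid = protein$residue_name,
                   chain = protein$chain_id,
                   elety = protein$atom_name,
                   elesy = toupper(protein$element))
  invisible(path)
}

#' Read ligands from an SDF file
#'
#' One `pv_ligand` per SDF (V2000) block, in file order. Hydrogens are
#' stripped from the graph and conformer. When `smiles` is supplied, the
#' heavy-atom graph of each block must match the corresponding SMILES graph
#' (element/charge/bond-order isomorphism, stereo ignored).
#'
#' @param sdf_path path to an SDF file.
#' @param smiles optional character vector of SMILES, order-matched to the
#'   SDF blocks.
#' @return List of `pv_ligand`.
#' @export
read_ligands <- function(sdf_path, smiles = NULL) {
  if (!file.exists(sdf_path)) stop("file not found: ", sdf_path,
                                   call. = FALSE)
  # ChemmineR warns about blocks with no bonds (e.g. lone ions); those are
  # legitimate here and re-parsed by the fixed-width fallback
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(sdf_path)),
                     error = function(e) stop("cannot parse SDF '", sdf_path,
                                              "': ", conditionMessage(e),
                                              call. = FALSE))
  raw_blocks <- split_sdf_blocks(readLines(sdf_path, warn = FALSE))
  n_block <- length(sdfset)
  if (!is.null(smiles) && length(smiles) != n_block)
    stop("got ", length(smiles), " SMILES for ", n_block, " SDF blocks",
         call. = FALSE)
  ligs <- vector("list", n_block)
  for (k in seq_len(n_block)) {
    lig <- tryCatch(sdf_to_ligand(sdfset[[k]], raw_blocks[[k]]),
                    error = function(e) stop("SDF block ", k, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    if (!is.null(smiles)) {
      ref <- parse_smiles(smiles[k])
      if (!same_graph(lig, ref))
        stop("SDF block ", k, " does not match SMILES '", smiles[k], "'",
             call. = FALSE)
    }
    ligs[[k]] <- lig
  }
  ligs
}

split_sdf_blocks <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  purrr::map2(starts, ends, ~lines[.x:.y])
}

sdf_to_ligand <- function(sdf, raw_lines) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  counts <- raw_lines[4]
  n_declared <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (!is.na(n_declared) &&
      (is.null(dim(ab)) || nrow(ab) != n_declared || ncol(ab) < 3)) {
    # blocks with a single atom or no bonds confuse the ChemmineR reader;
    # fall back to parsing the fixed-width V2000 records directly
    parsed <- parse_v2000_block(raw_lines)
    ab <- parsed$ab; bb <- parsed$bb
  }
  elements <- gsub("_.*", "", rownames(ab))
  elements <- paste0(toupper(substr(elements, 1, 1)),
                     tolower(substr(elements, 2, 10)))
  n <- nrow(ab)
  charge <- integer(n)
  # ChemmineR drops `M  CHG` property lines; recover them from the raw block
  for (ln in grep("^M  CHG", raw_lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    cnt <- f[1]
    for (p in seq_len(cnt)) {
      charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  if (all(charge == 0)) {
    # old-style atom-block charge codes (column 5 of V2000): 1..7 map to
    # +3..-3 skipping the doublet code 4
    code_col <- ab[, 5]
    code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                  `7` = -3L)
    hit <- as.character(code_col) %in% names(code_map)
    charge[hit] <- code_map[as.character(code_col[hit])]
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    tibble::tibble(i = integer(), j = integer(), order = numeric())
  } else {
    tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = ifelse(bb[, 3] == 4, 1.5, as.numeric(bb[, 3])))
  }
  atoms <- tibble::tibble(element = elements, formal_charge = charge,
                          x = ab[, 1], y = ab[, 2], z = ab[, 3])
  if (any(bonds$i > n | bonds$j > n))
    stop("bond endpoints index invalid atoms")
  # strip hydrogens, remapping bond indices
  keep <- which(atoms$element != "H")
  if (length(keep) == 0) stop("no heavy atoms in block")
  remap <- match(seq_len(n), keep)
  bonds <- bonds[atoms$element[bonds$i] != "H" &
                   atoms$element[bonds$j] != "H", , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  lig <- ligand_mol(atoms[keep, ], bonds,
                    ligand_code = sdf_block_name(raw_lines))
  check_valences(lig)
  lig
}

parse_v2000_block <- function(raw_lines) {
  counts <- raw_lines[4]
  n <- as.integer(substr(counts, 1, 3))
  m <- as.integer(substr(counts, 4, 6))
  atom_lines <- raw_lines[4 + seq_len(n)]
  ab <- matrix(0, n, 5)
  els <- character(n)
  for (i in seq_len(n)) {
    ab[i, 1] <- as.numeric(substr(atom_lines[i], 1, 10))
    ab[i, 2] <- as.numeric(substr(atom_lines[i], 11, 20))
    ab[i, 3] <- as.numeric(substr(atom_lines[i], 21, 30))
    els[i] <- trimws(substr(atom_lines[i], 32, 34))
    chg <- suppressWarnings(as.integer(substr(atom_lines[i], 37, 39)))
    ab[i, 5] <- ifelse(is.na(chg), 0, chg)
  }
  rownames(ab) <- paste(els, seq_len(n), sep = "_")
  bb <- matrix(0, 0, 3)
  if (m > 0) {
    bond_lines <- raw_lines[4 + n + seq_len(m)]
    bb <- matrix(0, m, 3)
    for (b in seq_len(m)) {
      bb[b, 1] <- as.integer(substr(bond_lines[b], 1, 3))
      bb[b, 2] <- as.integer(substr(bond_lines[b], 4, 6))
      bb[b, 3] <- as.integer(substr(bond_lines[b], 7, 9))
    }
  }
  list(ab = ab, bb = bb)
}

sdf_block_name <- function(raw_lines) {
  nm <- trimws(raw_lines[1])
  if (nm == "") "LIG" else nm
}

# valence screen applied at parse time: catches corrupt blocks early
check_valences <- function(lig) {
  s <- atom_bond_order_sum(lig)
  for (i in seq_len(nrow(lig$atoms))) {
    el <- lig$atoms$element[i]
    maxv <- MAX_VALENCE[el]
    if (is.na(maxv)) next  # metals etc.: no ceiling enforced
    allowed <- maxv + max(0, lig$atoms$formal_charge[i])
    if (s[i] > allowed + 1e-6)
      stop("valence of atom ", i, " (", el, ") is ", s[i],
           ", exceeds allowed ", allowed)
  }
  invisible(lig)
}

#' Parse a SMILES string into a ligand graph
#'
#' Uses Open Babel (via ChemmineOB) to interpret the SMILES; the returned
#' ligand carries a flat placeholder conformer and is intended for graph
#' comparison only.
#'
#' @param smiles a single SMILES string.
#' @return A `pv_ligand`.
#' @export
parse_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES parsing requires the ChemmineOB package", call. = FALSE)
  sdfset <- ChemmineR::smiles2sdf(smiles)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  ChemmineR::write.SDF(sdfset, tmp)
  sdf_to_ligand(sdfset[[1]], readLines(tmp, warn = FALSE))
}

#' Write ligands to an SDF (V2000) file
#'
#' A plain formatter that preserves formal charges via `M  CHG` property
#' lines (which the ChemmineR writer does not emit).
#'
#' @param ligands a `pv_ligand` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ligands <- function(ligands, path) {
  if (inherits(ligands, "pv_ligand")) ligands <- list(ligands)
  out <- unlist(lapply(ligands, function(l) {
    n <- nrow(l$atoms); m <- nrow(l$bonds)
    lines <- c(l$ligand_code, "  poseval", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      l$atoms$x, l$atoms$y, l$atoms$z, l$atoms$element))
    if (m > 0) {
      ord <- ifelse(l$bonds$order == 1.5, 4, l$bonds$order)
      lines <- c(lines, sprintf("%3d%3d%3d  0", l$bonds$i, l$bonds$j, ord))
    }
    chg <- which(l$atoms$formal_charge != 0)
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste(sprintf("%4d%4d", grp, l$atoms$formal_charge[grp]),
              collapse = "")))
    }
    c(lines, "M  END", "$$$$")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Extract a method's prediction of the primary ligand
#'
#' Finds the predicted fragment whose molecular graph matches the reference
#' primary ligand; among several graph matches the one whose centroid is
#' nearest the reference primary wins. A missing match signals that the
#' prediction must be excluded from evaluation.
#'
#' @param pred a `pv_complex` (the prediction).
#' @param ref_primary the reference primary `pv_ligand`.
#' @return The matching predicted `pv_ligand`, with its `ligand_code` set to
#'   the reference code.
#' @export
extract_primary <- function(pred, ref_primary) {
  stopifnot(inherits(pred, "pv_complex"))
  if (length(pred$ligands) < 1) stop("prediction contains no ligands",
                                     call. = FALSE)
  hits <- which(vapply(pred$ligands, same_graph, TRUE, b = ref_primary))
  if (length(hits) == 0)
    rlang::abort(paste0("no predicted fragment matches the primary ligand '",
                        ref_primary$ligand_code, "'"),
                 class = "poseval_missing_primary")
  if (length(hits) > 1) {
    ref_ctr <- ligand_centroid(ref_primary)
    d <- vapply(hits, function(i)
      vnorm(ligand_centroid(pred$ligands[[i]]) - ref_ctr), 0)
    hits <- hits[which.min(d)]
  }
  out <- pred$ligands[[hits]]
  out$ligand_code <- ref_primary$ligand_code
  out
}
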