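#' Evaluation configuration
#'
#' @param rmsd_success RMSD success threshold in Angstrom (default 2).
#' @param centroid_success centroid-distance success threshold (default 1).
#' @param pocket_cutoff binding-pocket residue cutoff (default 10).
#' @param lddt a [lddt_params()] object.
#' @param plif a [geometric_criteria()] object.
#' @param validity a [validity_tolerances()] object.
#' @param symmetry symmetry-correct ligand RMSD (default `TRUE`)?
#' @param relaxed free-text label passed through to outputs (the toolkit
#'   itself performs no relaxation).
#' @return List of class `pv_config`.
#' @export
eval_config <- function(rmsd_success = 2, centroid_success = 1,
                        pocket_cutoff = 10, lddt = lddt_params(),
                        plif = geometric_criteria(),
                        validity = validity_tolerances(),
                        symmetry = TRUE, relaxed = "unrelaxed") {
  stopifnot(rmsd_success > 0, centroid_success > 0, pocket_cutoff > 0)
  structure(list(rmsd_success = rmsd_success,
                 centroid_success = centroid_success,
                 pocket_cutoff = pocket_cutoff, lddt = lddt, plif = plif,
                 validity = validity, symmetry = symmetry,
                 relaxed = relaxed),
            class = "pv_config")
}

result_row <- function(target_id, status = "scored", reason = NA_character_,
                       rmsd = NA_real_, crmsd = NA_real_,
                       lddt_pli = NA_real_, pb_valid = NA,
                       plif_emd = NA_real_, protein_ligand_clashes = NA_integer_,
                       inter_ligand_clashes = NA_integer_,
                       fragment = NA_character_) {
  tibble::tibble(target_id = target_id, status = status, reason = reason,
                 rmsd = rmsd, crmsd = crmsd, lddt_pli = lddt_pli,
                 pb_valid = pb_valid, plif_emd = plif_emd,
                 protein_ligand_clashes = protein_ligand_clashes,
                 inter_ligand_clashes = inter_ligand_clashes,
                 fragment = fragment)
}

#' Score a primary-ligand prediction against its reference
#'
#' Runs the full primary-ligand protocol: optimal chain mapping, reference
#' pocket definition (10 Angstrom rule), pocket C-alpha superposition of the
#' predicted protein (the transform is applied to the predicted ligands
#' too), primary-fragment extraction by graph match, symmetry-corrected RMSD
#' and centroid distance in the aligned frame, the validity verdict,
#' interface lDDT, and PLIF detection on both complexes with their
#' Wasserstein distance. Any scoring error marks the prediction excluded
#' (with the reason recorded) rather than raising.
#'
#' @param pred,ref `pv_complex` objects; `ref` must have exactly one
#'   primary ligand.
#' @param cfg an [eval_config()].
#' @param target_id label for the output row.
#' @return One-row tibble (`pv_result`): `target_id`, `status`, `reason`,
#'   `rmsd`, `crmsd`, `lddt_pli`, `pb_valid`, `plif_emd`, clash counts.
#' @export
evaluate_primary <- function(pred, ref, cfg = eval_config(),
                             target_id = "target") {
  out <- tryCatch({
    ref_prim <- primary_ligand(ref)
    mapping <- map_chains(pred$protein, ref$protein, NULL)
    pocket <- define_pocket(ref$protein, ref$ligands, cfg$pocket_cutoff)
    ali <- align_to_pocket(pred$protein, ref$protein, pocket, mapping)
    pred_aligned <- apply_transform(pred, ali$transform)
    prim <- extract_primary(pred_aligned, ref_prim)
    rmsd <- heavy_atom_rmsd(prim, ref_prim, symmetry = cfg$symmetry)
    crmsd <- centroid_rmsd(prim, ref_prim)
    val <- pb_valid(pred_aligned, cfg$validity, ref = ref)
    pli_params <- lddt_params(
      inclusion_radius = cfg$lddt$inclusion_radius,
      thresholds = cfg$lddt$thresholds,
      exclude_same_residue = cfg$lddt$exclude_same_residue,
      cross_only = TRUE, pli_radius = cfg$lddt$pli_radius)
    ldt <- tryCatch(
      lddt_pli(complex_pose(pred_aligned$protein, prim),
               complex_pose(ref$protein, ref_prim),
               pli_params, mapping,
               tibble::tibble(pred_index = 1L, ref_index = 1L)),
      poseval_undefined_score = function(e) NA_real_)
    u <- detect_plifs(complex_pose(pred_aligned$protein, prim), cfg$plif)
    v <- detect_plifs(complex_pose(ref$protein, ref_prim), cfg$plif)
    emd <- tryCatch(plif_emd(u, v),
                    poseval_empty_histograms = function(e) NA_real_)
    result_row(target_id, rmsd = rmsd, crmsd = crmsd, lddt_pli = ldt,
               pb_valid = val$pb_valid, plif_emd = emd,
               protein_ligand_clashes = val$protein_ligand_clashes,
               inter_ligand_clashes = val$inter_ligand_clashes)
  }, error = function(e) {
    result_row(target_id, status = "excluded",
               reason = conditionMessage(e))
  })
  class(out) <- c("pv_result", class(out))
  out
}

#' Score a multi-ligand prediction against its reference
#'
#' Pocket alignment is performed once; predicted fragments are assigned to
#' reference fragments by optimal within-class matching; each fragment gets
#' its own RMSD, centroid distance and interface lDDT row, while the
#' validity verdict and the inter-ligand clash count are calculated once
#' per complex. Unmatched reference fragments are recorded as unsuccessful
#' rows, not errors.
#'
#' @inheritParams evaluate_primary
#' @return Tibble (`pv_result`) with one row per reference fragment plus
#'   one `complex` row carrying `pb_valid` and the clash counts.
#' @export
evaluate_multi <- function(pred, ref, cfg = eval_config(),
                           target_id = "target") {
  out <- tryCatch({
    if (length(ref$ligands) < 2)
      stop("multi-ligand protocol requires >= 2 reference fragments",
           call. = FALSE)
    mapping <- map_chains(pred$protein, ref$protein, NULL)
    pocket <- define_pocket(ref$protein, ref$ligands, cfg$pocket_cutoff)
    ali <- align_to_pocket(pred$protein, ref$protein, pocket, mapping)
    pred_aligned <- apply_transform(pred, ali$transform)
    assign <- assign_fragments(pred_aligned$ligands, ref$ligands,
                               symmetry = cfg$symmetry)
    pli_params <- lddt_params(
      inclusion_radius = cfg$lddt$inclusion_radius,
      thresholds = cfg$lddt$thresholds,
      exclude_same_residue = cfg$lddt$exclude_same_residue,
      cross_only = TRUE, pli_radius = cfg$lddt$pli_radius)
    rows <- list()
    for (ri in seq_along(ref$ligands)) {
      hit <- which(assign$ref_index == ri)
      code <- ref$ligands[[ri]]$ligand_code
      frag_id <- paste0(code, "#", ri)
      if (length(hit) == 0) {
        rows[[length(rows) + 1]] <- result_row(
          target_id, status = "excluded", reason = "unmatched fragment",
          fragment = frag_id)
        next
      }
      pl <- pred_aligned$ligands[[assign$pred_index[hit]]]
      rl <- ref$ligands[[ri]]
      ldt <- tryCatch(
        lddt_pli(complex_pose(pred_aligned$protein, pl),
                 complex_pose(ref$protein, rl), pli_params, mapping,
                 tibble::tibble(pred_index = 1L, ref_index = 1L)),
        poseval_undefined_score = function(e) NA_real_)
      rows[[length(rows) + 1]] <- result_row(
        target_id, rmsd = assign$rmsd[hit],
        crmsd = centroid_rmsd(pl, rl), lddt_pli = ldt,
        fragment = frag_id)
    }
    val <- pb_valid(pred_aligned, cfg$validity, ref = ref)
    u <- detect_plifs(pred_aligned, cfg$plif)
    v <- detect_plifs(ref, cfg$plif)
    emd <- tryCatch(plif_emd(u, v),
                    poseval_empty_histograms = function(e) NA_real_)
    rows[[length(rows) + 1]] <- result_row(
      target_id, pb_valid = val$pb_valid, plif_emd = emd,
      protein_ligand_clashes = val$protein_ligand_clashes,
      inter_ligand_clashes = val$inter_ligand_clashes,
      fragment = "complex")
    dplyr::bind_rows(rows)
  }, error = function(e) {
    result_row(target_id, status = "excluded", reason = conditionMessage(e),
               fragment = "complex")
  })
  class(out) <- c("pv_result", class(out))
  out
}

#' Evaluate a manifest of prediction/reference pairs
#'
#' The manifest is a data frame (or CSV path) with columns `target_id`,
#' `method`, `run`, `pred_protein`, `pred_ligands`, `ref_protein`,
#' `ref_ligands`, `primary_ligand_code`. Paths are resolved relative to
#' `base_dir`. Scoring failures become excluded rows, never errors.
#'
#' @param manifest data frame or CSV path.
#' @param cfg an [eval_config()].
#' @param base_dir directory against which relative paths resolve.
#' @param quiet suppress per-target progress lines on stderr?
#' @return Tibble of per-target results with `method` and `run` columns.
#' @export
evaluate_batch <- function(manifest, cfg = eval_config(), base_dir = ".",
                           quiet = FALSE) {
  if (is.character(manifest))
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  needed <- c("target_id", "method", "run", "pred_protein", "pred_ligands",
              "ref_protein", "ref_ligands", "primary_ligand_code")
  missing <- setdiff(needed, names(manifest))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    m <- manifest[r, ]
    res <- tryCatch({
      ref <- load_complex(file.path(base_dir, m$ref_protein),
                          file.path(base_dir, m$ref_ligands),
                          primary_code = m$primary_ligand_code)
      pred <- load_complex(file.path(base_dir, m$pred_protein),
                           file.path(base_dir, m$pred_ligands),
                           primary_code = m$primary_ligand_code)
      evaluate_primary(pred, ref, cfg, target_id = m$target_id)
    }, error = function(e)
      result_row(m$target_id, status = "excluded",
                 reason = conditionMessage(e)))
    res$method <- m$method; res$run <- m$run
    if (!quiet)
      message(sprintf("[%s/%s run %s] %s", m$method, m$target_id, m$run,
                      res$status[1]))
    rows[[r]] <- res
  }
  dplyr::bind_rows(rows)
}

#' Load a complex from a protein file plus an SDF
#'
#' @param protein_path PDB/mmCIF path.
#' @param ligand_path SDF path.
#' @param primary_code ligand code marking the primary ligand; defaults to
#'   the first SDF block.
#' @param smiles optional SMILES sidecar (character vector or path to a
#'   text file with one SMILES per line, order-matched to blocks).
#' @return A `pv_complex`.
#' @export
load_complex <- function(protein_path, ligand_path, primary_code = NULL,
                         smiles = NULL) {
  if (!is.null(smiles) && length(smiles) == 1 && file.exists(smiles))
    smiles <- readLines(smiles, warn = FALSE)
  protein <- read_protein(protein_path)
  ligands <- read_ligands(ligand_path, smiles = smiles)
  codes <- vapply(ligands, `[[`, "", "ligand_code")
  roles <- rep("fragment", length(ligands))
  idx <- if (!is.null(primary_code) && primary_code %in% codes)
    which(codes == primary_code)[1] else 1L
  roles[idx] <- "primary"
  complex_pose(protein, ligands, roles)
}
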