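#' Synthetic benchmark with planted success fractions
#'
#' Writes a reference complex per target and, for each synthetic "method"
#' profile, predictions in which exactly `round(success_fraction *
#' n_targets)` targets receive a sub-threshold pose. A successful pose is
#' the reference ligand translated by `success_shift` (default 0.5
#' Angstrom, inside both success thresholds) plus per-atom Gaussian jitter
#' of sd `noise`; a failed pose is translated by `failure_shift` (default
#' 6 Angstrom). Each prediction's protein is the reference protein under a
#' seeded global rigid motion, emulating a prediction frame that the pocket
#' alignment must recover; because the protein is otherwise exact, the
#' planted pose errors survive alignment unchanged and the realized success
#' rates equal the planted fractions exactly.
#'
#' @param seed integer seed governing all randomness.
#' @param n_targets number of complexes.
#' @param method_profiles list of lists with `name`, `success_fraction`,
#'   `noise` (Angstrom sd; keep well below the success margin).
#' @param dir output directory (created).
#' @param runs number of independent runs per method.
#' @param templates ligand templates cycled over targets.
#' @param n_residues pocket size per complex.
#' @return The manifest tibble (also written to `dir/manifest.csv`).
#' @export
make_benchmark <- function(seed, n_targets, method_profiles, dir,
                           runs = 1, success_shift = 0.5, failure_shift = 6,
                           templates = c("benzene", "ethanol", "acetate",
                                         "imidazole", "methylammonium"),
                           n_residues = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  templates <- rep_len(templates, n_targets)
  manifest <- list()
  refs <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    refs[[t]] <- make_toy_complex(sub_seed(seed, t, 10L),
                                  templates = templates[t],
                                  n_residues = n_residues)
    ref_p <- sprintf("ref_%03d_protein.pdb", t)
    ref_l <- sprintf("ref_%03d_ligands.sdf", t)
    write_protein(refs[[t]]$protein, file.path(dir, ref_p))
    write_ligands(refs[[t]]$ligands, file.path(dir, ref_l))
  }
  for (m in method_profiles) {
    k_success <- round(m$success_fraction * n_targets)
    for (run in seq_len(runs)) {
      for (t in seq_len(n_targets)) {
        s <- sub_seed(seed, t, 100L + 10L * run +
                        match(m$name, vapply(method_profiles, `[[`, "",
                                             "name")))
        shift <- if (t <= k_success) success_shift else failure_shift
        pred <- perturb_pose(refs[[t]], "translate", magnitude = shift,
                             seed = s)
        if (!is.null(m$noise) && m$noise > 0)
          pred <- perturb_pose(pred, "jitter", magnitude = m$noise,
                               seed = s + 1L)
        # emulate a predicted frame: global rigid motion of the whole pose
        tf <- withr::with_seed(sub_seed(s, 3L), rigid_transform(
          random_rotation(), stats::rnorm(3, sd = 8)))
        pred <- apply_transform(pred, tf)
        pred_p <- sprintf("%s_run%d_%03d_protein.pdb", m$name, run, t)
        pred_l <- sprintf("%s_run%d_%03d_ligands.sdf", m$name, run, t)
        write_protein(pred$protein, file.path(dir, pred_p))
        write_ligands(pred$ligands, file.path(dir, pred_l))
        manifest[[length(manifest) + 1]] <- tibble::tibble(
          target_id = sprintf("T%03d", t), method = m$name, run = run,
          pred_protein = pred_p, pred_ligands = pred_l,
          ref_protein = sprintf("ref_%03d_protein.pdb", t),
          ref_ligands = sprintf("ref_%03d_ligands.sdf", t),
          primary_ligand_code = refs[[t]]$ligands[[1]]$ligand_code)
      }
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}
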