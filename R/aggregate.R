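#' Aggregate per-target results into per-method summaries
#'
#' Success rates use the full target count as denominator, so excluded
#' predictions count as unsuccessful; excluded targets are dropped only
#' from mean-metric computations (PLIF-EMD, lDDT-PLI). Per-run rates are
#' averaged to mean and sample standard deviation across runs, and the
#' per-method mean PLIF-EMD values are min-max normalized into PLIF-WM
#' across the supplied method collection.
#'
#' @param results tibble from [evaluate_batch()] (or bound rows of
#'   [evaluate_primary()] results with `method` and `run` columns).
#' @param cfg an [eval_config()] supplying the success thresholds.
#' @param n_targets denominator per run; default the number of distinct
#'   targets seen per method and run.
#' @return A `pv_summary` tibble with one row per method: `n_targets`,
#'   `n_runs`, `rate_rmsd`, `rate_rmsd_sd`, `rate_centroid`,
#'   `rate_centroid_sd`, `rate_rmsd_pbvalid`, `rate_rmsd_pbvalid_sd`
#'   (percentages), `mean_plif_emd`, `mean_lddt_pli`, `plif_wm`.
#' @export
aggregate_runs <- function(results, cfg = eval_config(), n_targets = NULL) {
  stopifnot(all(c("method", "run") %in% names(results)))
  if (nrow(results) == 0) stop("no results to aggregate", call. = FALSE)
  frag <- results
  if ("fragment" %in% names(frag)) {
    # complex-level rows of the multi protocol carry no pose metrics
    frag <- frag[is.na(frag$fragment) | frag$fragment != "complex", ]
  }
  per_run <- frag |>
    dplyr::group_by(.data$method, .data$run) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      k_rmsd = sum(.data$status == "scored" & !is.na(.data$rmsd) &
                     .data$rmsd <= cfg$rmsd_success),
      k_centroid = sum(.data$status == "scored" & !is.na(.data$crmsd) &
                         .data$crmsd <= cfg$centroid_success),
      k_both = sum(.data$status == "scored" & !is.na(.data$rmsd) &
                     .data$rmsd <= cfg$rmsd_success &
                     !is.na(.data$pb_valid) & .data$pb_valid),
      .groups = "drop") |>
    dplyr::mutate(
      n = if (is.null(n_targets)) .data$n_obs else n_targets,
      rate_rmsd = 100 * .data$k_rmsd / .data$n,
      rate_centroid = 100 * .data$k_centroid / .data$n,
      rate_rmsd_pbvalid = 100 * .data$k_both / .data$n)
  means <- results |>
    dplyr::filter(.data$status == "scored") |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_plif_emd = mean(.data$plif_emd, na.rm = TRUE),
      mean_lddt_pli = mean(.data$lddt_pli, na.rm = TRUE),
      .groups = "drop")
  out <- per_run |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_targets = .data$n[1], n_runs = dplyr::n(),
      rate_rmsd_sd = if (dplyr::n() > 1) stats::sd(.data$rate_rmsd) else
        NA_real_,
      rate_rmsd = mean(.data$rate_rmsd),
      rate_centroid_sd = if (dplyr::n() > 1)
        stats::sd(.data$rate_centroid) else NA_real_,
      rate_centroid = mean(.data$rate_centroid),
      rate_rmsd_pbvalid_sd = if (dplyr::n() > 1)
        stats::sd(.data$rate_rmsd_pbvalid) else NA_real_,
      rate_rmsd_pbvalid = mean(.data$rate_rmsd_pbvalid),
      .groups = "drop") |>
    dplyr::left_join(means, by = "method") |>
    dplyr::relocate("method", "n_targets", "n_runs", "rate_rmsd",
                    "rate_rmsd_sd", "rate_centroid", "rate_centroid_sd",
                    "rate_rmsd_pbvalid", "rate_rmsd_pbvalid_sd")
  wm <- plif_wm(setNames(out$mean_plif_emd, out$method))
  out$plif_wm <- unname(wm[out$method])
  class(out) <- c("pv_summary", class(out))
  out
}

#' Aggregate pre-computed per-run success rates
#'
#' Convenience for combining externally tabulated per-run rates: returns
#' mean and sample standard deviation per method.
#'
#' @param rates tibble with columns `method`, `run`, `rate`.
#' @return Tibble with `method`, `mean_rate`, `sd_rate`.
#' @export
summarise_run_rates <- function(rates) {
  rates |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     sd_rate = if (dplyr::n() > 1) stats::sd(.data$rate)
                       else NA_real_,
                     .groups = "drop")
}
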