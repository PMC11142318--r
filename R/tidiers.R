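#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fingerprint histogram
#'
#' @param x a `pv_plif`.
#' @param ... unused.
#' @return The histogram as a plain tibble with a `fraction` column.
#' @method tidy pv_plif
#' @export
tidy.pv_plif <- function(x, ...) {
  out <- as_plain_tibble(x)
  out$fraction <- if (nrow(out) > 0) out$count / sum(out$count) else numeric()
  out
}

#' One-row overview of a validity report
#'
#' @param x a `pv_validity` from [pb_valid()].
#' @param ... unused.
#' @return One-row tibble of the flags and clash counts.
#' @method glance pv_validity
#' @export
glance.pv_validity <- function(x, ...) {
  keep <- setdiff(names(x), "violations")
  tibble::as_tibble(x[keep])
}

#' Tidy the violation records of a validity report
#'
#' @param x a `pv_validity`.
#' @param ... unused.
#' @return Tibble with one row per violation.
#' @method tidy pv_validity
#' @export
tidy.pv_validity <- function(x, ...) x$violations

#' One-row overview of a method summary table
#'
#' @param x a `pv_summary` from [aggregate_runs()].
#' @param ... unused.
#' @return Tibble with methods ranked by the combined accuracy+validity
#'   rate.
#' @method glance pv_summary
#' @export
glance.pv_summary <- function(x, ...) {
  as_plain_tibble(x) |>
    dplyr::arrange(dplyr::desc(.data$rate_rmsd_pbvalid))
}

#' Bar-chart of per-method success rates
#'
#' @param object a `pv_summary`.
#' @param ... unused.
#' @return A ggplot object: grouped bars of the three success rates with
#'   inter-run sd error bars, PLIF-WM annotated.
#' @method autoplot pv_summary
#' @export
autoplot.pv_summary <- function(object, ...) {
  long <- as_plain_tibble(object) |>
    tidyr::pivot_longer(
      cols = c("rate_rmsd", "rate_centroid", "rate_rmsd_pbvalid"),
      names_to = "metric", values_to = "rate") |>
    dplyr::mutate(sd = dplyr::case_when(
      .data$metric == "rate_rmsd" ~ .data$rate_rmsd_sd,
      .data$metric == "rate_centroid" ~ .data$rate_centroid_sd,
      TRUE ~ .data$rate_rmsd_pbvalid_sd),
      metric = factor(.data$metric,
                      levels = c("rate_rmsd", "rate_centroid",
                                 "rate_rmsd_pbvalid"),
                      labels = c("RMSD ≤ 2 Å",
                                 "cRMSD ≤ 1 Å",
                                 "RMSD ≤ 2 Å & PB-Valid")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$rate,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate - .data$sd,
                   ymax = .data$rate + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "success rate (%)", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Fingerprint histogram plot
#'
#' @param object a `pv_plif`.
#' @param ... unused.
#' @return A ggplot object: counts per interaction tuple, faceted by
#'   residue.
#' @method autoplot pv_plif
#' @export
autoplot.pv_plif <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interaction, y = .data$count,
                                  fill = .data$ligand_code)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~residue_name) +
    ggplot2::labs(x = NULL, y = "count", fill = "ligand") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
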