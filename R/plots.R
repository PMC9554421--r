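# ggplot2 helpers for the standard result figures.

#' Histogram of the protein adequacy ratio
#'
#' Weighted histogram of intake-to-requirement ratios with the adequacy
#' threshold at 1 marked.
#'
#' @param run A `protdiv_run` from [run_pipeline()].
#' @param binwidth Histogram bin width on the ratio scale.
#' @return A ggplot object.
#' @export
plot_adequacy_histogram <- function(run, binwidth = 0.1) {
  ggplot2::ggplot(run$fig_adequacy_histogram,
                  ggplot2::aes(x = .data$protein_ratio,
                               weight = .data$weight)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "protein intake / requirement",
                  y = "weighted participants") +
    ggplot2::theme_minimal()
}

#' Protein intake by food source across diversity strata
#'
#' Stacked weighted mean protein (g/d) from each of the eight sources by
#' diversity stratum: rising animal protein and flat plant protein with
#' increasing diversity is the expected pattern.
#'
#' @param run A `protdiv_run`.
#' @return A ggplot object.
#' @export
plot_protein_by_source <- function(run) {
  dat <- dplyr::mutate(
    run$fig_protein_by_source,
    source = factor(.data$source, levels = protein_sources))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$diversity_stratum,
                                    y = .data$protein_g,
                                    fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "protein diversity stratum",
                  y = "mean protein (g/d)", fill = "source") +
    ggplot2::theme_minimal()
}

#' Per-EAA inadequacy prevalence by subgroup
#'
#' @param run A `protdiv_run`.
#' @param subgroup One of `"sex"`, `"age_group"`, `"wealth_tertile"`,
#'   `"education"`.
#' @return A ggplot object.
#' @export
plot_eaa_inadequacy <- function(run, subgroup = "sex") {
  dat <- dplyr::filter(run$fig_eaa_inadequacy,
                       .data$subgroup == .env$subgroup)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$eaa,
                                    y = .data$prevalence_inadequate,
                                    fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% with ratio < 1", fill = subgroup) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pipeline run
#'
#' @param object A `protdiv_run`.
#' @param type Which figure: `"adequacy"` (ratio histogram), `"sources"`
#'   (protein by source across strata) or `"eaa"` (per-EAA inadequacy).
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.protdiv_run <- function(object, type = c("adequacy", "sources",
                                                  "eaa"), ...) {
  type <- match.arg(type)
  switch(type,
         adequacy = plot_adequacy_histogram(object, ...),
         sources = plot_protein_by_source(object),
         eaa = plot_eaa_inadequacy(object, ...))
}
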