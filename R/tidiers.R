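# broom-style tidy()/glance() methods for fitted objects.

#' Turn model results into tidy tibbles
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.or_fit <- function(x, ...) {
  out <- x
  attr(out, "fit") <- NULL
  class(out) <- setdiff(class(out), "or_fit")
  out
}

#' @rdname tidiers
#' @export
glance.or_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble::tibble(
    null_deviance = fit$null.deviance,
    deviance = fit$deviance,
    df_residual = fit$df.residual,
    aic = fit$aic,
    n_levels = nrow(x) + 1L,
    any_separation = any(x$separation))
}

#' @rdname tidiers
#' @export
glance.protdiv_run <- function(x, ...) {
  wm <- function(v) weighted.mean(x$data[[v]], x$data$weight)
  tibble::tibble(
    n_analysed = x$manifest$n_analysed,
    n_excluded_missing = x$manifest$n_excluded_missing,
    mean_energy_kcal = wm("energy_kcal"),
    mean_protein_g = wm("protein_total"),
    mean_diversity = wm("diversity_score"),
    pct_protein_inadequate = 100 * wm("protein_inadequate"),
    pct_mar_inadequate = 100 * wm("mar_inadequate"))
}
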