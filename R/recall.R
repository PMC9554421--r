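# 24 h recall aggregation: recall rows -> per-participant daily intakes.

#' Aggregate 24 h recall entries into per-participant daily intakes
#'
#' Sums energy and protein contributions of every recall row against the
#' food composition table, splits protein across the eight protein-source
#' categories plus non-source foods, and converts per-source protein into
#' the nine essential amino acid intakes via per-source EAA profiles:
#' `eaa[k] = sum_s protein_by_source[s] * profile[s, k]` (mg/day).
#'
#' The study design this models uses a single recall day per participant;
#' if the recall table carries a `day` column, more than one distinct day
#' for a participant is an error rather than being averaged.
#'
#' @param recall Data frame with columns `participant_id`, `food_id`,
#'   `amount_g` (grams >= 0), optionally `day`.
#' @param fct An `fct_table` from [load_fct()]/[validate_fct()].
#' @param aa An `aa_profile` from [load_aa_profiles()]; defaults to the
#'   bundled profiles.
#' @param participant_ids Optional vector of ids that must appear in the
#'   output. Ids with no recall rows get an all-zero intake row and
#'   `empty_recall = TRUE` (with a warning).
#' @return A tibble, one row per participant: `participant_id`,
#'   `energy_kcal`, `protein_total`, `protein_<source>` for the eight
#'   sources, `protein_nonsource`, `protein_animal`, `protein_plant`, the
#'   nine `eaa_<name>` columns (mg/d), and `empty_recall`.
#' @examples
#' fct <- default_fct()
#' recall <- tibble::tibble(
#'   participant_id = "p1",
#'   food_id = c("C01", "L01", "F01"),
#'   amount_g = c(300, 50, 80)
#' )
#' aggregate_recalls(recall, fct)
#' @export
aggregate_recalls <- function(recall, fct, aa = default_aa_profiles(),
                              participant_ids = NULL) {
  stopifnot(all(c("participant_id", "food_id", "amount_g") %in%
                  names(recall)))
  recall <- tibble::as_tibble(recall)
  recall$participant_id <- as.character(recall$participant_id)
  recall$food_id <- as.character(recall$food_id)

  if ("day" %in% names(recall)) {
    ndays <- tapply(recall$day, recall$participant_id,
                    function(d) length(unique(d)))
    multi <- names(ndays)[ndays > 1L]
    if (length(multi) > 0L) {
      stop("multiple recall days for participant(s): ",
           paste(multi, collapse = ", "),
           "; one 24 h recall per participant is required", call. = FALSE)
    }
  }
  if (any(!is.finite(recall$amount_g) | recall$amount_g < 0)) {
    stop("amount_g must be finite and >= 0", call. = FALSE)
  }
  unresolved <- setdiff(unique(recall$food_id), fct$food_id)
  if (length(unresolved) > 0L) {
    stop("food_id not in food composition table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }

  joined <- dplyr::left_join(
    recall,
    dplyr::select(fct, "food_id", "energy_density", "protein_density",
                  "source"),
    by = "food_id"
  )
  joined <- dplyr::mutate(
    joined,
    energy_kcal = .data$energy_density * .data$amount_g / 100,
    protein_g   = .data$protein_density * .data$amount_g / 100
  )

  per_source <- joined |>
    dplyr::group_by(.data$participant_id, .data$source) |>
    dplyr::summarise(protein_g = sum(.data$protein_g), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "source", values_from = "protein_g",
                       values_fill = 0)
  for (s in c(protein_sources, non_source_label)) {
    if (!s %in% names(per_source)) per_source[[s]] <- 0
  }

  totals <- joined |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      energy_kcal = sum(.data$energy_kcal),
      protein_total = sum(.data$protein_g),
      .groups = "drop"
    )

  out <- dplyr::left_join(totals, per_source, by = "participant_id")
  out <- dplyr::rename(out, protein_nonsource = !!non_source_label)
  names(out)[match(protein_sources, names(out))] <-
    paste0("protein_", protein_sources)
  out <- dplyr::mutate(
    out,
    protein_animal = rowSums(
      dplyr::pick(dplyr::all_of(paste0("protein_", animal_sources)))),
    protein_plant = rowSums(
      dplyr::pick(dplyr::all_of(paste0("protein_", plant_sources)))),
    empty_recall = FALSE
  )

  # mg/day EAA = per-source protein (g) %*% profile (mg per g protein)
  prof <- as.matrix(aa[, eaa_names])
  rownames(prof) <- aa$source
  psrc <- as.matrix(out[, paste0("protein_", protein_sources)])
  eaa <- psrc %*% prof[protein_sources, , drop = FALSE]
  colnames(eaa) <- paste0("eaa_", eaa_names)
  out <- dplyr::bind_cols(out, tibble::as_tibble(eaa))

  if (!is.null(participant_ids)) {
    participant_ids <- as.character(participant_ids)
    missing_ids <- setdiff(participant_ids, out$participant_id)
    if (length(missing_ids) > 0L) {
      warning(length(missing_ids),
              " participant(s) had no recall rows; zero intakes assigned",
              call. = FALSE)
      zero <- tibble::tibble(participant_id = missing_ids)
      for (cn in setdiff(names(out), c("participant_id", "empty_recall"))) {
        zero[[cn]] <- 0
      }
      zero$empty_recall <- TRUE
      out <- dplyr::bind_rows(out, zero)
    }
    out <- out[match(participant_ids, out$participant_id), ]
  }

  col_order <- c("participant_id", "energy_kcal", "protein_total",
                 paste0("protein_", protein_sources), "protein_nonsource",
                 "protein_animal", "protein_plant",
                 paste0("eaa_", eaa_names), "empty_recall")
  out[, col_order]
}
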