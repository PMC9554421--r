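# Protein diversity score, protein/EAA adequacy ratios and MAR.

#' Adult essential amino acid requirements (mg/kg body weight/day)
#'
#' The 2007 FAO/WHO/UNU adult scoring pattern, shipped as data so users can
#' substitute alternative requirement sets. Also carries the adult protein
#' requirement of 0.83 g per kg body weight per day.
#'
#' @param path Optional CSV with columns `eaa`, `requirement_mg_per_kg`
#'   covering the nine EAAs; defaults to the bundled table.
#' @param protein_g_per_kg Protein requirement in g/kg/d (default 0.83).
#' @return A list with `eaa_mg_per_kg` (named numeric vector of length 9 in
#'   [eaa_names] order) and `protein_g_per_kg`.
#' @export
default_eaa_requirements <- function(path = NULL, protein_g_per_kg = 0.83) {
  if (is.null(path)) path <- protdiv_example("eaa_requirements.csv")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_eaa <- setdiff(eaa_names, x$eaa)
  if (length(missing_eaa) > 0L) {
    stop("missing EAA requirement(s): ",
         paste(missing_eaa, collapse = ", "), call. = FALSE)
  }
  req <- setNames(x$requirement_mg_per_kg[match(eaa_names, x$eaa)],
                  eaa_names)
  if (any(!is.finite(req) | req <= 0) || protein_g_per_kg <= 0) {
    stop("requirements must be positive", call. = FALSE)
  }
  list(eaa_mg_per_kg = req, protein_g_per_kg = protein_g_per_kg)
}

#' Daily protein requirement from body weight
#'
#' `requirement (g/d) = body_weight (kg) x 0.83 g/kg/d` for adults.
#'
#' @param body_weight Body weight in kg, > 0.
#' @param g_per_kg Requirement slope, default 0.83 g/kg/d.
#' @return Requirement in g/day.
#' @examples
#' protein_requirement(60) # 49.8
#' @export
protein_requirement <- function(body_weight, g_per_kg = 0.83) {
  if (any(!is.finite(body_weight) | body_weight <= 0)) {
    stop("body_weight must be positive", call. = FALSE)
  }
  g_per_kg * body_weight
}

#' Protein-source diversity score
#'
#' Counts how many of the eight protein food-source categories contributed
#' any protein (> 0 g/d) to a participant's recall, and assigns the score
#' to one of four ordered strata. The count is strictly threshold-based:
#' 0.001 g counts. Scores have a theoretical range of 1-8 for anyone who
#' ate at least one listed source; a score of 0 (protein only from
#' non-source foods) is retained, flagged, and placed in the lowest
#' stratum.
#'
#' @param intakes Intake tibble from [aggregate_recalls()] (needs the
#'   `protein_<source>` columns).
#' @param cutpoints Upper bounds of the first three strata, default
#'   `c(3, 4, 5)` giving strata 1-3, 4, 5, 6-8.
#' @return A tibble: `participant_id`, `diversity_score` (integer 0-8),
#'   `diversity_stratum` (ordered factor), `out_of_range` (TRUE when the
#'   score is 0).
#' @examples
#' fct <- default_fct()
#' recall <- tibble::tibble(participant_id = "p1",
#'                          food_id = c("C01", "L01", "F01"),
#'                          amount_g = c(300, 50, 80))
#' diversity_score(aggregate_recalls(recall, fct))
#' @export
diversity_score <- function(intakes, cutpoints = c(3, 4, 5)) {
  stopifnot(length(cutpoints) == 3L, !is.unsorted(cutpoints))
  src <- as.matrix(intakes[, paste0("protein_", protein_sources)])
  score <- as.integer(rowSums(src > 0))
  breaks <- c(-Inf, cutpoints, 8)
  labels <- stratum_labels(cutpoints)
  tibble::tibble(
    participant_id = intakes$participant_id,
    diversity_score = score,
    diversity_stratum = cut(score, breaks = breaks, labels = labels,
                            ordered_result = TRUE),
    out_of_range = score == 0L
  )
}

stratum_labels <- function(cutpoints) {
  lo <- c(1, cutpoints + 1)
  hi <- c(cutpoints, 8)
  ifelse(lo >= hi, as.character(hi), paste0(lo, "-", hi))
}

#' Protein and essential amino acid adequacy profile
#'
#' For each participant computes the protein adequacy ratio
#' (intake / (0.83 g x body weight)), the nine EAA adequacy ratios
#' (intake in mg/d over body-weight-scaled requirement in mg/d) and their
#' arithmetic mean, the mean adequacy ratio (MAR). Ratios are left
#' untruncated by default, so a ratio (and the MAR) may exceed 1; set
#' `truncate_ratios = TRUE` for the classical MAR that caps each ratio at 1
#' before averaging. Dichotomous flags use `>=` semantics against 1.0 (and
#' 0.7 for the secondary protein threshold).
#'
#' @param intakes Intake tibble from [aggregate_recalls()].
#' @param participants Data frame with `participant_id` and `body_weight`
#'   (kg).
#' @param requirements Requirement list from [default_eaa_requirements()].
#' @param truncate_ratios Cap each EAA ratio at 1 before averaging
#'   (default FALSE).
#' @return A tibble: `participant_id`, `protein_requirement_g`,
#'   `protein_ratio`, `protein_adequate_1`, `protein_adequate_07`, nine
#'   `ratio_<eaa>` columns, `mar`, `mar_adequate`.
#' @export
adequacy_profile <- function(intakes, participants,
                             requirements = default_eaa_requirements(),
                             truncate_ratios = FALSE) {
  stopifnot(all(c("participant_id", "body_weight") %in% names(participants)))
  bw <- participants$body_weight[
    match(intakes$participant_id, participants$participant_id)]
  if (any(is.na(bw))) {
    stop("body weight missing for some participants", call. = FALSE)
  }
  preq <- protein_requirement(bw, requirements$protein_g_per_kg)
  eaa_int <- as.matrix(intakes[, paste0("eaa_", eaa_names)])
  eaa_req <- outer(bw, requirements$eaa_mg_per_kg)  # mg/day
  ratios <- eaa_int / eaa_req
  if (truncate_ratios) ratios <- pmin(ratios, 1)
  colnames(ratios) <- paste0("ratio_", eaa_names)

  out <- tibble::tibble(
    participant_id = intakes$participant_id,
    protein_requirement_g = preq,
    protein_ratio = intakes$protein_total / preq,
    protein_adequate_1 = intakes$protein_total / preq >= 1,
    protein_adequate_07 = intakes$protein_total / preq >= 0.7
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(ratios))
  out$mar <- rowMeans(ratios)
  out$mar_adequate <- out$mar >= 1
  out
}
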