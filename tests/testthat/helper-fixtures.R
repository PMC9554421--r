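# Deterministic fixtures shared across test files.

fixture_fct <- function() default_fct()

# Ten-participant recall fixture spanning plant-only, animal-only, all-8
# and no-protein-source diets.
fixture_recall <- function() {
  tibble::tribble(
    ~participant_id, ~food_id, ~amount_g,
    "p01", "C01", 300, "p01", "L01", 50, "p01", "F01", 80,
    "p02", "C01", 250,
    "p03", "C02", 200, "p03", "E01", 55, "p03", "Y01", 100, "p03", "D02", 200,
    "p04", "C03", 120, "p04", "B01", 150, "p04", "P01", 60, "p04", "F02", 30,
    "p05", "N01", 20, "p05", "N05", 30,
    "p06", "C01", 200, "p06", "L02", 100, "p06", "E01", 50, "p06", "D01", 30,
    "p06", "B01", 50, "p06", "P01", 40, "p06", "Y02", 60, "p06", "F03", 70,
    "p07", "C01", 400, "p07", "L03", 40, "p07", "N03", 100,
    "p08", "F01", 100, "p08", "F03", 50, "p08", "Y01", 80,
    "p09", "C02", 150, "p09", "C03", 50, "p09", "L01", 80, "p09", "E01", 110,
    "p10", "C01", 350, "p10", "L01", 60, "p10", "F02", 25, "p10", "N02", 200,
    "p10", "N04", 120
  )
}

fixture_participants <- function() {
  tibble::tibble(
    participant_id = sprintf("p%02d", 1:10),
    body_weight = c(55, 60, 70, 80, 52, 65, 48, 90, 62, 58)
  )
}

# Expected scores for the fixture, frozen from an independent
# spreadsheet-style oracle (plain arithmetic over the bundled CSVs).
fixture_expected <- function() {
  tibble::tribble(
    ~participant_id, ~diversity_score, ~protein_requirement_g,
      ~protein_ratio, ~mar,
    "p01", 3L, 45.65, 0.771084337349, 1.63637275317,
    "p02", 1L, 49.80, 0.120481927711, 0.246666666667,
    "p03", 4L, 58.10, 0.854216867470, 1.90454301587,
    "p04", 4L, 66.40, 1.131325301200, 2.54098425214,
    "p05", 0L, 43.16, 0.000000000000, 0.00000000000,
    "p06", 8L, 53.95, 1.504170528270, 3.35651348236,
    "p07", 2L, 39.84, 0.585341365462, 1.02728062678,
    "p08", 2L, 74.70, 0.774297188755, 1.69751954416,
    "p09", 3L, 51.46, 0.811309755150, 1.78675212756,
    "p10", 3L, 48.14, 0.690693809722, 1.26671669614
  )
}

# Frozen per-EAA ratios for p01 from the same oracle.
fixture_expected_ratios_p01 <- function() {
  c(histidine = 1.77163636364, isoleucine = 1.46181818182,
    leucine = 1.31804195804, lysine = 1.54181818182,
    threonine = 1.72703030303, tryptophan = 1.92,
    valine = 1.28839160839, met_cys = 1.54763636364,
    phe_tyr = 2.15098181818)
}

# Random 2xk outcome/exposure data with all cells occupied.
random_or_table <- function(k = 2, n_min = 20, n_max = 80) {
  repeat {
    counts <- matrix(sample(n_min:n_max, 2 * k, replace = TRUE),
                     nrow = k)
    cases <- vapply(seq_len(k), function(i) {
      sample(1:(counts[i, 1] + counts[i, 2] - 1), 1)
    }, integer(1))
    tot <- rowSums(counts)
    if (all(cases >= 1) && all(cases < tot)) {
      return(list(tot = tot, cases = cases))
    }
  }
}
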