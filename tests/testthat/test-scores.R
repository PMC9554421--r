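test_that("diversity score counts sources with any intake", {
  fct <- default_fct()
  intakes <- aggregate_recalls(fixture_recall(), fct)
  ds <- diversity_score(intakes)
  exp <- fixture_expected()
  expect_equal(ds$diversity_score[match(exp$participant_id,
                                        ds$participant_id)],
               exp$diversity_score)
  # all-8 participant hits the maximum; no-source participant is flagged
  expect_equal(ds$diversity_score[ds$participant_id == "p06"], 8L)
  expect_true(ds$out_of_range[ds$participant_id == "p05"])
  expect_equal(as.character(ds$diversity_stratum[ds$participant_id == "p05"]),
               "1-3")
  # a trace amount still counts
  tiny <- aggregate_recalls(
    tibble::tibble(participant_id = "t", food_id = c("C01", "F01"),
                   amount_g = c(300, 0.005)), fct)
  expect_equal(diversity_score(tiny)$diversity_score, 2L)
})

test_that("protein requirement is 0.83 g per kg body weight", {
  expect_equal(protein_requirement(60), 49.8)
  expect_equal(protein_requirement(100), 83)
  expect_equal(protein_requirement(50), 41.5)
  expect_error(protein_requirement(0), "positive")
  expect_error(protein_requirement(-10), "positive")
})

test_that("scores match the independent spreadsheet oracle to 1e-9", {
  fct <- default_fct()
  intakes <- aggregate_recalls(fixture_recall(), fct)
  adeq <- adequacy_profile(intakes, fixture_participants())
  exp <- fixture_expected()
  m <- match(exp$participant_id, adeq$participant_id)
  expect_equal(adeq$protein_requirement_g[m], exp$protein_requirement_g,
               tolerance = 1e-9)
  expect_equal(adeq$protein_ratio[m], exp$protein_ratio, tolerance = 1e-9)
  expect_equal(adeq$mar[m], exp$mar, tolerance = 1e-9)
  p01 <- adeq[adeq$participant_id == "p01", paste0("ratio_", eaa_names)]
  expect_equal(unname(as.numeric(p01)),
               unname(fixture_expected_ratios_p01()), tolerance = 1e-9)
})

test_that("adequacy flags use >= semantics at 1 and 0.7", {
  req <- default_eaa_requirements()
  bw <- 60
  # intake exactly at requirement on protein and every EAA
  intake <- tibble::tibble(participant_id = "z",
                           protein_total = 0.83 * bw)
  for (k in eaa_names) {
    intake[[paste0("eaa_", k)]] <- req$eaa_mg_per_kg[[k]] * bw
  }
  prof <- adequacy_profile(intake,
                           tibble::tibble(participant_id = "z",
                                          body_weight = bw))
  expect_equal(prof$protein_ratio, 1)
  expect_equal(as.numeric(prof[, paste0("ratio_", eaa_names)]),
               rep(1, 9))
  expect_equal(prof$mar, 1)
  expect_true(prof$protein_adequate_1)
  expect_true(prof$mar_adequate)

  just_under <- intake
  just_under$protein_total <- 0.99 * 0.83 * bw
  p2 <- adequacy_profile(just_under,
                         tibble::tibble(participant_id = "z",
                                        body_weight = bw))
  expect_false(p2$protein_adequate_1)
  expect_true(p2$protein_adequate_07)
})

test_that("ratios are untruncated by default with a truncation switch", {
  fct <- default_fct()
  intakes <- aggregate_recalls(fixture_recall(), fct)
  parts <- fixture_participants()
  free <- adequacy_profile(intakes, parts)
  expect_true(any(as.matrix(free[, paste0("ratio_", eaa_names)]) > 1))
  expect_true(any(free$mar > 1))
  capped <- adequacy_profile(intakes, parts, truncate_ratios = TRUE)
  expect_true(all(as.matrix(capped[, paste0("ratio_", eaa_names)]) <= 1))
  expect_true(all(capped$mar <= free$mar))
})

test_that("adding a protein-source food never decreases any score", {
  set.seed(31)
  fct <- default_fct()
  parts <- tibble::tibble(participant_id = "m", body_weight = 60)
  src_foods <- fct$food_id[fct$source %in% protein_sources]
  for (i in 1:15) {
    nfoods <- sample(2:6, 1)
    base <- tibble::tibble(
      participant_id = "m",
      food_id = sample(fct$food_id, nfoods),
      amount_g = runif(nfoods, 10, 300))
    extra <- tibble::tibble(participant_id = "m",
                            food_id = sample(src_foods, 1),
                            amount_g = runif(1, 5, 200))
    i0 <- aggregate_recalls(base, fct)
    i1 <- aggregate_recalls(dplyr::bind_rows(base, extra), fct)
    expect_gte(diversity_score(i1)$diversity_score,
               diversity_score(i0)$diversity_score)
    a0 <- adequacy_profile(i0, parts)
    a1 <- adequacy_profile(i1, parts)
    expect_gte(a1$protein_ratio, a0$protein_ratio)
    expect_gte(a1$mar, a0$mar)
    expect_true(all(as.numeric(a1[, paste0("ratio_", eaa_names)]) >=
                      as.numeric(a0[, paste0("ratio_", eaa_names)])))
  }
})

test_that("doubling all intakes doubles every adequacy ratio exactly", {
  fct <- default_fct()
  rec <- fixture_recall()
  parts <- fixture_participants()
  a1 <- adequacy_profile(aggregate_recalls(rec, fct), parts)
  rec2 <- dplyr::mutate(rec, amount_g = 2 * amount_g)
  a2 <- adequacy_profile(aggregate_recalls(rec2, fct), parts)
  expect_equal(a2$protein_ratio, 2 * a1$protein_ratio, tolerance = 1e-12)
  expect_equal(as.matrix(a2[, paste0("ratio_", eaa_names)]),
               2 * as.matrix(a1[, paste0("ratio_", eaa_names)]),
               tolerance = 1e-12)
  expect_equal(a2$mar, 2 * a1$mar, tolerance = 1e-12)
})
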