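# helper: asset table driven by a single latent factor
latent_asset_table <- function(n, w) {
  lev3 <- function(w, cuts, levs) levs[findInterval(w + rnorm(n, 0, 0.5),
                                                    cuts) + 1L]
  tibble::tibble(
    participant_id = sprintf("s%04d", seq_len(n)),
    wall = lev3(w, c(-0.8, 0.3), c("bamboo", "wood", "brick")),
    floor = lev3(w, c(-1, 0.5), c("earth", "cement", "tile")),
    toilet = lev3(w, c(-0.9, 0), c("none", "shared", "private")),
    electricity = lev3(w, c(-1.5), c("none", "grid")),
    cooking_fuel = lev3(w, c(-0.7, 0.4), c("wood", "kerosene", "lpg")),
    car = rbinom(n, 1, plogis(-1.5 + 2 * w)),
    bicycle = rbinom(n, 1, plogis(0.2 + 0.8 * w)),
    motorcycle = rbinom(n, 1, plogis(0.5 + 1.5 * w)),
    refrigerator = rbinom(n, 1, plogis(0 + 2 * w)),
    mobile_phone = rbinom(n, 1, plogis(1 + 1.5 * w)),
    landline = rbinom(n, 1, plogis(-1.8 + 1.5 * w)),
    television = rbinom(n, 1, plogis(1 + 2 * w)),
    radio = rbinom(n, 1, plogis(-0.3 + w))
  )
}

test_that("wealth index recovers a single dominant latent factor", {
  set.seed(41)
  n <- 800
  w <- rnorm(n)
  assets <- latent_asset_table(n, w)
  wi <- wealth_index(assets)
  expect_gt(cor(wi$wealth_score, w, method = "spearman"), 0.9)
  # car ownership must load positively (orientation convention)
  load <- attr(wi, "loadings")
  expect_gt(load["car", 1], 0)
})

test_that("identical asset rows get identical scores; tertiles are monotone", {
  set.seed(42)
  assets <- latent_asset_table(300, rnorm(300))
  assets[2, -1] <- assets[1, -1]
  wi <- wealth_index(assets)
  expect_equal(wi$wealth_score[1], wi$wealth_score[2], tolerance = 1e-12)
  expect_equal(wi$wealth_tertile[1], wi$wealth_tertile[2])

  # tertiles partition into near-thirds and are monotone in the score
  expect_true(all(abs(table(wi$wealth_tertile) - 100) <= 1))
  ord <- order(wi$wealth_score)
  expect_true(!is.unsorted(as.integer(wi$wealth_tertile[ord])))
})

test_that("degenerate and invalid asset tables are handled", {
  assets <- latent_asset_table(50, rnorm(50))
  expect_error(wealth_index(dplyr::select(assets, -"radio")),
               "missing asset")

  same <- assets[rep(1, 40), ]
  same$participant_id <- sprintf("d%02d", 1:40)
  expect_warning(expect_warning(wi <- wealth_index(same), "zero-variance"),
                 "no asset variation")
  expect_true(all(wi$wealth_tertile == "T2"))

  novar <- assets
  novar$radio <- 1
  expect_warning(wealth_index(novar), "zero-variance.*radio")
})

test_that("wealth score is invariant to one-hot relabeling up to sign", {
  set.seed(43)
  assets <- latent_asset_table(400, rnorm(400))
  relab <- assets
  relab$wall <- c(bamboo = "z_bamboo", wood = "a_wood",
                  brick = "m_brick")[relab$wall]
  s1 <- wealth_index(assets)$wealth_score
  s2 <- wealth_index(relab)$wealth_score
  expect_gt(abs(cor(s1, s2)), 1 - 1e-9)
})

test_that("urbanisation mapping follows the province rules", {
  expect_equal(urbanisation_class("Jakarta", "urban"), "urban")
  expect_equal(urbanisation_class("West Java", "urban"), "urban")
  expect_equal(urbanisation_class("Bali", "urban"), "urban")
  expect_equal(urbanisation_class("West Sumatra", "urban"), "suburban")
  expect_equal(urbanisation_class("South Sulawesi", "urban"), "suburban")
  expect_equal(urbanisation_class("Bali", "rural"), "rural")
  expect_equal(urbanisation_class("West Sumatra", "rural"), "rural")
  expect_error(urbanisation_class("Sabah", "urban"), "unknown province")
})

test_that("modernisation points sum the three component scores", {
  expect_equal(modernisation_index("T3", "urban", 1)$modernisation_points,
               150L)
  expect_equal(modernisation_index("T1", "rural", 6)$modernisation_points,
               20L)
  expect_equal(
    modernisation_index("T2", "suburban", 3)$modernisation_points, 90L)
  expect_error(modernisation_index("T1", "rural", -1), "n_children")

  # monotone in wealth and urbanisation, non-increasing in children
  pts <- function(...) modernisation_index(...)$modernisation_points
  expect_true(pts("T1", "rural", 0) <= pts("T2", "rural", 0))
  expect_true(pts("T2", "rural", 0) <= pts("T3", "rural", 0))
  expect_true(pts("T1", "rural", 0) <= pts("T1", "suburban", 0))
  expect_true(pts("T1", "suburban", 0) <= pts("T1", "urban", 0))
  expect_true(pts("T1", "urban", 0) >= pts("T1", "urban", 3))
  expect_true(pts("T1", "urban", 3) >= pts("T1", "urban", 5))
})
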