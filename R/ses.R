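# Socio-economic indices: asset wealth index (PCA + varimax), urbanisation
# class, point-scored modernisation index.

#' The thirteen asset and housing variables behind the wealth index
#'
#' Five categorical housing variables (wall and floor material, toilet
#' type, electricity source, cooking fuel) and eight 0/1 ownership
#' variables (car, bicycle, motorcycle, refrigerator, mobile phone, land
#' line, television, radio).
#'
#' @export
asset_variables <- c(
  "wall", "floor", "toilet", "electricity", "cooking_fuel",
  "car", "bicycle", "motorcycle", "refrigerator", "mobile_phone",
  "landline", "television", "radio"
)

asset_categorical <- c("wall", "floor", "toilet", "electricity",
                       "cooking_fuel")

#' Asset-based wealth index
#'
#' DHS-style wealth index from the thirteen asset/housing variables:
#' categorical variables are one-hot encoded, binary ownership kept 0/1,
#' all columns standardised; principal components with eigenvalue > 1 are
#' retained and varimax-rotated; the wealth score is the first rotated
#' factor's regression-method score, sign-oriented so that car ownership
#' loads positively. Scores are split into tertiles on the weighted
#' empirical distribution (T1 = least wealth), with ties broken by stable
#' row order.
#'
#' @param participants Data frame with `participant_id` and the thirteen
#'   [asset_variables] columns.
#' @param weights Optional positive sampling weights (default 1).
#' @return A tibble `participant_id`, `wealth_score`, `wealth_tertile`
#'   (ordered factor T1 < T2 < T3), with the rotated loading matrix in the
#'   `"loadings"` attribute and the share of variance explained by the
#'   retained factors in `"var_explained"`.
#' @export
wealth_index <- function(participants, weights = NULL) {
  missing_vars <- setdiff(c("participant_id", asset_variables),
                          names(participants))
  if (length(missing_vars) > 0L) {
    stop("missing asset variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  n <- nrow(participants)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))

  design <- one_hot_assets(participants)
  keep <- vapply(design, function(col) stats::var(col) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping zero-variance asset column(s): ",
            paste(names(design)[!keep], collapse = ", "), call. = FALSE)
  }
  design <- design[, keep, drop = FALSE]

  if (ncol(design) < 2L) {
    warning("no asset variation; degenerate wealth index (all T2)",
            call. = FALSE)
    return(structure(
      tibble::tibble(
        participant_id = as.character(participants$participant_id),
        wealth_score = 0,
        wealth_tertile = factor("T2", levels = c("T1", "T2", "T3"),
                                ordered = TRUE)),
      loadings = NULL, var_explained = NA_real_))
  }

  X <- as.matrix(design)
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pca$sdev^2
  k <- max(1L, sum(ev > 1))
  load <- pca$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pca$sdev[seq_len(k)], k)
  if (k >= 2L) {
    rot <- varimax(load)
    trans <- rot$rotmat
    load_rot <- load %*% trans
    # order rotated factors by explained variance, largest first
    ord <- order(colSums(load_rot^2), decreasing = TRUE)
    load_rot <- load_rot[, ord, drop = FALSE]
    trans <- trans[, ord, drop = FALSE]
  } else {
    load_rot <- load
    trans <- diag(1)
  }
  colnames(load_rot) <- paste0("factor", seq_len(k))

  # Regression-method factor scores. The one-hot design is rank deficient
  # (complete dummy sets), so the pseudo-inverse form via the PCA basis is
  # used: scores = Z V_k diag(1/sdev_k) T = pca$x_k diag(1/sdev_k) T.
  scores <- pca$x[, seq_len(k), drop = FALSE] %*%
    diag(1 / pca$sdev[seq_len(k)], k) %*% trans

  wscore <- scores[, 1]
  orient <- if ("car" %in% rownames(load_rot)) {
    sign(load_rot["car", 1])
  } else {
    sign(sum(load_rot[, 1]))
  }
  if (orient < 0) {
    wscore <- -wscore
    load_rot[, 1] <- -load_rot[, 1]
  }

  structure(
    tibble::tibble(
      participant_id = as.character(participants$participant_id),
      wealth_score = as.numeric(wscore),
      wealth_tertile = weighted_tertile(wscore, weights)),
    loadings = load_rot,
    var_explained = sum(ev[seq_len(k)]) / sum(ev))
}

one_hot_assets <- function(participants) {
  out <- list()
  for (v in asset_categorical) {
    col <- as.character(participants[[v]])
    for (lev in sort(unique(col))) {
      out[[paste0(v, "_", lev)]] <- as.numeric(col == lev)
    }
  }
  for (v in setdiff(asset_variables, asset_categorical)) {
    out[[v]] <- as.numeric(participants[[v]])
  }
  tibble::as_tibble(out)
}

# Weighted tertiles with stable-order tie breaking: order by value (then by
# original position), cut the cumulative weight at 1/3 and 2/3.
weighted_tertile <- function(x, w, labels = c("T1", "T2", "T3")) {
  ord <- order(x, seq_along(x))
  cw <- cumsum(w[ord]) / sum(w)
  grp <- integer(length(x))
  grp[ord] <- findInterval(cw, c(1 / 3, 2 / 3), left.open = TRUE) + 1L
  factor(labels[grp], levels = labels, ordered = TRUE)
}

study_provinces <- c("West Sumatra", "Jakarta", "West Java", "East Java",
                     "Bali", "South Sulawesi")
urban_provinces <- c("Jakarta", "West Java", "East Java", "Bali")
suburban_provinces <- c("West Sumatra", "South Sulawesi")

#' Urbanisation class from province and district density class
#'
#' Urban districts in the Java-island provinces (Jakarta, West Java, East
#' Java) and Bali are classed urban; urban districts in West Sumatra and
#' South Sulawesi are classed suburban; every other district is rural.
#'
#' @param province Province name, one of the six study provinces.
#' @param district_class `"urban"` or `"rural"` district designation.
#' @return Character vector in `{"urban", "suburban", "rural"}`.
#' @examples
#' urbanisation_class("Jakarta", "urban")      # "urban"
#' urbanisation_class("West Sumatra", "urban") # "suburban"
#' @export
urbanisation_class <- function(province, district_class) {
  bad <- setdiff(unique(province), study_provinces)
  if (length(bad) > 0L) {
    stop("unknown province: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::case_when(
    district_class == "urban" & province %in% urban_provinces ~ "urban",
    district_class == "urban" & province %in% suburban_provinces ~ "suburban",
    .default = "rural"
  )
}

#' Point-scored modernisation index
#'
#' Composite of wealth tertile (T1 = 10, T2 = 30, T3 = 50 points),
#' urbanisation (urban = 50, suburban = 30, rural = 10) and number of
#' children (0-2 = 50, 3-4 = 30, 5+ = 0); the index is the sum, ranging 20
#' to 150. The stratum is assigned by `banding` cut-points when supplied,
#' otherwise by weighted tertiles of the points.
#'
#' @param wealth_tertile Factor/character in T1/T2/T3.
#' @param urbanisation Character in urban/suburban/rural.
#' @param n_children Non-negative integer count of children.
#' @param weights Optional weights used for the default tertile banding.
#' @param banding Optional numeric cut-points (upper bounds of the first
#'   strata) overriding the tertile banding.
#' @return Tibble with `modernisation_points` (integer) and
#'   `modernisation_stratum` (ordered factor, low < medium < high).
#' @examples
#' modernisation_index("T3", "urban", 1)$modernisation_points  # 150
#' @export
modernisation_index <- function(wealth_tertile, urbanisation, n_children,
                                weights = NULL, banding = NULL) {
  if (any(n_children < 0)) stop("n_children must be >= 0", call. = FALSE)
  wt_pts <- c(T1 = 10, T2 = 30, T3 = 50)[as.character(wealth_tertile)]
  urb_pts <- c(urban = 50, suburban = 30, rural = 10)[
    as.character(urbanisation)]
  child_pts <- ifelse(n_children <= 2, 50, ifelse(n_children <= 4, 30, 0))
  if (any(is.na(wt_pts)) || any(is.na(urb_pts))) {
    stop("invalid wealth tertile or urbanisation label", call. = FALSE)
  }
  points <- as.integer(wt_pts + urb_pts + child_pts)
  if (is.null(weights)) weights <- rep(1, length(points))
  stratum <- if (is.null(banding)) {
    weighted_tertile(points, weights, labels = c("low", "medium", "high"))
  } else {
    cut(points, breaks = c(-Inf, banding, Inf),
        labels = c("low", "medium", "high")[seq_len(length(banding) + 1L)],
        ordered_result = TRUE)
  }
  tibble::tibble(modernisation_points = points,
                 modernisation_stratum = stratum)
}

#' Full socio-economic profile for a participant table
#'
#' Convenience wrapper computing the wealth index, urbanisation class and
#' modernisation index in one call.
#'
#' @param participants Data frame with `participant_id`, `province`,
#'   `district_class`, `n_children` and the thirteen [asset_variables].
#' @param weights Optional sampling weights.
#' @return Tibble: `participant_id`, `wealth_score`, `wealth_tertile`,
#'   `urbanisation`, `modernisation_points`, `modernisation_stratum`.
#' @export
ses_profile <- function(participants, weights = NULL) {
  wi <- wealth_index(participants, weights)
  urb <- urbanisation_class(participants$province,
                            participants$district_class)
  mod <- modernisation_index(wi$wealth_tertile, urb,
                             participants$n_children, weights)
  dplyr::bind_cols(wi, tibble::tibble(urbanisation = urb), mod)
}
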