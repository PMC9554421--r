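# Food composition table: loading, validation, per-food nutrient arithmetic.

#' Load and validate a food composition table
#'
#' Reads a delimited food composition table (FCT) with one row per food and
#' validates it against the package's contract: unique `food_id`, energy
#' density >= 0 kcal/100 g, protein density in \[0, 100\] g/100 g, and a
#' `source` drawn from the eight protein categories plus
#' `"non_protein_source"`. Meat types outside the closed set (e.g. goat,
#' mutton) can be folded into a category via `source_aliases`.
#'
#' @param path Path to a delimited text file with columns `food_id`, `name`,
#'   `energy_density` (kcal/100 g), `protein_density` (g/100 g), `source`,
#'   and optionally `food_group`.
#' @param source_aliases Named character vector mapping non-canonical source
#'   labels to canonical ones, e.g. `c(goat = "beef")`. Applied before
#'   validation.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with class `fct_table`, one row per food, canonical
#'   column order, and a `version` attribute (file name).
#' @examples
#' fct <- load_fct(protdiv_example("fct_synthetic.csv"))
#' nrow(fct)
#' @export
load_fct <- function(path, source_aliases = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) stop("empty table: ", path, call. = FALSE)
  validate_fct(raw, source_aliases = source_aliases,
               version = basename(path))
}

#' Validate an in-memory food composition table
#'
#' @param x Data frame with the columns described in [load_fct()].
#' @inheritParams load_fct
#' @param version Provenance string stored as an attribute.
#' @return A validated `fct_table` tibble.
#' @export
validate_fct <- function(x, source_aliases = NULL, version = "in-memory") {
  required <- c("food_id", "name", "energy_density", "protein_density",
                "source")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"food_group" %in% names(x)) x$food_group <- NA_character_
  x <- dplyr::mutate(
    x,
    food_id = as.character(.data$food_id),
    source  = as.character(.data$source)
  )
  if (!is.null(source_aliases)) {
    hit <- x$source %in% names(source_aliases)
    x$source[hit] <- unname(source_aliases[x$source[hit]])
  }

  dup <- x$food_id[duplicated(x$food_id)]
  if (length(dup) > 0L) {
    stop("duplicate food_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  allowed <- c(protein_sources, non_source_label)
  bad_src <- which(!x$source %in% allowed)
  if (length(bad_src) > 0L) {
    stop("unknown source label(s) on row(s) ",
         paste(bad_src, collapse = ", "), ": ",
         paste(unique(x$source[bad_src]), collapse = ", "), call. = FALSE)
  }
  bad_energy <- which(!is.finite(x$energy_density) | x$energy_density < 0)
  if (length(bad_energy) > 0L) {
    stop("energy_density out of range on row(s) ",
         paste(bad_energy, collapse = ", "), call. = FALSE)
  }
  bad_protein <- which(!is.finite(x$protein_density) |
                         x$protein_density < 0 | x$protein_density > 100)
  if (length(bad_protein) > 0L) {
    stop("protein_density out of [0, 100] on row(s) ",
         paste(bad_protein, collapse = ", "), call. = FALSE)
  }

  out <- dplyr::select(x, "food_id", "name", "food_group",
                       "energy_density", "protein_density", "source")
  attr(out, "version") <- version
  class(out) <- c("fct_table", class(out))
  out
}

#' Energy and protein contributed by an amount of a food
#'
#' Linear scaling of per-100 g densities: `energy = energy_density *
#' amount_g / 100` and likewise for protein. Vectorised over rows.
#'
#' @param items Data frame with columns `energy_density`, `protein_density`
#'   and `source` (e.g. rows of an `fct_table`).
#' @param amount_g Grams consumed, recycled against rows of `items`; must be
#'   >= 0.
#' @return Tibble with columns `energy_kcal`, `protein_g`, `source`.
#' @examples
#' fct <- load_fct(protdiv_example("fct_synthetic.csv"))
#' nutrient_contribution(fct[1, ], 200)
#' @export
nutrient_contribution <- function(items, amount_g) {
  if (any(!is.finite(amount_g) | amount_g < 0)) {
    stop("amount_g must be finite and >= 0", call. = FALSE)
  }
  tibble::tibble(
    energy_kcal = items$energy_density * amount_g / 100,
    protein_g   = items$protein_density * amount_g / 100,
    source      = items$source
  )
}

#' Load per-source essential amino acid profiles
#'
#' Reads a table of EAA concentrations (mg EAA per g protein) for each of
#' the eight protein sources. All eight sources must be present, every
#' entry must be >= 0 and each source's nine concentrations must sum to
#' <= 1000 mg/g (amino acids cannot exceed the protein they sit in).
#'
#' @param path CSV with column `source` plus the nine EAA columns in
#'   [eaa_names] order.
#' @return Tibble with class `aa_profile`: 8 rows, columns `source` +
#'   nine EAA columns.
#' @examples
#' aa <- load_aa_profiles(protdiv_example("eaa_profiles_synthetic.csv"))
#' @export
load_aa_profiles <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_aa_profiles(x)
}

#' @rdname load_aa_profiles
#' @param x Data frame to validate in place of a file.
#' @export
validate_aa_profiles <- function(x) {
  missing_cols <- setdiff(c("source", eaa_names), names(x))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[, c("source", eaa_names)]
  missing_src <- setdiff(protein_sources, x$source)
  if (length(missing_src) > 0L) {
    stop("missing source(s): ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  }
  x <- x[match(protein_sources, x$source), ]
  mat <- as.matrix(x[, eaa_names])
  if (any(!is.finite(mat) | mat < 0)) {
    stop("EAA concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(rowSums(mat) > 1000)) {
    stop("EAA concentrations for a source exceed 1000 mg per g protein",
         call. = FALSE)
  }
  class(x) <- c("aa_profile", class(x))
  x
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
protdiv_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "protdiv"))
  } else {
    system.file("extdata", file, package = "protdiv", mustWork = TRUE)
  }
}

#' Bundled miniature food composition table
#'
#' A synthetic, desk-scale FCT of Indonesian-style foods spanning all eight
#' protein sources plus non-protein foods. Densities are representative
#' values constructed for testing and simulation; this is not a published
#' national FCT.
#'
#' @return An `fct_table` tibble.
#' @export
default_fct <- function() {
  load_fct(protdiv_example("fct_synthetic.csv"))
}

#' Bundled per-source EAA profiles
#'
#' Representative (synthetic) mg-per-g-protein EAA concentrations for the
#' eight protein sources, constructed from typical published amino acid
#' compositions of rice, soy, egg, milk, beef, pork, chicken and fish
#' protein.
#'
#' @return An `aa_profile` tibble.
#' @export
default_aa_profiles <- function() {
  load_aa_profiles(protdiv_example("eaa_profiles_synthetic.csv"))
}
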