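#' Modelled habitat categories
#'
#' The nine habitat categories modelled by the selection analysis. Raw field
#' categories map onto these: `bare_soil` is folded into `bare_ground`, and
#' `other` is excluded from modelling. `cover` is an overlay (a quadrat cell
#' can be both, say, grass and cover), so per-site proportions across
#' categories need not sum to one.
#'
#' @return Character vector of the nine category names.
#' @export
habitat_categories <- function() {
  c("angiosperm", "grass", "leaf_litter", "moss", "rock",
    "water", "wood", "cover", "bare_ground")
}

# raw -> modelled category mapping; "other" maps to NA (excluded)
map_raw_category <- function(raw) {
  substrate <- c("angiosperm", "grass", "leaf_litter", "moss", "rock",
                 "water", "wood", "bare_ground")
  out <- ifelse(raw == "bare_soil", "bare_ground", raw)
  out[!out %in% substrate] <- NA_character_
  out
}

#' Construct a quadrat sample
#'
#' A quadrat is a 0.5 x 0.5 m sampling frame subdivided into a 5 x 5 grid of
#' 25 cells. Each cell records the set of raw habitat categories present
#' (at minimum `"other"`) and a flag for whether the cell offers immediate
#' cover (tall grass, wood, hiding places). Cover overlays the substrate
#' categories.
#'
#' @param site_id Site identifier.
#' @param cells List of 25 non-empty character vectors of raw categories.
#' @param cover Logical vector of length 25.
#' @param provenance `"random_site"` or `"lizard_site"`.
#' @return An object of class `quadrat_sample`.
#' @export
quadrat_sample <- function(site_id, cells, cover = rep(FALSE, 25),
                           provenance = c("random_site", "lizard_site")) {
  provenance <- match.arg(provenance)
  if (!is.list(cells) || length(cells) != 25L)
    stop("a quadrat must have exactly 25 cells, got ", length(cells))
  if (any(lengths(cells) == 0L))
    stop("every quadrat cell must contain at least one raw category (use \"other\")")
  stopifnot(is.logical(cover), length(cover) == 25L)
  structure(list(site_id = site_id, cells = cells, cover = cover,
                 provenance = provenance),
            class = "quadrat_sample")
}

#' Quadrat grid to per-category proportions
#'
#' Converts a 25-cell quadrat into per-category proportions: for each
#' modelled category, the number of cells containing that category divided
#' by 25. `bare_soil` cells count toward `bare_ground`; the `cover`
#' proportion is the fraction of cells whose cover flag is set. Because a
#' cell may hold several categories and cover overlays substrate, the nine
#' proportions need not sum to one.
#'
#' @param quadrat A [quadrat_sample()].
#' @param sex,parity Optional labels for lizard sites (`NA` for random
#'   sites).
#' @return A one-row data frame in the standard observation schema:
#'   `site_id`, `group_kind`, `sex`, `parity`, then one column per modelled
#'   category, each a multiple of 1/25.
#' @examples
#' q <- quadrat_sample("s1", rep(list("grass"), 25))
#' compute_proportions(q)$grass  # 1
#' @export
compute_proportions <- function(quadrat, sex = NA_character_, parity = NA_character_) {
  stopifnot(inherits(quadrat, "quadrat_sample"))
  cats <- habitat_categories()
  counts <- vapply(setdiff(cats, "cover"), function(cc) {
    sum(vapply(quadrat$cells,
               function(cell) cc %in% map_raw_category(cell), logical(1)))
  }, numeric(1))
  props <- c(counts, cover = sum(quadrat$cover)) / 25
  kind <- if (quadrat$provenance == "random_site") "random" else "lizard"
  out <- data.frame(site_id = quadrat$site_id, group_kind = kind,
                    sex = if (kind == "random") NA_character_ else sex,
                    parity = if (kind == "random") NA_character_ else parity,
                    stringsAsFactors = FALSE)
  out[cats] <- as.list(props[cats])
  out
}

#' Classify parity mode from an admixture membership value
#'
#' Individuals are genotyped and assigned a two-cluster admixture membership
#' `Q`. Membership values strictly between 0.1 and 0.9 mark the individual
#' as admixed (excluded from model fits); values at or beyond the thresholds
#' are classified as purely one parity mode or the other. By convention `q`
#' is membership in the oviparous cluster; set `oviparous_is_high = FALSE`
#' to flip the labelling.
#'
#' @param q Membership values in \[0, 1\] (vectorised).
#' @param oviparous_is_high If `TRUE` (default), `q >= 0.9` is oviparous and
#'   `q <= 0.1` viviparous; if `FALSE`, the labels swap.
#' @return Character vector over `"oviparous"`, `"viviparous"`, `"admixed"`.
#' @examples
#' classify_parity(c(0.05, 0.5, 0.95))
#' @export
classify_parity <- function(q, oviparous_is_high = TRUE) {
  if (any(is.na(q)) || any(q < 0 | q > 1))
    stop("admixture membership `q` must lie in [0, 1]")
  high <- if (oviparous_is_high) "oviparous" else "viviparous"
  low <- if (oviparous_is_high) "viviparous" else "oviparous"
  ifelse(q >= 0.9, high, ifelse(q <= 0.1, low, "admixed"))
}

obs_columns <- function() {
  c("site_id", "group_kind", "sex", "parity", habitat_categories())
}

#' Read and validate a site-observation table
#'
#' Reads the standard observations CSV (columns `site_id`, `group_kind`,
#' `sex`, `parity`, then the nine category proportions). Validation errors
#' name the offending row and column. Missing values are empty fields;
#' random sites must have empty `sex`/`parity`.
#'
#' @param path CSV file path.
#' @return A validated data frame of site observations.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site_id = "character", group_kind = "character",
                                       sex = "character", parity = "character"))
  missing_cols <- setdiff(obs_columns(), names(df))
  if (length(missing_cols))
    stop("observations file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[obs_columns()]
  for (col in c("sex", "parity"))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  for (col in habitat_categories())
    if (is.logical(df[[col]]) && all(is.na(df[[col]])))
      df[[col]] <- as.numeric(df[[col]])
  validate_observations(df)
  df
}

validate_observations <- function(df) {
  bad_kind <- which(!df$group_kind %in% c("random", "lizard"))
  if (length(bad_kind))
    stop("row ", bad_kind[1], ", column group_kind: must be 'random' or 'lizard', got '",
         df$group_kind[bad_kind[1]], "'")
  for (col in habitat_categories()) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop("column ", col, ": proportions must be numeric")
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop("row ", bad[1], ", column ", col, ": proportion ", v[bad[1]],
           " outside [0, 1]")
  }
  bad_random <- which(df$group_kind == "random" &
                        (!is.na(df$sex) | !is.na(df$parity)))
  if (length(bad_random))
    stop("row ", bad_random[1], ": random sites must not carry sex or parity labels")
  invisible(df)
}

#' Write a site-observation table
#'
#' Inverse of [read_observations()]: writes the standard CSV with empty
#' fields for missing values, so that a write/read round trip reproduces the
#' table exactly.
#'
#' @param observations Data frame in the observation schema.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_observations <- function(observations, path) {
  validate_observations(observations[, obs_columns(), drop = FALSE])
  utils::write.csv(observations[, obs_columns(), drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

lizard_columns <- function() {
  c("id", "sex", "parity", "svl_mm", "tl_mm", "mass_g",
    "pattern_anterior", "pattern_posterior", "admixture_q")
}

#' Read and validate a lizard-record table
#'
#' Reads per-individual records: sex, parity mode, morphometrics (snout-vent
#' length, tail length, mass), dorsal / basking-site / habitat colour as
#' either RGB channels (`dorsal_r`, `dorsal_g`, `dorsal_b`, ...) or HSL
#' triples (`dorsal_h`, `dorsal_s`, `dorsal_l`, ...), the by-eye pattern
#' category for the anterior and posterior body, and the admixture
#' membership `admixture_q`. RGB columns, when present, are converted to HSL
#' with [rgb_to_hsl()]; both representations are retained.
#'
#' Records with `parity == "admixed"` are flagged: they are excluded from
#' all model fits downstream.
#'
#' @param path CSV file path.
#' @return A validated data frame with HSL columns
#'   `<surface>_h`, `<surface>_s`, `<surface>_l` for each of `dorsal`,
#'   `basking`, `habitat` (missing surfaces stay `NA`).
#' @export
read_lizards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(lizard_columns(), names(df))
  if (length(missing_cols))
    stop("lizards file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (surface in c("dorsal", "basking", "habitat")) {
    rgb_cols <- paste0(surface, "_", c("r", "g", "b"))
    hsl_cols <- paste0(surface, "_", c("h", "s", "l"))
    if (all(rgb_cols %in% names(df))) {
      hsl <- rgb_to_hsl(df[[rgb_cols[1]]], df[[rgb_cols[2]]], df[[rgb_cols[3]]])
      for (k in 1:3) df[[hsl_cols[k]]] <- hsl[[c("h", "s", "l")[k]]]
    } else if (!all(hsl_cols %in% names(df))) {
      for (k in hsl_cols) df[[k]] <- NA_real_
    }
  }
  validate_lizards(df)
  df
}

#' Validate a lizard-record table
#'
#' Checks morphometrics are strictly positive, sex/parity/pattern labels are
#' from their vocabularies, and admixture memberships lie in \[0, 1\].
#' Errors name the offending row and column.
#'
#' @param df Lizard-record data frame.
#' @return The data frame, invisibly, if valid.
#' @export
validate_lizards <- function(df) {
  for (col in c("svl_mm", "tl_mm", "mass_g")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop("row ", bad[1], ", column ", col, ": must be strictly positive")
  }
  bad_sex <- which(!is.na(df$sex) & !df$sex %in% c("female", "male"))
  if (length(bad_sex))
    stop("row ", bad_sex[1], ", column sex: must be 'female' or 'male'")
  bad_par <- which(!is.na(df$parity) &
                     !df$parity %in% c("oviparous", "viviparous", "admixed"))
  if (length(bad_par))
    stop("row ", bad_par[1], ", column parity: unknown parity label '",
         df$parity[bad_par[1]], "'")
  badq <- which(!is.na(df$admixture_q) & (df$admixture_q < 0 | df$admixture_q > 1))
  if (length(badq))
    stop("row ", badq[1], ", column admixture_q: must lie in [0, 1]")
  pats <- c("reticulated", "intermediate", "linear")
  for (col in c("pattern_anterior", "pattern_posterior")) {
    bad <- which(!is.na(df[[col]]) & !df[[col]] %in% pats)
    if (length(bad))
      stop("row ", bad[1], ", column ", col, ": unknown pattern '",
           df[[col]][bad[1]], "'")
  }
  invisible(df)
}

#' Write a lizard-record table
#'
#' @param lizards Data frame of lizard records.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_lizards <- function(lizards, path) {
  validate_lizards(lizards)
  utils::write.csv(lizards, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a quadrat grid file
#'
#' Long-format grid file: columns `site_id`, `cell_index` (0-24),
#' `categories` (semicolon-separated raw categories), `cover_flag` (0/1),
#' and optionally `provenance`. Returns one [quadrat_sample()] per site.
#'
#' @param path CSV file path.
#' @return Named list of `quadrat_sample` objects.
#' @export
read_quadrats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "cell_index", "categories", "cover_flag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("quadrat file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  lapply(split(df, df$site_id), function(d) {
    d <- d[order(d$cell_index), ]
    if (nrow(d) != 25L || !identical(d$cell_index, 0:24))
      stop("site ", d$site_id[1], ": quadrat must have cell_index 0..24 exactly once each")
    prov <- if ("provenance" %in% names(d)) d$provenance[1] else "random_site"
    quadrat_sample(d$site_id[1],
                   cells = strsplit(d$categories, ";", fixed = TRUE),
                   cover = d$cover_flag == 1,
                   provenance = prov)
  })
}
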