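#' Habitat simulation scenario
#'
#' Describes a generative model for site observations: a grouping scheme,
#' per-group ZOIB parameters for each habitat category, and group sample
#' sizes. The generated data have exactly the structure the ZOIB ladder
#' assumes, so fits on them constitute parameter-recovery experiments.
#'
#' @param scheme A [model_scheme()]; its mean groups are the generating
#'   groups.
#' @param params Named list: one entry per habitat category, each itself a
#'   named list mapping every group label of `scheme` to a
#'   [zoib_params()].
#' @param n_per_group Named integer vector of sites per group (names =
#'   group labels of `scheme`).
#' @param discretize If `TRUE`, interior draws are snapped to the nearest
#'   k/25 with k in 1..24, mimicking 25-cell quadrat counting; atoms are
#'   never created or destroyed by snapping.
#' @param seed Integer seed; the generator is a pure function of the
#'   scenario including this seed.
#' @return An object of class `habitat_scenario`.
#' @export
habitat_scenario <- function(scheme, params, n_per_group, discretize = FALSE,
                             seed = 1) {
  stopifnot(inherits(scheme, "model_scheme"))
  labels <- scheme_group_labels(scheme$grouping)
  if (!all(names(n_per_group) %in% labels) || any(n_per_group < 1))
    stop("n_per_group must be named by the scheme's group labels, all >= 1")
  bad_cat <- setdiff(names(params), habitat_categories())
  if (length(bad_cat))
    stop("unknown habitat categories in params: ", paste(bad_cat, collapse = ", "))
  for (cat in names(params)) {
    missing_groups <- setdiff(names(n_per_group), names(params[[cat]]))
    if (length(missing_groups))
      stop("category '", cat, "' lacks parameters for group(s): ",
           paste(missing_groups, collapse = ", "))
    ok <- vapply(params[[cat]], inherits, logical(1), what = "zoib_params")
    if (!all(ok)) stop("category '", cat, "' has non-zoib_params entries")
  }
  structure(list(scheme = scheme, params = params,
                 n_per_group = n_per_group, discretize = isTRUE(discretize),
                 seed = as.integer(seed)),
            class = "habitat_scenario")
}

snap_to_grid <- function(y) {
  mid <- y > 0 & y < 1
  k <- pmin(pmax(round(y[mid] * 25), 1), 24)
  y[mid] <- k / 25
  y
}

group_label_attrs <- function(label) {
  # sex/parity implied by a group label; NA means "not fixed by the label"
  switch(label,
    random = list(kind = "random", sex = NA, parity = NA),
    lizard = list(kind = "lizard", sex = NA, parity = NA),
    female = list(kind = "lizard", sex = "female", parity = NA),
    male = list(kind = "lizard", sex = "male", parity = NA),
    oviparous = list(kind = "lizard", sex = NA, parity = "oviparous"),
    viviparous = list(kind = "lizard", sex = NA, parity = "viviparous"),
    oviparous_female = list(kind = "lizard", sex = "female", parity = "oviparous"),
    oviparous_male = list(kind = "lizard", sex = "male", parity = "oviparous"),
    viviparous_female = list(kind = "lizard", sex = "female", parity = "viviparous"),
    viviparous_male = list(kind = "lizard", sex = "male", parity = "viviparous"),
    all = list(kind = NA, sex = NA, parity = NA))
}

#' Generate site observations from a habitat scenario
#'
#' Draws each category's proportions from [rzoib()] with the group's
#' parameters. Attributes the generating group label does not fix are
#' filled in at random (sites under the `"all"` group of a null scheme are
#' split evenly between random and lizard provenance; sex and parity not
#' determined by the label are drawn 50/50), so the output supports fitting
#' every scheme in the ladder, not just the generating one.
#'
#' @param scenario A [habitat_scenario()].
#' @return Data frame in the observation schema; categories absent from the
#'   scenario are `NA`.
#' @export
generate_habitat_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "habitat_scenario"))
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(scenario$seed)
  rows <- list()
  for (label in names(scenario$n_per_group)) {
    n <- scenario$n_per_group[[label]]
    at <- group_label_attrs(label)
    kind <- if (is.na(at$kind))
      sample(rep_len(c("random", "lizard"), n)) else rep(at$kind, n)
    sex <- ifelse(kind == "random", NA_character_,
                  if (is.na(at$sex)) sample(c("female", "male"), n, replace = TRUE)
                  else rep(at$sex, n))
    parity <- ifelse(kind == "random", NA_character_,
                     if (is.na(at$parity)) sample(c("oviparous", "viviparous"), n, replace = TRUE)
                     else rep(at$parity, n))
    df <- data.frame(site_id = paste0(label, "_", seq_len(n)),
                     group_kind = kind, sex = sex, parity = parity,
                     stringsAsFactors = FALSE)
    for (cat in habitat_categories()) {
      if (cat %in% names(scenario$params)) {
        y <- rzoib(n, scenario$params[[cat]][[label]])
        if (scenario$discretize) y <- snap_to_grid(y)
        df[[cat]] <- y
      } else df[[cat]] <- NA_real_
    }
    rows[[label]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Named habitat scenario presets
#'
#' Two ready-made generative scenarios calibrated to the grouped posterior
#' means the field study reports:
#'
#' * `"grass-lizard"` - grass proportions differing between random sites
#'   (`mu = 0.70`) and lizard sites (`mu = 0.55`), `phi = 10`, atom mass
#'   `alpha = 0.25` with `gamma` fixed at 0 (no all-grass quadrats inflate
#'   to one), 200 sites per group.
#' * `"moss-parity"` - moss presence differing by parity mode: zero-mass
#'   probabilities `alpha` of 0.88 (random), 0.71 (oviparous) and 0.86
#'   (viviparous), interior means 0.20 / 0.30 / 0.20, `phi = 8`, 150 sites
#'   per group.
#'
#' @param name `"grass-lizard"` or `"moss-parity"`.
#' @param n_per_group Optional override of the per-group sample sizes
#'   (single number or named vector).
#' @param seed Integer seed.
#' @param discretize Passed to [habitat_scenario()].
#' @return A [habitat_scenario()].
#' @export
preset_scenario <- function(name = c("grass-lizard", "moss-parity"),
                            n_per_group = NULL, seed = 1, discretize = FALSE) {
  name <- match.arg(name)
  if (name == "grass-lizard") {
    scheme <- model_scheme("lizard", "shared")
    params <- list(grass = list(
      random = zoib_params(0.25, 0, 0.70, 10, "fixed_zero"),
      lizard = zoib_params(0.25, 0, 0.55, 10, "fixed_zero")))
    n_def <- c(random = 200L, lizard = 200L)
  } else {
    scheme <- model_scheme("parity", "shared")
    params <- list(moss = list(
      random = zoib_params(0.88, 0, 0.20, 8, "fixed_zero"),
      oviparous = zoib_params(0.71, 0, 0.30, 8, "fixed_zero"),
      viviparous = zoib_params(0.86, 0, 0.20, 8, "fixed_zero")))
    n_def <- c(random = 150L, oviparous = 150L, viviparous = 150L)
  }
  if (!is.null(n_per_group)) {
    if (is.null(names(n_per_group)))
      n_def[] <- as.integer(n_per_group)
    else n_def[names(n_per_group)] <- as.integer(n_per_group)
  }
  habitat_scenario(scheme, params, n_def, discretize = discretize, seed = seed)
}

#' Colour simulation scenario
#'
#' Generative model for per-lizard colour records. Habitat hue and
#' lightness are truncated normals; basking-site colour is a linear
#' response to habitat colour plus noise; dorsal colour responds linearly
#' to habitat hue and basking lightness, with additive parity/sex shifts.
#' Defaults are calibrated to the colour summaries the field study reports:
#' habitat hue mean 54.9 and sd 7.2 on range 33-69, a basking-on-habitat
#' hue slope of 0.39 with noise chosen to give R-squared near 0.33, a
#' dorsal-on-habitat hue slope of 0.21 (R-squared near 0.15), a
#' dorsal-on-basking lightness slope of -0.10, a two-thirds female sex
#' ratio, and pattern odds of reticulation increasing with male sex (log
#' odds 1.068) and body length (0.071 per mm).
#'
#' @param n Number of individuals (default 165, the study's
#'   both-surfaces sample).
#' @param habitat_hue_mean,habitat_hue_sd,habitat_hue_bounds Habitat hue
#'   distribution (degrees).
#' @param basking_hue_intercept,basking_hue_slope,basking_hue_noise_sd
#'   Basking hue response to habitat hue.
#' @param dorsal_hue_intercept,dorsal_hue_slope,dorsal_hue_noise_sd Dorsal
#'   hue response to habitat hue.
#' @param habitat_l_mean,habitat_l_sd,habitat_l_bounds Habitat lightness.
#' @param basking_l_intercept,basking_l_slope,basking_l_noise_sd Basking
#'   lightness response to habitat lightness.
#' @param dorsal_l_intercept,dorsal_l_slope,dorsal_l_noise_sd Dorsal
#'   lightness response to basking lightness (negative default slope:
#'   lizards bask on surfaces slightly darker than themselves).
#' @param viviparous_hue_shift,viviparous_l_shift Additive dorsal shifts
#'   for viviparous individuals.
#' @param p_female Probability an individual is female.
#' @param pattern_sex_logodds,pattern_svl_logodds Log-odds effects of male
#'   sex and SVL (per mm, centred) on reticulated patterning.
#' @param seed Integer seed.
#' @return An object of class `colour_scenario`.
#' @export
colour_scenario <- function(n = 165,
                            habitat_hue_mean = 54.9, habitat_hue_sd = 7.2,
                            habitat_hue_bounds = c(33, 69),
                            basking_hue_intercept = 25.9, basking_hue_slope = 0.39,
                            basking_hue_noise_sd = 4.0,
                            dorsal_hue_intercept = 25.3, dorsal_hue_slope = 0.21,
                            dorsal_hue_noise_sd = 3.6,
                            habitat_l_mean = 30.1, habitat_l_sd = 6.6,
                            habitat_l_bounds = c(17.3, 47.6),
                            basking_l_intercept = 26.9, basking_l_slope = 0.33,
                            basking_l_noise_sd = 5.0,
                            dorsal_l_intercept = 48.7, dorsal_l_slope = -0.10,
                            dorsal_l_noise_sd = 7.0,
                            viviparous_hue_shift = 1.5, viviparous_l_shift = -3.1,
                            p_female = 0.67,
                            pattern_sex_logodds = 1.068, pattern_svl_logodds = 0.071,
                            seed = 1) {
  stopifnot(n >= 1, habitat_hue_sd > 0, basking_hue_noise_sd >= 0,
            dorsal_hue_noise_sd >= 0, habitat_l_sd > 0,
            basking_l_noise_sd >= 0, dorsal_l_noise_sd >= 0,
            habitat_hue_bounds[1] < habitat_hue_bounds[2],
            habitat_l_bounds[1] < habitat_l_bounds[2],
            p_female > 0, p_female < 1)
  structure(as.list(environment()), class = "colour_scenario")
}

rtruncnorm <- function(n, mean, sd, bounds) {
  lo <- stats::pnorm(bounds[1], mean, sd)
  hi <- stats::pnorm(bounds[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate lizard records from a colour scenario
#'
#' @param scenario A [colour_scenario()].
#' @return Lizard-record data frame (HSL columns for dorsal, basking and
#'   habitat surfaces, morphometrics, pattern categories, parity and
#'   admixture membership) that passes [validate_lizards()].
#' @export
generate_colour_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "colour_scenario"))
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(scenario$seed)
  s <- scenario
  n <- s$n
  sex <- ifelse(stats::runif(n) < s$p_female, "female", "male")
  parity <- sample(c("oviparous", "viviparous"), n, replace = TRUE)
  viv <- as.numeric(parity == "viviparous")
  admixture_q <- ifelse(parity == "oviparous",
                        stats::runif(n, 0.9, 1), stats::runif(n, 0, 0.1))
  svl <- rtruncnorm(n, ifelse(sex == "female", 60, 55), 5, c(40, 80))
  tl <- pmax(1.6 * svl + stats::rnorm(n, 0, 6), 30)
  mass <- pmax(stats::rnorm(n, 3.5 + 0.05 * (svl - 58), 0.5), 0.8)

  habitat_h <- rtruncnorm(n, s$habitat_hue_mean, s$habitat_hue_sd, s$habitat_hue_bounds)
  basking_h <- s$basking_hue_intercept + s$basking_hue_slope * habitat_h +
    stats::rnorm(n, 0, s$basking_hue_noise_sd)
  dorsal_h <- s$dorsal_hue_intercept + s$dorsal_hue_slope * habitat_h +
    s$viviparous_hue_shift * viv + stats::rnorm(n, 0, s$dorsal_hue_noise_sd)
  habitat_l <- rtruncnorm(n, s$habitat_l_mean, s$habitat_l_sd, s$habitat_l_bounds)
  basking_l <- s$basking_l_intercept + s$basking_l_slope * habitat_l +
    stats::rnorm(n, 0, s$basking_l_noise_sd)
  dorsal_l <- s$dorsal_l_intercept + s$dorsal_l_slope * basking_l +
    s$viviparous_l_shift * viv + stats::rnorm(n, 0, s$dorsal_l_noise_sd)
  habitat_s <- rtruncnorm(n, 30, 8, c(5, 60))
  basking_s <- 10 + 0.5 * habitat_s + stats::rnorm(n, 0, 3)
  dorsal_s <- rtruncnorm(n, 45, 8, c(10, 90))

  p_ret <- stats::plogis(-1 + s$pattern_sex_logodds * (sex == "male") +
                           s$pattern_svl_logodds * (svl - mean(svl)))
  ret <- stats::runif(n) < p_ret
  other <- sample(c("intermediate", "linear"), n, replace = TRUE)
  pattern_anterior <- ifelse(ret, "reticulated", other)
  pattern_posterior <- ifelse(stats::runif(n) < 0.9, pattern_anterior,
                              sample(c("reticulated", "intermediate", "linear"),
                                     n, replace = TRUE))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  df <- data.frame(
    id = sprintf("liz%03d", seq_len(n)), sex = sex, parity = parity,
    svl_mm = svl, tl_mm = tl, mass_g = mass,
    pattern_anterior = pattern_anterior, pattern_posterior = pattern_posterior,
    admixture_q = admixture_q,
    dorsal_h = dorsal_h, dorsal_s = clamp(dorsal_s, 0, 100),
    dorsal_l = clamp(dorsal_l, 0, 100),
    basking_h = basking_h, basking_s = clamp(basking_s, 0, 100),
    basking_l = clamp(basking_l, 0, 100),
    habitat_h = habitat_h, habitat_s = clamp(habitat_s, 0, 100),
    habitat_l = clamp(habitat_l, 0, 100),
    stringsAsFactors = FALSE)
  validate_lizards(df)
  df
}
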