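#' Convert RGB channels to HSL
#'
#' Standard hue/saturation/lightness transform of 8-bit RGB: with
#' `M = max(r, g, b) / 255` and `m = min / 255`, lightness is
#' `50 * (M + m)`, saturation is `0` for greys and otherwise
#' `100 * (M - m) / (M + m)` when `l <= 50` or `100 * (M - m) / (2 - M - m)`
#' when `l > 50`, and hue follows the piecewise 60-degree sector formula.
#' Hue is undefined for greys and is reported as 0 with `grey = TRUE`.
#'
#' @param r,g,b Channel values in \[0, 255\] (vectorised).
#' @return Data frame with columns `h` (degrees, \[0, 360)), `s`, `l`
#'   (percent), and `grey`.
#' @examples
#' rgb_to_hsl(255, 0, 0)  # h = 0, s = 100, l = 50
#' @export
rgb_to_hsl <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255, na.rm = TRUE))
    stop("RGB channels must lie in [0, 255]")
  R <- r / 255; G <- g / 255; B <- b / 255
  M <- pmax(R, G, B); m <- pmin(R, G, B)
  C <- M - m
  l <- 50 * (M + m)
  s <- ifelse(C == 0, 0,
              ifelse(l <= 50, 100 * C / (M + m), 100 * C / (2 - M - m)))
  s <- pmin(pmax(s, 0), 100)  # guard float overshoot at full saturation
  hp <- ifelse(C == 0, 0,
        ifelse(M == R, ((G - B) / C) %% 6,
        ifelse(M == G, (B - R) / C + 2, (R - G) / C + 4)))
  h <- 60 * hp
  data.frame(h = h, s = s, l = l, grey = C == 0 & !is.na(C))
}

#' Convert HSL to RGB channels
#'
#' Inverse of [rgb_to_hsl()]; returns continuous channel values in
#' \[0, 255\] (not rounded to integers).
#'
#' @param h Hue in degrees.
#' @param s,l Saturation and lightness in percent.
#' @return Data frame with columns `r`, `g`, `b`.
#' @export
hsl_to_rgb <- function(h, s, l) {
  if (any(s < -1e-9 | s > 100 + 1e-9, na.rm = TRUE) ||
      any(l < -1e-9 | l > 100 + 1e-9, na.rm = TRUE))
    stop("saturation and lightness must lie in [0, 100]")
  s <- pmin(pmax(s, 0), 100)
  l <- pmin(pmax(l, 0), 100)
  h <- h %% 360
  S <- s / 100; L <- l / 100
  C <- (1 - abs(2 * L - 1)) * S
  X <- C * (1 - abs((h / 60) %% 2 - 1))
  mm <- L - C / 2
  sector <- floor(h / 60) %% 6
  r1 <- c(1, 2, 0, 0, 2, 1)  # 1 -> C, 2 -> X, 0 -> 0, indexed by sector
  g1 <- c(2, 1, 1, 2, 0, 0)
  b1 <- c(0, 0, 2, 1, 1, 2)
  pick <- function(code) ifelse(code == 1, C, ifelse(code == 2, X, 0))
  data.frame(r = 255 * (pick(r1[sector + 1]) + mm),
             g = 255 * (pick(g1[sector + 1]) + mm),
             b = 255 * (pick(b1[sector + 1]) + mm))
}

#' Ordinary least squares on a design matrix
#'
#' Least-squares fit of `response` on the columns of `design` (which should
#' include an intercept column of ones if one is wanted). Coefficients,
#' standard errors, t statistics and two-sided p-values come from the
#' standard linear-model machinery; R-squared is computed against the mean
#' of the response when the design spans an intercept, and against zero
#' otherwise.
#'
#' @param response Numeric vector.
#' @param design Numeric matrix with named columns, `nrow(design) ==
#'   length(response)`, full column rank.
#' @return An object of class `linear_fit`: a coefficient table
#'   (`estimate`, `se`, `statistic`, `p_value`), `df_residual`,
#'   `r_squared`, `n`, and `kind = "ols"`.
#' @export
fit_ols <- function(response, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  n <- length(response)
  stopifnot(nrow(design) == n, n > ncol(design))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(response ~ 0 + design)
  sm <- summary(fit)
  coef_tab <- data.frame(term = colnames(design),
                         estimate = unname(sm$coefficients[, 1]),
                         se = unname(sm$coefficients[, 2]),
                         statistic = unname(sm$coefficients[, 3]),
                         p_value = unname(sm$coefficients[, 4]),
                         stringsAsFactors = FALSE)
  rss <- sum(stats::residuals(fit)^2)
  has_intercept <- qr(cbind(design, 1))$rank == qrd$rank
  tss <- if (has_intercept) sum((response - mean(response))^2) else sum(response^2)
  structure(list(coefficients = coef_tab, df_residual = fit$df.residual,
                 r_squared = 1 - rss / tss, n = n, kind = "ols",
                 fitted = unname(stats::fitted(fit))),
            class = "linear_fit")
}

#' Logistic regression on a design matrix
#'
#' Binomial GLM with logit link, fitted by iteratively reweighted least
#' squares; per-coefficient Wald z statistics and two-sided p-values.
#' Complete or quasi-complete separation is flagged with a warning and a
#' `separation` flag on the result.
#'
#' @param response 0/1 vector.
#' @param design Numeric matrix with named columns (include an intercept
#'   column if wanted).
#' @return An object of class `linear_fit` with `kind = "logistic"`
#'   (`r_squared` is `NA`).
#' @export
fit_logistic <- function(response, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  stopifnot(all(response %in% c(0, 1)), nrow(design) == length(response),
            length(response) > ncol(design))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(response ~ 0 + design, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 15)) sep <- TRUE
  if (sep)
    warning("possible complete separation: some coefficients are effectively infinite")
  sm <- summary(fit)
  coef_tab <- data.frame(term = colnames(design),
                         estimate = unname(sm$coefficients[, 1]),
                         se = unname(sm$coefficients[, 2]),
                         statistic = unname(sm$coefficients[, 3]),
                         p_value = unname(sm$coefficients[, 4]),
                         stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, df_residual = fit$df.residual,
                 r_squared = NA_real_, n = length(response), kind = "logistic",
                 separation = sep),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (n = %d, residual df = %d%s)\n", x$kind, x$n, x$df_residual,
              if (!is.na(x$r_squared)) sprintf(", R^2 = %.3f", x$r_squared) else ""))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition:
#' `F = MS_between / MS_within` with `k - 1` and `n - k` degrees of
#' freedom. With two groups the F statistic equals the square of the
#' pooled-variance two-sample t statistic.
#'
#' @param values Numeric vector.
#' @param group_labels Group label per value (at least two distinct
#'   groups).
#' @return An object of class `anova_result`: `f_value`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
one_way_anova <- function(values, group_labels) {
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  group_labels <- factor(group_labels[keep])
  if (nlevels(group_labels) < 2)
    stop("one-way ANOVA needs at least two groups")
  if (length(values) <= nlevels(group_labels))
    stop("need more observations than groups")
  tab <- stats::anova(stats::lm(values ~ group_labels))
  structure(list(f_value = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 p_value = tab$`Pr(>F)`[1]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_value, x$p_value))
  invisible(x)
}

hue_linearity_check <- function(h, what) {
  h <- h[!is.na(h)]
  if (length(h) && any(h > 300 | h < 10))
    warning("hue values for ", what, " fall near the 0/360 wrap (",
            "min ", round(min(h), 1), ", max ", round(max(h), 1),
            "); hue is treated as a linear variable")
  invisible(h)
}

pattern_binary <- function(pattern, coding) {
  if (coding == "reticulated_vs_rest") {
    ifelse(is.na(pattern), NA_real_, as.numeric(pattern == "reticulated"))
  } else {  # reticulated_vs_linear: intermediate dropped
    ifelse(is.na(pattern) | pattern == "intermediate", NA_real_,
           as.numeric(pattern == "reticulated"))
  }
}

design_from <- function(df, terms) {
  X <- cbind(intercept = rep(1, nrow(df)))
  for (tm in terms) {
    v <- switch(tm,
                sex_male = as.numeric(df$sex == "male"),
                parity_viviparous = as.numeric(df$parity == "viviparous"),
                df[[tm]])
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

fit_on_complete <- function(df, response_col, terms, fitter) {
  cols <- c(response_col, vapply(terms, function(tm)
    switch(tm, sex_male = "sex", parity_viviparous = "parity", tm), character(1)))
  ok <- stats::complete.cases(df[, unique(cols), drop = FALSE])
  d <- df[ok, , drop = FALSE]
  min_n <- length(terms) + 2L
  if (nrow(d) < min_n)
    return(list(skipped = TRUE,
                reason = sprintf("only %d complete rows (need >= %d)", nrow(d), min_n)))
  fit <- fitter(d[[response_col]], design_from(d, terms))
  fit$n_used <- nrow(d)
  fit$n_dropped <- nrow(df) - nrow(d)
  fit
}

#' Colour and pattern model suite
#'
#' Fits the eight statistical models linking dorsal colouration (HSL),
#' dorsal patterning, morphometrics, and the colouration of the basking
#' site and surrounding microhabitat:
#'
#' * model 1 - dorsal H, S and L each regressed on parity mode, sex, body
#'   length (SVL) and mass (least squares);
#' * model 2 - dorsal patterning on sex, body length, parity and mass
#'   (logistic);
#' * model 3 - dorsal H and L across the three pattern categories
#'   (one-way ANOVA);
#' * model 4 - basking-site H, S and L each on the matching habitat
#'   channel (least squares);
#' * model 5 - dorsal H on basking H, and dorsal L on basking L, with and
#'   without sex as a covariate;
#' * model 6 - dorsal H on habitat H, with and without sex;
#' * models 7 and 8 - dorsal patterning on basking (7) or habitat (8)
#'   H and L (logistic).
#'
#' Individuals of admixed parity are excluded throughout; rows with missing
#' fields are dropped per model and the counts reported. Patterning enters
#' the logistic models as a binary outcome; the default coding is
#' reticulated versus the rest, with reticulated-versus-linear (dropping
#' intermediates) as the alternative. All p-values are raw (no
#' multiple-testing adjustment), matching the field practice this suite
#' mirrors.
#'
#' @param records Lizard-record data frame (see [read_lizards()]).
#' @param pattern_coding `"reticulated_vs_rest"` (default) or
#'   `"reticulated_vs_linear"`.
#' @param pattern_region Which body region's pattern category to use:
#'   `"anterior"` (default) or `"posterior"`.
#' @return A list keyed `model1` ... `model8`; entries are `linear_fit` /
#'   `anova_result` objects (sub-keyed by colour channel or variant) or a
#'   skip record with a reason.
#' @export
run_colour_models <- function(records,
                             pattern_coding = c("reticulated_vs_rest", "reticulated_vs_linear"),
                             pattern_region = c("anterior", "posterior")) {
  pattern_coding <- match.arg(pattern_coding)
  pattern_region <- match.arg(pattern_region)
  df <- records[is.na(records$parity) | records$parity != "admixed", , drop = FALSE]
  df$pattern <- df[[paste0("pattern_", pattern_region)]]
  df$pattern_bin <- pattern_binary(df$pattern, pattern_coding)
  for (col in c("dorsal_h", "basking_h", "habitat_h"))
    if (col %in% names(df)) hue_linearity_check(df[[col]], col)

  out <- list()
  morpho <- c("parity_viviparous", "sex_male", "svl_mm", "mass_g")
  out$model1 <- list(
    h = fit_on_complete(df, "dorsal_h", morpho, fit_ols),
    s = fit_on_complete(df, "dorsal_s", morpho, fit_ols),
    l = fit_on_complete(df, "dorsal_l", morpho, fit_ols))
  out$model2 <- fit_on_complete(df, "pattern_bin",
                                c("sex_male", "svl_mm", "parity_viviparous", "mass_g"),
                                fit_logistic)
  out$model3 <- list(
    h = tryCatch(one_way_anova(df$dorsal_h, df$pattern), error = function(e)
      list(skipped = TRUE, reason = conditionMessage(e))),
    l = tryCatch(one_way_anova(df$dorsal_l, df$pattern), error = function(e)
      list(skipped = TRUE, reason = conditionMessage(e))))
  out$model4 <- list(
    h = fit_on_complete(df, "basking_h", "habitat_h", fit_ols),
    s = fit_on_complete(df, "basking_s", "habitat_s", fit_ols),
    l = fit_on_complete(df, "basking_l", "habitat_l", fit_ols))
  out$model5 <- list(
    h = fit_on_complete(df, "dorsal_h", c("basking_h", "sex_male"), fit_ols),
    h_no_sex = fit_on_complete(df, "dorsal_h", "basking_h", fit_ols),
    l = fit_on_complete(df, "dorsal_l", c("basking_l", "sex_male"), fit_ols),
    l_no_sex = fit_on_complete(df, "dorsal_l", "basking_l", fit_ols))
  out$model6 <- list(
    h = fit_on_complete(df, "dorsal_h", c("habitat_h", "sex_male"), fit_ols),
    h_no_sex = fit_on_complete(df, "dorsal_h", "habitat_h", fit_ols))
  out$model7 <- fit_on_complete(df, "pattern_bin", c("basking_h", "basking_l"),
                                fit_logistic)
  out$model8 <- fit_on_complete(df, "pattern_bin", c("habitat_h", "habitat_l"),
                                fit_logistic)
  attr(out, "pattern_coding") <- pattern_coding
  attr(out, "pattern_region") <- pattern_region
  out
}
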