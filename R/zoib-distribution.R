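#' Zero-and-one-inflated beta (ZOIB) parameters
#'
#' Bundle of mixture parameters for one observation group. The ZOIB
#' distribution places an atom of probability `alpha * (1 - gamma)` at 0, an
#' atom of `alpha * gamma` at 1, and distributes the remaining `1 - alpha`
#' over the open interval (0, 1) as a beta distribution parameterised by its
#' mean `mu` and precision `phi` (shape parameters `mu * phi` and
#' `(1 - mu) * phi`).
#'
#' `gamma_fixed` records whether the one-given-atom probability `gamma` is a
#' free parameter or pinned by the data: when a response variable contains no
#' ones, `gamma` is fixed at 0 (all atom mass sits at zero); when it contains
#' no zeros, `gamma` is fixed at 1. `gamma` may equal exactly 0 or 1 only in
#' those fixed modes.
#'
#' @param alpha Mixture probability of the Bernoulli (atom) component, in
#'   (0, 1).
#' @param gamma Probability that an atom draw equals 1, in \[0, 1\].
#' @param mu Mean of the interior beta component, in (0, 1).
#' @param phi Precision of the interior beta component, > 0.
#' @param gamma_fixed One of `"free"`, `"fixed_zero"`, `"fixed_one"`.
#' @return An object of class `zoib_params`.
#' @examples
#' p <- zoib_params(alpha = 0.3, gamma = 0, mu = 0.6, phi = 8,
#'                  gamma_fixed = "fixed_zero")
#' zoib_mean(p)
#' @export
zoib_params <- function(alpha, gamma, mu, phi, gamma_fixed = c("free", "fixed_zero", "fixed_one")) {
  gamma_fixed <- match.arg(gamma_fixed)
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(gamma), length(gamma) == 1L,
            is.numeric(mu), length(mu) == 1L,
            is.numeric(phi), length(phi) == 1L)
  if (!(alpha > 0 && alpha < 1))
    stop("`alpha` must lie strictly in (0, 1), got ", alpha)
  if (gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1], got ", gamma)
  if ((gamma == 0 || gamma == 1) && gamma_fixed == "free")
    stop("`gamma` may equal 0 or 1 only when `gamma_fixed` is not \"free\"")
  if (gamma_fixed == "fixed_zero" && gamma != 0)
    stop("`gamma_fixed = \"fixed_zero\"` requires gamma == 0")
  if (gamma_fixed == "fixed_one" && gamma != 1)
    stop("`gamma_fixed = \"fixed_one\"` requires gamma == 1")
  if (!(mu > 0 && mu < 1))
    stop("`mu` must lie strictly in (0, 1), got ", mu)
  if (!(phi > 0))
    stop("`phi` must be positive, got ", phi)
  structure(list(alpha = alpha, gamma = gamma, mu = mu, phi = phi,
                 gamma_fixed = gamma_fixed),
            class = "zoib_params")
}

#' @export
print.zoib_params <- function(x, ...) {
  cat(sprintf("ZOIB parameters: alpha = %.4g, gamma = %.4g (%s), mu = %.4g, phi = %.4g\n",
              x$alpha, x$gamma, x$gamma_fixed, x$mu, x$phi))
  invisible(x)
}

#' Beta density in mean-precision parameterisation
#'
#' Density of the beta distribution with mean `mu` and precision `phi`,
#' i.e. shape parameters `a = mu * phi`, `b = (1 - mu) * phi`. This is the
#' interior component of the ZOIB mixture; the atoms at 0 and 1 are handled
#' by the mixture, so `y` must be strictly inside (0, 1).
#'
#' @param y Values strictly in (0, 1) (vectorised).
#' @param mu Beta mean in (0, 1).
#' @param phi Beta precision, > 0.
#' @param log If `TRUE` return the log density.
#' @return Density (or log density) values.
#' @examples
#' dbeta_mp(0.25, mu = 0.5, phi = 4)  # Beta(2, 2): 6 * 0.25 * 0.75
#' @export
dbeta_mp <- function(y, mu, phi, log = FALSE) {
  stopifnot(length(mu) == 1L, length(phi) == 1L)
  if (!(mu > 0 && mu < 1)) stop("`mu` must lie strictly in (0, 1)")
  if (!(phi > 0)) stop("`phi` must be positive")
  if (any(y <= 0 | y >= 1))
    stop("`y` must lie strictly in (0, 1); atoms at 0 and 1 belong to the mixture, not the beta component")
  stats::dbeta(y, shape1 = mu * phi, shape2 = (1 - mu) * phi, log = log)
}

#' ZOIB log density / log mass
#'
#' Evaluates the three-branch ZOIB log probability function:
#' `log(alpha * (1 - gamma))` at `y = 0`, `log(alpha * gamma)` at `y = 1`,
#' and `log((1 - alpha)) + log f(y; mu, phi)` for `0 < y < 1`, where `f` is
#' the mean-precision beta density. The two atoms and the interior integral
#' together carry total probability one.
#'
#' @param y Values in \[0, 1\] (vectorised). Atoms are recognised at exact
#'   floating-point 0 and 1 only.
#' @param params A [zoib_params()] object.
#' @return Log density/mass values; `-Inf` where an atom has zero
#'   probability (e.g. `y = 1` under `gamma_fixed = "fixed_zero"`).
#' @examples
#' p <- zoib_params(0.4, 0.25, 0.5, 2)
#' dzoib(c(0, 1, 0.5), p)  # log(0.3), log(0.1), log(0.6 * 1)
#' @export
dzoib <- function(y, params) {
  stopifnot(inherits(params, "zoib_params"))
  if (any(y < 0 | y > 1)) stop("`y` must lie in [0, 1]")
  out <- numeric(length(y))
  at0 <- y == 0
  at1 <- y == 1
  mid <- !at0 & !at1
  out[at0] <- log(params$alpha) + log1p(-params$gamma)
  out[at1] <- log(params$alpha) + log(params$gamma)
  if (any(mid))
    out[mid] <- log1p(-params$alpha) +
      dbeta_mp(y[mid], params$mu, params$phi, log = TRUE)
  out
}

#' Sample from the ZOIB distribution
#'
#' Draws i.i.d. values: with probability `alpha` an atom (1 with probability
#' `gamma`, else 0), otherwise a beta variate with mean `mu` and precision
#' `phi`.
#'
#' @param n Number of draws.
#' @param params A [zoib_params()] object.
#' @param seed Optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of length `n` with values in \[0, 1\].
#' @examples
#' y <- rzoib(10, zoib_params(0.3, 0.4, 0.5, 5), seed = 1)
#' mean(y == 0)
#' @export
rzoib <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "zoib_params"), n >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  atom <- stats::runif(n) < params$alpha
  one <- stats::runif(n) < params$gamma
  y <- stats::rbeta(n, params$mu * params$phi, (1 - params$mu) * params$phi)
  y[atom] <- as.numeric(one[atom])
  y
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' ZOIB expected value
#'
#' The mean of the mixture: `alpha * gamma + (1 - alpha) * mu`.
#'
#' @param params A [zoib_params()] object.
#' @return The expected value.
#' @export
zoib_mean <- function(params) {
  stopifnot(inherits(params, "zoib_params"))
  params$alpha * params$gamma + (1 - params$alpha) * params$mu
}
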