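# Visual pigment absorbance templates and oil droplet transmittance curves.
#
# The pigment template is the vitamin-A1 (rhodopsin-like) nomogram of
# Govardovskii et al. (2000): an alpha band parameterised only by lambda_max
# plus a Gaussian beta band whose position and width scale with lambda_max.
# Every lambda_max estimator in this package works by inverting this curve.

#' Shape constants of the A1 visual pigment template
#'
#' Returns the constants of the vitamin-A1 absorbance template (alpha band
#' plus beta band) as a single machine-readable table. All wavelength-like
#' quantities are in nanometres; the remaining constants are dimensionless.
#'
#' The alpha band is
#' \deqn{S_\alpha(\lambda) = 1 / [e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D]}
#' with \eqn{x = \lambda_{max}/\lambda} and
#' \eqn{a = a_0 + a_1 \exp(-(\lambda_{max}-300)^2/11940)}.
#' The beta band is a Gaussian
#' \eqn{S_\beta(\lambda) = A_\beta \exp(-((\lambda-\lambda_{m\beta})/b_\beta)^2)}
#' with \eqn{\lambda_{m\beta} = 189 + 0.315\,\lambda_{max}} and
#' \eqn{b_\beta = -40.5 + 0.195\,\lambda_{max}}.
#'
#' @return A data.frame with columns `constant`, `band`, `value`, `unit`.
#' @seealso [pigment_absorbance()], [write_template_constants()]
#' @export
govardovskii_constants <- function() {
  data.frame(
    constant = c("A", "B", "C", "D", "b", "c", "a0", "a1", "a_width",
                 "A_beta", "beta_pos_intercept", "beta_pos_slope",
                 "beta_width_intercept", "beta_width_slope"),
    band = c(rep("alpha", 9L), rep("beta", 5L)),
    value = c(69.7, 28, -14.9, 0.674, 0.922, 1.104, 0.8795, 0.0459, 11940,
              0.26, 189, 0.315, -40.5, 0.195),
    unit = c(rep("dimensionless", 8L), "nm^2",
             "dimensionless", "nm", "dimensionless", "nm", "dimensionless"),
    stringsAsFactors = FALSE
  )
}

#' Export the template constants for audit
#'
#' Writes [govardovskii_constants()] as tab-delimited text so the exact
#' constants in use can be inspected without reading source code.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_template_constants <- function(path) {
  utils::write.table(govardovskii_constants(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Unnormalised template (alpha + optional beta), vectorised over both
# arguments with recycling. No argument validation: internal hot path.
.gov_raw <- function(lambda_max, wavelength, beta = TRUE) {
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    bwb <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((wavelength - lmb) / bwb)^2)
  }
  s
}

# Cache of peak-height interpolators so pigment_absorbance() can renormalise
# to max 1 without an inner optimisation on every call.
.tmpl_cache <- new.env(parent = emptyenv())

.gov_norm_fun <- function(beta) {
  key <- if (beta) "norm_beta" else "norm_alpha"
  f <- .tmpl_cache[[key]]
  if (!is.null(f)) return(f)
  lm_grid <- seq(295, 705, by = 0.25)
  off <- seq(-15, 15, by = 0.05)
  peak <- vapply(lm_grid, function(lm) {
    y <- .gov_raw(lm, lm + off, beta = beta)
    i <- which.max(y)
    # quadratic refinement around the grid argmax
    if (i > 1L && i < length(y)) {
      d <- (y[i + 1L] - y[i - 1L]) / 2
      h <- y[i + 1L] - 2 * y[i] + y[i - 1L]
      if (h < 0) return(y[i] - d^2 / (2 * h))
    }
    y[i]
  }, numeric(1))
  f <- stats::splinefun(lm_grid, peak, method = "fmm")
  .tmpl_cache[[key]] <- f
  f
}

# Normalised template, internal (no range validation). Vectorised.
.gov_template <- function(lambda_max, wavelength, beta = TRUE) {
  .gov_raw(lambda_max, wavelength, beta = beta) /
    .gov_norm_fun(beta)(lambda_max)
}

#' Fractional absorbance of a visual pigment
#'
#' Evaluates the A1 absorbance template for a pigment with the given peak
#' wavelength, renormalised so the curve maximum equals 1.
#'
#' @param lambda_max Peak absorbance wavelength(s), nm; must lie in
#'   \[350, 620\].
#' @param wavelength Evaluation wavelength(s), nm; must lie in \[330, 800\].
#'   Recycled against `lambda_max`.
#' @param beta Include the beta band (default) or evaluate the alpha band
#'   alone.
#' @return Fractional absorbance in \[0, 1\].
#' @examples
#' pigment_absorbance(500, 500)   # 1 at the peak
#' pigment_absorbance(500, 600)   # long-limb falloff
#' @export
pigment_absorbance <- function(lambda_max, wavelength, beta = TRUE) {
  if (any(!is.finite(lambda_max)) || any(lambda_max < 350 | lambda_max > 620))
    stop("lambda_max must be finite and within [350, 620] nm", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(wavelength < 330 | wavelength > 800))
    stop("wavelength must be finite and within [330, 800] nm", call. = FALSE)
  .gov_template(lambda_max, wavelength, beta = beta)
}

# Vectorised bracketed bisection solving template(lambda_max, wavelength) ==
# fraction on a monotone branch. `increasing` says whether the normalised
# template is increasing in lambda_max at the fixed wavelength (TRUE on the
# long limb, FALSE on the short limb).
.bisect_lambda_max <- function(fraction, wavelength, lo, hi,
                               increasing = TRUE, tol = 1e-3, beta = TRUE) {
  n <- length(fraction)
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  flo <- .gov_template(lo, wavelength, beta = beta) - fraction
  fhi <- .gov_template(hi, wavelength, beta = beta) - fraction
  ok <- if (increasing) flo < 0 & fhi > 0 else flo > 0 & fhi < 0
  lo[!ok] <- NA_real_
  hi[!ok] <- NA_real_
  n_iter <- ceiling(log2(max(hi - lo, tol, na.rm = TRUE) / tol)) + 2L
  for (k in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    fm <- .gov_template(mid, wavelength, beta = beta) - fraction
    up <- if (increasing) fm < 0 else fm > 0
    up[is.na(up)] <- FALSE
    lo[up] <- mid[up]
    dn <- !up & !is.na(mid)
    hi[dn] <- mid[dn]
  }
  (lo + hi) / 2
}

#' Recover lambda_max from a long-limb absorbance fraction
#'
#' Given a fractional absorbance observed at a wavelength on the
#' long-wavelength (descending) limb of the pigment curve, finds the unique
#' lambda_max whose template passes through that point. This inversion is the
#' per-point engine of the lambda_max estimators: it locates the template
#' curve that would produce the observed per-cent absorbance value.
#'
#' The forward map is strictly increasing in lambda_max on the long limb, so
#' the root is found by bracketed bisection to `tol` nm.
#'
#' @param fraction Fractional absorbance value(s), strictly inside `bounds`.
#' @param wavelength Wavelength(s) nm at which `fraction` was observed.
#' @param bounds Admissible open interval for `fraction` (default 0.05-0.95;
#'   values outside are too close to the peak or the noise floor to invert
#'   stably).
#' @param interval Search interval for lambda_max, nm.
#' @param tol Bisection tolerance, nm.
#' @param beta Include the beta band.
#' @return Numeric vector of lambda_max values; `NA` where no root exists in
#'   the interval (the failure is recorded against the data point rather
#'   than raised as an error).
#' @export
invert_long_limb <- function(fraction, wavelength, bounds = c(0.05, 0.95),
                             interval = c(300, 700), tol = 1e-3, beta = TRUE) {
  if (any(!is.finite(fraction)) ||
      any(fraction <= bounds[1] | fraction >= bounds[2]))
    stop(sprintf("fraction must lie strictly within (%g, %g)",
                 bounds[1], bounds[2]), call. = FALSE)
  n <- max(length(fraction), length(wavelength))
  fraction <- rep_len(fraction, n)
  wavelength <- rep_len(wavelength, n)
  hi <- pmin(interval[2], wavelength - 0.25)
  .bisect_lambda_max(fraction, wavelength, lo = interval[1], hi = hi,
                     increasing = TRUE, tol = tol, beta = beta)
}

# Short-limb counterpart used by the secondary estimator: on the short limb
# the normalised template is decreasing in lambda_max (for lambda_max above
# the observation wavelength), so the same bisection applies mirrored.
.invert_short_limb <- function(fraction, wavelength, interval = c(300, 700),
                               tol = 1e-3, beta = TRUE) {
  n <- max(length(fraction), length(wavelength))
  fraction <- rep_len(fraction, n)
  wavelength <- rep_len(wavelength, n)
  lo <- pmax(interval[1], wavelength + 0.25)
  .bisect_lambda_max(fraction, wavelength, lo = lo, hi = interval[2],
                     increasing = FALSE, tol = tol, beta = beta)
}

#' Oil droplet transmittance
#'
#' Smooth long-pass cut-off filter used to model the transmittance of a
#' pigmented cone oil droplet, in the standard exponentiated-exponential
#' form
#' \deqn{T(\lambda) = \exp(-e^{-B_{mid}(\lambda - \lambda_{mid})})}
#' where `lambda_mid` locates the rising edge and `b_mid` sets its steepness.
#' By default `lambda_mid` is derived from the droplet's cut-off wavelength
#' by a linear map `lambda_mid = lambda_cut + mid_offset`.
#'
#' @param wavelength Wavelength(s) nm.
#' @param lambda_cut Cut-off wavelength nm (within \[330, 700\]); ignored if
#'   `lambda_mid` is supplied.
#' @param lambda_mid Wavelength of the filter mid-edge, nm.
#' @param b_mid Edge steepness, per nm.
#' @param mid_offset Offset of `lambda_mid` above `lambda_cut`, nm.
#' @return Transmittance in \[0, 1\], non-decreasing in wavelength.
#' @export
droplet_transmittance <- function(wavelength, lambda_cut = NULL,
                                  lambda_mid = NULL, b_mid = 0.04,
                                  mid_offset = 15) {
  if (is.null(lambda_mid)) {
    if (is.null(lambda_cut))
      stop("supply lambda_cut or lambda_mid", call. = FALSE)
    if (any(!is.finite(lambda_cut)) ||
        any(lambda_cut < 330 | lambda_cut > 700))
      stop("lambda_cut must be finite and within [330, 700] nm",
           call. = FALSE)
    lambda_mid <- lambda_cut + mid_offset
  }
  if (any(!is.finite(lambda_mid)) || !is.finite(b_mid) || b_mid <= 0)
    stop("non-finite or non-positive droplet filter parameters",
         call. = FALSE)
  exp(-exp(-b_mid * (wavelength - lambda_mid)))
}
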