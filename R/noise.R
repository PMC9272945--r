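#' @importFrom stats rnorm coef optimize uniroot sd nls
NULL

#' Rician noise model
#'
#' Magnitude MR data are approximately Rice distributed: independent Gaussian
#' noise of standard deviation \code{sigma} enters the real and imaginary
#' channels and the magnitude is taken. At low SNR this rectification produces
#' a positive bias, the rectified noise floor \eqn{\sigma\sqrt{\pi/2}}.
#'
#' @param sigma Noise standard deviation per complex channel, signal units.
#' @param seed Optional integer seed for reproducible sampling.
#' @return An object of class \code{rician_noise}.
#' @export
rician_noise <- function(sigma, seed = NULL) {
  if (sigma < 0) stop("'sigma' must be nonnegative")
  structure(list(sigma = sigma, seed = seed), class = "rician_noise")
}

#' Expected magnitude signal under Rician noise
#'
#' First-order approximation of the expected magnitude:
#' \deqn{M = \sqrt{S^2 + (\sigma\sqrt{\pi/2})^2}.}
#' At \eqn{S = 0} this reduces to the noise floor \eqn{\sigma\sqrt{\pi/2}}
#' (the exact Rayleigh mean); at high SNR the bias vanishes.
#'
#' @param true_signal Noise-free signal \eqn{S \ge 0} (vectorized).
#' @param sigma Noise standard deviation \eqn{\sigma \ge 0}.
#' @return Expected magnitude, same length as \code{true_signal}.
#' @export
rician_expected_signal <- function(true_signal, sigma) {
  if (any(true_signal < 0)) stop("'true_signal' must be nonnegative")
  if (any(sigma < 0)) stop("'sigma' must be nonnegative")
  sqrt(true_signal^2 + (sigma * sqrt(pi / 2))^2)
}

#' Sample magnitude signals with complex Gaussian noise
#'
#' Adds independent zero-mean Gaussian noise of standard deviation
#' \code{sigma} to the real and imaginary parts of the noise-free signal and
#' returns the magnitude \eqn{|S + n_1 + i n_2|}. Sampling in the complex
#' domain and rectifying avoids any distributional approximation.
#'
#' @param true_signal Noise-free signal (scalar or vector, recycled over
#'   draws).
#' @param model A \code{\link{rician_noise}} model (or a numeric sigma).
#' @param n_draws Number of realizations per signal value.
#' @param seed Optional seed overriding the model's.
#' @return If \code{true_signal} is scalar, a vector of \code{n_draws}
#'   magnitudes; otherwise a matrix with one row per signal value.
#' @export
sample_magnitude <- function(true_signal, model, n_draws = 1L, seed = NULL) {
  sigma <- if (inherits(model, "rician_noise")) model$sigma else model
  if (is.null(seed) && inherits(model, "rician_noise")) seed <- model$seed
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("'n_draws' must be >= 1")
  ns <- length(true_signal)
  draw <- function() {
    n1 <- matrix(rnorm(ns * n_draws, 0, sigma), ns, n_draws)
    n2 <- matrix(rnorm(ns * n_draws, 0, sigma), ns, n_draws)
    sqrt((true_signal + n1)^2 + n2^2)
  }
  m <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (ns == 1L) as.numeric(m) else m
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Signal-to-noise-floor ratio and signal-to-noise ratio
#'
#' \code{snfr} is the mean non-diffusion-weighted signal divided by the
#' rectified noise floor, \eqn{\bar{S}(0) / (\sigma\sqrt{\pi/2})}; it bounds
#' the maximum signal attenuation that can be measured accurately.
#' \code{snr} is \eqn{\bar{S}(0)/\sigma}. The two differ by the constant
#' \eqn{\sqrt{\pi/2}}.
#'
#' @param mean_b0_signal Mean measured signal at b = 0.
#' @param sigma Noise standard deviation (> 0).
#' @return Dimensionless ratio.
#' @export
snfr <- function(mean_b0_signal, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  mean_b0_signal / (sigma * sqrt(pi / 2))
}

#' @rdname snfr
#' @export
snr <- function(mean_b0_signal, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  mean_b0_signal / sigma
}

#' Mono-exponential diffusion signal of free water
#'
#' \deqn{S(\alpha, b) = S_0 \cdot \alpha \cdot \exp(-b D),}
#' where \eqn{S_0} is the non-diffusion-weighted signal at aspect factor 1:
#' the signal scales with voxel volume, hence with the aspect factor.
#'
#' @param s0 Non-diffusion-weighted signal at \eqn{\alpha = 1}.
#' @param diffusivity Diffusion coefficient D in um^2/ms.
#' @param aspect_factor Aspect factor \eqn{\alpha}.
#' @param b b-value in ms/um^2 (vectorized).
#' @return Noise-free signal.
#' @export
monoexp_signal <- function(s0, diffusivity, aspect_factor, b) {
  if (any(b < 0)) stop("'b' must be nonnegative")
  s0 * aspect_factor * exp(-b * diffusivity)
}

#' Fit the noise-floor-biased mono-exponential model
#'
#' Least-squares fit of the Rician-biased water signal
#' \deqn{\bar{S}(\alpha, b) \approx
#'   \sqrt{(S_0 \alpha e^{-bD})^2 + (\sigma\sqrt{\pi/2})^2}}
#' to mean measured magnitudes over a set of (aspect factor, b-value)
#' conditions, estimating \eqn{S_0}, \eqn{D} and the noise level
#' \eqn{\sigma} jointly. Starting values are derived from the data:
#' \eqn{S_0} from the b = 0 signal at the smallest aspect factor, \eqn{D}
#' from a log-linear fit over the low-b points, and \eqn{\sigma} from the
#' highest-b residual.
#'
#' @param mean_signals Mean measured magnitude per observation.
#' @param b_values b-value of each observation (ms/um^2); must include 0.
#' @param aspect_factors Aspect factor of each observation (scalar or vector).
#' @return List with \code{s0}, \code{diffusivity}, \code{sigma},
#'   \code{residual_norm} and the \code{fit} object.
#' @export
fit_biased_monoexp <- function(mean_signals, b_values, aspect_factors = 1) {
  n <- length(mean_signals)
  if (length(b_values) != n) stop("lengths of signals and b-values differ")
  alpha <- rep_len(aspect_factors, n)
  if (n < 3L) stop("need at least 3 observations")
  if (!any(b_values == 0)) stop("b-values must include 0")

  a_min <- min(alpha)
  s0_start <- mean(mean_signals[b_values == 0 & alpha == a_min]) / a_min
  low_b <- b_values <= stats::quantile(b_values[b_values > 0], 0.5)
  lf <- stats::lm(log(pmax(mean_signals[low_b] / alpha[low_b], 1e-12))
                  ~ b_values[low_b])
  d_start <- max(-coef(lf)[[2L]], 1e-4)
  i_hi <- which.max(b_values)
  resid_hi <- mean_signals[i_hi]^2 -
    (s0_start * alpha[i_hi] * exp(-b_values[i_hi] * d_start))^2
  sig_start <- max(sqrt(max(resid_hi, 0)) / sqrt(pi / 2),
                   1e-4 * s0_start)

  df <- data.frame(m = mean_signals, b = b_values, a = alpha)
  fit <- minpack.lm::nlsLM(
    m ~ sqrt((s0 * a * exp(-b * d))^2 + (sig * sqrt(pi / 2))^2),
    data = df,
    start = list(s0 = s0_start, d = d_start, sig = sig_start),
    lower = c(s0 = 0, d = 0, sig = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200L)
  )
  if (!fit$convInfo$isConv && fit$convInfo$stopCode > 3L) {
    stop("biased mono-exponential fit did not converge: ",
         fit$convInfo$stopMessage)
  }
  cf <- coef(fit)
  list(s0 = cf[["s0"]], diffusivity = cf[["d"]], sigma = cf[["sig"]],
       residual_norm = sqrt(sum(stats::residuals(fit)^2)), fit = fit)
}

#' Threshold attenuation factor before noise-floor bias
#'
#' The attenuation factor \eqn{\beta = bD} at which the rectified noise floor
#' inflates the measured signal by a factor \code{f} (default 1.05, i.e. 5\%
#' bias):
#' \deqn{\beta_{thr} = \log\!\big(\mathrm{SNFR}\,\sqrt{f^2 - 1}\big), \qquad
#'   \mathrm{SNFR} = \frac{S_0\,\alpha}{\sigma\sqrt{\pi/2}}.}
#' Larger voxels (higher \eqn{\alpha}) raise the SNFR and push the usable
#' b-value range upward.
#'
#' @param snfr Signal-to-noise-floor ratio; either pass this directly or give
#'   \code{s0}, \code{aspect_factor} and \code{sigma}.
#' @param s0,aspect_factor,sigma Alternative parameterization of the SNFR.
#' @param f Bias factor threshold (> 1), default 1.05.
#' @param diffusivity If supplied, also return the threshold b-value
#'   \eqn{b_{thr} = \beta_{thr}/D} in ms/um^2.
#' @return List with \code{beta_thr} and, if \code{diffusivity} is given,
#'   \code{b_thr}. A nonpositive \code{beta_thr} (bias exceeded already at
#'   b = 0) triggers a warning.
#' @export
threshold_attenuation <- function(snfr = NULL, s0 = 1, aspect_factor = 1,
                                  sigma = NULL, f = 1.05,
                                  diffusivity = NULL) {
  if (f <= 1) stop("'f' must exceed 1")
  if (is.null(snfr)) {
    if (is.null(sigma)) stop("give either 'snfr' or 'sigma'")
    snfr <- s0 * aspect_factor / (sigma * sqrt(pi / 2))
  }
  arg <- snfr * sqrt(f^2 - 1)
  beta <- log(arg)
  if (any(arg <= 1)) {
    warning("signal bias exceeds the threshold already at b = 0 ",
            "(SNFR * sqrt(f^2 - 1) <= 1)")
  }
  out <- list(beta_thr = beta)
  if (!is.null(diffusivity)) out$b_thr <- beta / diffusivity
  out
}

#' Two-compartment dot model signal
#'
#' Signal from a "dot" compartment (near-zero isotropic diffusivity, e.g.
#' densely packed granule cells under spherical b-tensor encoding) plus freely
#' diffusing tissue:
#' \deqn{S(b) = S_0 (f_{dot} e^{-b D_{dot}} + (1 - f_{dot}) e^{-b D_{other}}).}
#'
#' @param f_dot Dot signal fraction in \code{[0, 1]}.
#' @param d_dot Dot diffusivity (um^2/ms), typically ~0.
#' @param d_other Diffusivity of the remaining tissue (um^2/ms),
#'   \code{>= d_dot}.
#' @param s0 Non-diffusion-weighted signal.
#' @param b b-value in ms/um^2 (vectorized).
#' @return Noise-free signal.
#' @export
dot_signal <- function(f_dot, d_dot, d_other, s0, b) {
  if (f_dot < 0 || f_dot > 1) stop("'f_dot' must lie in [0, 1]")
  if (d_dot > d_other) stop("'d_dot' must not exceed 'd_other'")
  s0 * (f_dot * exp(-b * d_dot) + (1 - f_dot) * exp(-b * d_other))
}

#' Estimate the dot fraction from high-b signal retention
#'
#' At very high b-values the non-dot signal is fully attenuated and
#' \eqn{f_{dot} \approx S(b_{high}) / S(0)}. The estimate is an upper bound
#' on the true fraction: residual slowly-diffusing tissue and the rectified
#' noise floor both contribute to the remaining signal.
#'
#' @param signal_bhigh Signal (map) at the high b-value.
#' @param signal_b0 Non-diffusion-weighted signal (map); voxels with
#'   nonpositive values are masked to \code{NA}.
#' @param clip If \code{TRUE}, clip estimates to \code{[0, 1]} (default
#'   \code{FALSE}: raw ratios are reported as upper bounds).
#' @return Dot-fraction estimate(s) with attribute \code{"n_above_one"}
#'   counting ratios exceeding 1.
#' @export
estimate_fdot <- function(signal_bhigh, signal_b0, clip = FALSE) {
  bad <- !(signal_b0 > 0)
  f <- signal_bhigh / signal_b0
  f[bad] <- NA_real_
  n_above <- sum(f > 1, na.rm = TRUE)
  if (clip) f <- pmin(pmax(f, 0), 1)
  attr(f, "n_above_one") <- n_above
  f
}

#' Contrast ratio between two regions of interest
#'
#' @param image Numeric matrix/array.
#' @param roi_a,roi_b Logical masks (same shape as \code{image}), non-empty.
#' @return \code{mean(image[roi_a]) / mean(image[roi_b])}.
#' @export
contrast_ratio <- function(image, roi_a, roi_b) {
  if (!any(roi_a) || !any(roi_b)) stop("ROI masks must be non-empty")
  mean(image[roi_a]) / mean(image[roi_b])
}
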