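#' Noise specification
#'
#' Describes the additive sensor-noise model used both to corrupt clean
#' fixtures and to build double-noise training pairs. `sigma` is the per-axis
#' standard deviation in normalized units (a fraction of the object radius
#' after [normalize_cloud()]); the uniform family draws per axis on
#' `[-sigma*sqrt(3), sigma*sqrt(3)]` so its per-axis standard deviation is
#' also `sigma`. A fraction `outlier_fraction` of points can additionally be
#' kicked by an isotropic Gaussian of standard deviation
#' `sigma * outlier_scale` to emulate sparse LiDAR outliers; it defaults to 0,
#' which is the pure additive model of the training theory.
#'
#' @param family `"gaussian"` or `"uniform"`.
#' @param sigma Per-axis standard deviation (normalized units), `>= 0`.
#'   Default 0.1, the strongest of the tested 0.01–0.1 intensities and the
#'   training default.
#' @param outlier_fraction Fraction of points receiving an extra outlier kick.
#' @param outlier_scale Multiplier on `sigma` for the outlier kick.
#' @param seed Integer seed used by [inject_noise()].
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(family = c("gaussian", "uniform"), sigma = 0.1,
                       outlier_fraction = 0, outlier_scale = 10, seed = 1L) {
  family <- match.arg(family)
  spec <- list(family = family,
               sigma = check_scalar(sigma, "sigma", lower = 0),
               outlier_fraction = check_scalar(outlier_fraction, "outlier_fraction", 0, 1),
               outlier_scale = check_scalar(outlier_scale, "outlier_scale", lower = 0),
               seed = as.integer(seed))
  structure(spec, class = "noise_spec")
}

# Draw the n x 3 noise matrix for a spec under an explicit seed.
draw_noise <- function(n, spec, seed) {
  withr::with_seed(as.integer(seed), {
    m <- if (spec$family == "gaussian") {
      matrix(rnorm(3L * n, sd = spec$sigma), n, 3L)
    } else {
      half <- spec$sigma * sqrt(3)
      matrix(runif(3L * n, -half, half), n, 3L)
    }
    if (spec$outlier_fraction > 0 && spec$sigma > 0) {
      n_out <- round(spec$outlier_fraction * n)
      if (n_out > 0) {
        idx <- sample.int(n, n_out)
        m[idx, ] <- m[idx, ] + matrix(rnorm(3L * n_out, sd = spec$sigma * spec$outlier_scale),
                                      n_out, 3L)
      }
    }
    m
  })
}

#' Corrupt a cloud with additive synthetic noise
#'
#' Adds an i.i.d. per-point draw from the [noise_spec()] family. The cloud is
#' expected in the normalized frame so `sigma` is meaningful; pass
#' `allow_raw = TRUE` to knowingly perturb raw coordinates (then `sigma` is in
#' meters). Deterministic given `spec$seed` (or the `seed` override) and
#' order-preserving.
#'
#' @param cloud A [point_cloud()].
#' @param spec A [noise_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @param allow_raw Permit raw-frame input.
#' @return A `point_cloud` with perturbed coordinates.
#' @export
inject_noise <- function(cloud, spec = noise_spec(), seed = NULL, allow_raw = FALSE) {
  stopifnot(is_point_cloud(cloud), inherits(spec, "noise_spec"))
  if (pc_frame(cloud) != "normalized" && !allow_raw) {
    stopf("cloud is in the raw frame; normalize first (sigma is in normalized units) or set allow_raw = TRUE")
  }
  m <- draw_noise(nrow(cloud), spec, seed %||% spec$seed)
  pc_replace_coords(cloud, as_matrix(cloud) + m)
}

#' Build a double-noise training pair
#'
#' The training unit of the unsupervised scheme. Given the observed noisy
#' cloud `base` (clean geometry plus unknown sensor noise), a second,
#' independent noise realization `M` with the same assumed family and level is
#' injected to form the double-noisy cloud `double = base + M`. The known
#' displacement between the two, `d_dot = base - double = -M`, is what the
#' network's prediction is compared against (scaled by two, see
#' [training_target()]). `M`'s stream is derived from `seed + 1` so it is
#' independent of any noise stream used to synthesize `base` under `seed`.
#'
#' @param base Observed noisy `point_cloud` (normalized frame).
#' @param spec [noise_spec()] describing the assumed sensor noise.
#' @param seed Integer pair seed.
#' @return A `double_noise_pair`: list with `base`, `injected` (the n x 3
#'   matrix `M`), `double` (`point_cloud`), `d_dot` (n x 3, equal to `-M`).
#' @export
double_noise_pair <- function(base, spec = noise_spec(), seed = 1L) {
  stopifnot(is_point_cloud(base), inherits(spec, "noise_spec"))
  m <- draw_noise(nrow(base), spec, as.integer(seed) + 1L)
  xb <- as_matrix(base)
  dbl <- pc_replace_coords(base, xb + m)
  m <- as_matrix(dbl) - xb  # representable difference: pair identities hold exactly
  structure(list(base = base, injected = m, double = dbl, d_dot = -m),
            class = "double_noise_pair")
}

#' Regression target of the double-noise scheme
#'
#' The conditional-expectation argument behind noise doubling shows that the
#' displacement from the double-noisy cloud back to the clean geometry equals
#' twice the displacement back to the singly-noisy cloud. The realized
#' training target is therefore `2 * d_dot = -2 * M`, aligned index-wise with
#' the double-noisy input.
#'
#' @param pair A [double_noise_pair()].
#' @return An n x 3 matrix of target displacement vectors.
#' @export
training_target <- function(pair) {
  stopifnot(inherits(pair, "double_noise_pair"))
  2 * pair$d_dot
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s, sigma = %g, outliers = %g%% x%g, seed = %d\n",
              x$family, x$sigma, 100 * x$outlier_fraction, x$outlier_scale, x$seed))
  invisible(x)
}

#' @export
print.double_noise_pair <- function(x, ...) {
  cat(sprintf("<double_noise_pair> %d points, |M| rms = %.4g\n",
              nrow(x$base), sqrt(mean(x$injected^2))))
  invisible(x)
}
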