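#' Uniaxial tensile record
#'
#' Pairs the raw material-tester channels (time, clamp displacement, force)
#' with the sample geometry needed to convert them to stress and strain.
#'
#' @param data Data frame with columns `time_s`, `displacement_mm`, `force_N`;
#'   time must be nondecreasing.
#' @param gauge_length_mm Clamp separation at the pre-stressed reference state
#'   (default 5 mm).
#' @param area_mm2 Initial cross-sectional area in mm^2.
#' @param width_mm Strip width in mm (default 4).
#' @param pre_load_n Pre-load applied to take up slack, in N (default 0.04);
#'   defines the zero-strain/zero-displacement reference state.
#' @param speed_mm_min Crosshead speed in mm/min (default 1.8).
#' @param region Optional region label (`"A"`-`"D"`).
#' @return Object of class `stress_strain_record`.
#' @export
stress_strain_record <- function(data,
                                 gauge_length_mm = 5,
                                 area_mm2,
                                 width_mm = 4,
                                 pre_load_n = 0.04,
                                 speed_mm_min = 1.8,
                                 region = NA_character_) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "displacement_mm", "force_N") %in% names(data)))
  if (is.unsorted(data$time_s)) stop("time must be nondecreasing", call. = FALSE)
  if (!all(is.finite(data$force_N))) stop("force must be finite", call. = FALSE)
  stopifnot(gauge_length_mm > 0, area_mm2 > 0)
  structure(
    list(data = data, gauge_length_mm = gauge_length_mm, area_mm2 = area_mm2,
         width_mm = width_mm, pre_load_n = pre_load_n,
         speed_mm_min = speed_mm_min, region = region),
    class = "stress_strain_record"
  )
}

#' @export
print.stress_strain_record <- function(x, ...) {
  cat(sprintf(
    "<stress_strain_record> %d samples over %.1f s, gauge %.1f mm, area %.2f mm^2%s\n",
    nrow(x$data), diff(range(x$data$time_s)), x$gauge_length_mm, x$area_mm2,
    if (is.na(x$region)) "" else sprintf(", region %s", x$region)
  ))
  invisible(x)
}

#' Extract the final loading ramp from a tensile record
#'
#' The protocol precedes the analysed extension with preconditioning cycles
#' and a rest; only the final monotone ramp to the maximum displacement is
#' analysed. The ramp is taken as the contiguous run of samples ending at the
#' global displacement maximum over which displacement is nondecreasing.
#'
#' @param rec A `stress_strain_record`.
#' @return A `stress_strain_record` restricted to the final ramp.
#' @export
extract_final_ramp <- function(rec) {
  stopifnot(inherits(rec, "stress_strain_record"))
  d <- rec$data$displacement_mm
  i_end <- which.max(d)
  i_start <- i_end
  while (i_start > 1L && d[i_start - 1L] <= d[i_start]) i_start <- i_start - 1L
  # drop leading flat samples (the rest period), keeping one start-of-ramp point
  while (i_start < i_end && d[i_start + 1L] == d[i_start]) i_start <- i_start + 1L
  rec$data <- rec$data[i_start:i_end, , drop = FALSE]
  rec
}

#' Engineering stress and strain from a tensile record
#'
#' Strain is clamp displacement over the reference gauge length,
#' \eqn{\varepsilon = (L - L_0)/L_0}; stress is force over the initial
#' cross-sectional area (engineering stress), in MPa since N/mm^2 = MPa.
#' Displacement is referenced to the pre-stressed state, so \eqn{\varepsilon =
#' 0} carries the pre-load stress `pre_load_n / area_mm2`.
#'
#' @param rec A `stress_strain_record`.
#' @param ramp_only Restrict to the final loading ramp first (default `TRUE`).
#' @return Data frame with columns `strain` and `stress_mpa`.
#' @export
compute_stress_strain <- function(rec, ramp_only = TRUE) {
  stopifnot(inherits(rec, "stress_strain_record"))
  if (ramp_only) rec <- extract_final_ramp(rec)
  data.frame(
    strain = rec$data$displacement_mm / rec$gauge_length_mm,
    stress_mpa = rec$data$force_N / rec$area_mm2
  )
}

#' Fit the exponential stress-strain model
#'
#' Least-squares fit of the exponential constitutive model
#' \deqn{\sigma = \sigma_0 + a\,(e^{b\varepsilon} - 1)}
#' over `fit_range` (default 0-6.5% strain, the preconditioned, pseudo-elastic
#' range). `stress_datum` is the known reference stress \eqn{\sigma_0} at zero
#' strain — the pre-load divided by the initial area under the protocol this
#' package models — and is held fixed, not estimated; with the default 0 the
#' classical two-parameter model is recovered.
#'
#' Initialisation is deterministic: `b0` is the log-slope of the smoothed
#' finite-difference tangent modulus, and `a0` follows from matching the
#' maximum stress in range. The bounded Levenberg-Marquardt solver
#' ([minpack.lm::nlsLM()]) then refines `(a, b)` with `a, b > 0`.
#'
#' @param strain Unitless strain series.
#' @param stress Stress series in MPa.
#' @param fit_range Strain interval used for fitting (default `c(0, 0.065)`).
#' @param stress_datum Known stress at zero strain, MPa (default 0).
#' @return Object of class `elastic_params`: `a` (MPa), `b` (unitless),
#'   `tangent_modulus_0 = a * b` (MPa), `fit_rmse` (MPa), `fit_range`,
#'   `stress_datum`, `n_points`.
#' @export
fit_exponential <- function(strain, stress, fit_range = c(0, 0.065),
                            stress_datum = 0) {
  stopifnot(length(strain) == length(stress), length(fit_range) == 2L)
  sel <- is.finite(strain) & is.finite(stress) &
    strain >= fit_range[1L] & strain <= fit_range[2L]
  eps <- strain[sel]
  sig <- stress[sel] - stress_datum
  if (length(eps) < 10L) {
    stop("need at least 10 samples inside fit_range", call. = FALSE)
  }
  o <- order(eps)
  eps <- eps[o]
  sig <- sig[o]
  # deterministic initialisation from the log-slope of the tangent modulus
  k <- min(7L, 2L * (length(eps) %/% 2L) - 1L)
  smooth <- as.numeric(stats::filter(sig, rep(1 / k, k), sides = 2L))
  smooth[is.na(smooth)] <- sig[is.na(smooth)]
  dmod <- diff(smooth) / pmax(diff(eps), .Machine$double.eps)
  mid <- (eps[-1L] + eps[-length(eps)]) / 2
  pos <- is.finite(dmod) & dmod > 0
  b0 <- if (sum(pos) >= 3L) {
    unname(stats::coef(stats::lm(log(dmod[pos]) ~ mid[pos]))[2L])
  } else {
    40
  }
  b0 <- min(max(b0, 1), 500)
  a0 <- max(max(sig), 1e-6) / max(expm1(b0 * max(eps)), 1e-6)
  a0 <- max(a0, 1e-8)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      sig ~ a * (exp(b * eps) - 1),
      start = list(a = a0, b = b0),
      lower = c(1e-10, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      stop(sprintf(
        "exponential fit failed to converge (start a0 = %.3g, b0 = %.3g, n = %d): %s",
        a0, b0, length(eps), conditionMessage(e)
      ), call. = FALSE)
    }
  )
  co <- stats::coef(fit)
  resid <- sig - co[["a"]] * expm1(co[["b"]] * eps)
  structure(
    list(a = co[["a"]], b = co[["b"]],
         tangent_modulus_0 = co[["a"]] * co[["b"]],
         fit_rmse = sqrt(mean(resid^2)),
         fit_range = fit_range,
         stress_datum = stress_datum,
         n_points = length(eps)),
    class = "elastic_params"
  )
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf(
    "<elastic_params> a = %.4g MPa, b = %.4g, E0 = a*b = %.4g MPa, RMSE %.3g MPa (n = %d, strain %.3g-%.3g)\n",
    x$a, x$b, x$tangent_modulus_0, x$fit_rmse, x$n_points,
    x$fit_range[1L], x$fit_range[2L]
  ))
  invisible(x)
}

#' Tangent modulus of the exponential model
#'
#' \eqn{E(\varepsilon) = d\sigma/d\varepsilon = a b e^{b\varepsilon}}; at zero
#' strain this is \eqn{a b}, the tangent modulus used for the correlation
#' analysis.
#'
#' @param params An `elastic_params` fit.
#' @param at_strain Strain at which to evaluate (default 0).
#' @return Tangent modulus in MPa.
#' @export
tangent_modulus <- function(params, at_strain = 0) {
  stopifnot(inherits(params, "elastic_params"))
  params$a * params$b * exp(params$b * at_strain)
}

#' Structural stiffness
#'
#' Product of tangent modulus at zero strain and laterally-averaged thickness:
#' a net load-bearing measure that absorbs regional thickness differences.
#'
#' @param tangent_modulus_0 Tangent modulus at 0% strain, MPa.
#' @param thickness Thickness in mm.
#' @return Structural stiffness in MPa mm.
#' @export
structural_stiffness <- function(tangent_modulus_0, thickness) {
  if (!(tangent_modulus_0 > 0) || !(thickness > 0)) {
    stop("tangent modulus and thickness must be positive", call. = FALSE)
  }
  tangent_modulus_0 * thickness
}

#' Power of the exponential stress-strain function
#'
#' Returns `b`, which equals the slope of tangent modulus against stress:
#' \eqn{E = b(\sigma - \sigma_0 + a)}, so \eqn{dE/d\sigma = b} independently
#' of `a`.
#'
#' @param params An `elastic_params` fit.
#' @return The unitless exponent `b`.
#' @export
exponential_power <- function(params) {
  stopifnot(inherits(params, "elastic_params"))
  params$b
}
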