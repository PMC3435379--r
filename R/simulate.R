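#' Specification of a birefringent layered phantom
#'
#' Describes a synthetic tissue volume for the Jones-matrix forward model:
#' per-voxel birefringence, an optic-axis field (uniform, two lateral domains,
#' von-Mises-Fisher dispersed, or i.i.d. random), and the detection SNR.
#'
#' @param dims `(z, x, y)` voxel counts.
#' @param dn Birefringence: scalar or `(z, x, y)` array (unitless).
#' @param axis Axis field, one of
#'   `list(type = "uniform", axis = c(q, u, v))`,
#'   `list(type = "two_domain", axis1 =, axis2 =, split_frac = 0.5)` (split
#'   along x),
#'   `list(type = "vmf", mean = c(q, u, v), kappa = )` (i.i.d. per voxel), or
#'   `list(type = "random")` (i.i.d. uniform on the sphere).
#' @param snr_db Detection SNR in dB (`Inf` for noiseless).
#' @param wavelength,axial_pitch,lateral_pitch Acquisition metadata (metres).
#' @param separation_pixels Axial separation the analysis will use; the wrap
#'   guard is enforced against it.
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims,
                         dn,
                         axis = list(type = "uniform", axis = c(1, 0, 0)),
                         snr_db = 30,
                         wavelength = 1.31e-6,
                         axial_pitch = 6.125e-6,
                         lateral_pitch = 6.125e-6,
                         separation_pixels = 8L,
                         rng_seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 1L), is.finite(snr_db) || is.infinite(snr_db))
  structure(
    list(dims = as.integer(dims), dn = dn, axis = axis, snr_db = snr_db,
         wavelength = wavelength, axial_pitch = axial_pitch,
         lateral_pitch = lateral_pitch,
         separation_pixels = as.integer(separation_pixels),
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

# i.i.d. von-Mises-Fisher draws on the unit sphere (kappa = 0 reduces to the
# uniform distribution); mean direction mu.
.rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- stats::runif(n)
  w <- if (kappa > 0) {
    1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  } else {
    2 * u - 1
  }
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - w^2, 0))
  local <- cbind(s * cos(phi), s * sin(phi), w)
  # rotate the pole (0,0,1) onto mu
  if (sum((mu - c(0, 0, 1))^2) < 1e-18) return(local)
  if (sum((mu + c(0, 0, 1))^2) < 1e-18) return(local %*% diag(c(1, -1, -1)))
  vax <- c(-mu[2L], mu[1L], 0)
  vax <- vax / sqrt(sum(vax^2))
  ang <- acos(mu[3L])
  K <- matrix(c(0, vax[3L], -vax[2L], -vax[3L], 0, vax[1L], vax[2L], -vax[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  local %*% t(R)
}

# Axis field as three (z, x, y) arrays of unit-vector components.
.axis_field <- function(axis, dims) {
  nt <- prod(dims)
  mk <- function(v) list(q = array(v[1L], dims), u = array(v[2L], dims), v = array(v[3L], dims))
  norm1 <- function(v) v / sqrt(sum(v^2))
  switch(axis$type,
    uniform = mk(norm1(axis$axis %||% c(1, 0, 0))),
    two_domain = {
      a1 <- norm1(axis$axis1)
      a2 <- norm1(axis$axis2)
      split <- ceiling((axis$split_frac %||% 0.5) * dims[2L])
      f <- mk(a1)
      if (split < dims[2L]) {
        f$q[, (split + 1L):dims[2L], ] <- a2[1L]
        f$u[, (split + 1L):dims[2L], ] <- a2[2L]
        f$v[, (split + 1L):dims[2L], ] <- a2[3L]
      }
      f
    },
    vmf = {
      m <- .rvmf(nt, axis$mean, axis$kappa)
      list(q = array(m[, 1L], dims), u = array(m[, 2L], dims), v = array(m[, 3L], dims))
    },
    random = {
      m <- .rvmf(nt, c(0, 0, 1), 0)
      list(q = array(m[, 1L], dims), u = array(m[, 2L], dims), v = array(m[, 3L], dims))
    },
    stop("unknown axis type: ", axis$type, call. = FALSE)
  )
}

#' Simulate a Jones-matrix OCT volume from a phantom specification
#'
#' Forward model: each voxel contributes a retarder increment with round-trip
#' retardation \eqn{4\pi\,\Delta n\,p_z/\lambda} about its local Poincaré
#' axis; the cumulative round-trip Jones matrix at depth `z` is the ordered
#' product of the increments from the surface down. Each A-scan is multiplied
#' by a random global unit phasor (speckle-phase surrogate) and independent
#' additive circular complex Gaussian noise scaled to `snr_db` is added to
#' every matrix element; the implied per-channel noise variance is recorded in
#' the volume's `noise_floor` metadata.
#'
#' Generation refuses parameter combinations whose local round-trip
#' retardance over the declared separation would reach \eqn{\pi} (phase
#' wrapping), reporting the offending depth.
#'
#' @param spec A [phantom_spec()].
#' @return A cumulative `jones_volume`.
#' @export
simulate_jones_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  dn <- spec$dn
  if (length(dn) == 1L) dn <- array(dn, d)
  stopifnot(identical(dim(dn), d), all(dn >= 0))
  # wrap guard: windowed sum of per-voxel round-trip retardation
  per_vox <- 4 * pi * dn * spec$axial_pitch / spec$wavelength
  sep <- min(spec$separation_pixels, d[1L])
  if (d[1L] >= 1L) {
    pv <- matrix(per_vox, d[1L], d[2L] * d[3L])
    cs <- rbind(0, apply(pv, 2L, cumsum))
    zmax <- d[1L] - sep + 1L
    if (zmax >= 1L) {
      wsum <- cs[(sep + 1L):(d[1L] + 1L), , drop = FALSE] - cs[1:zmax, , drop = FALSE]
      if (max(wsum) >= pi) {
        bad <- which(wsum >= pi, arr.ind = TRUE)[1L, ]
        stop(sprintf(
          "wrap guard: local retardance %.3f rad >= pi over %d pixels starting at depth %d",
          max(wsum), sep, bad[1L]
        ), call. = FALSE)
      }
    }
  }
  .with_seed(spec$rng_seed, {
    ax <- .axis_field(spec$axis, d)
    nxy <- d[2L] * d[3L]
    # cumulative product down z, elementwise over (x, y)
    cum11 <- matrix(complex(real = 1), 1L, nxy)
    cum12 <- matrix(complex(real = 0), 1L, nxy)
    cum21 <- matrix(complex(real = 0), 1L, nxy)
    cum22 <- matrix(complex(real = 1), 1L, nxy)
    j <- array(complex(real = 0), c(d, 4L))
    h <- per_vox / 2
    for (z in seq_len(d[1L])) {
      ch <- cos(h[z, , ])
      sh <- sin(h[z, , ])
      aq <- ax$q[z, , ]
      au <- ax$u[z, , ]
      av <- ax$v[z, , ]
      v11 <- complex(real = ch, imaginary = sh * aq)
      v12 <- complex(real = sh * av, imaginary = sh * au)
      v21 <- complex(real = -sh * av, imaginary = sh * au)
      v22 <- complex(real = ch, imaginary = -sh * aq)
      dim(v11) <- dim(v12) <- dim(v21) <- dim(v22) <- NULL
      n11 <- v11 * cum11 + v12 * cum21
      n12 <- v11 * cum12 + v12 * cum22
      n21 <- v21 * cum11 + v22 * cum21
      n22 <- v21 * cum12 + v22 * cum22
      cum11 <- n11; cum12 <- n12; cum21 <- n21; cum22 <- n22
      j[z, , , 1L] <- n11
      j[z, , , 2L] <- n21
      j[z, , , 3L] <- n12
      j[z, , , 4L] <- n22
    }
    # per-A-scan random global phasor
    phasor <- exp(2i * pi * stats::runif(nxy))
    ph <- rep(phasor, each = d[1L])
    for (k in 1:4) j[, , , k] <- array(as.vector(j[, , , k, drop = FALSE]) * ph, d)
    if (is.finite(spec$snr_db)) {
      sigma2 <- 0.5 * 10^(-spec$snr_db / 10)  # signal power 2 across the 4 channels
      nt <- prod(d)
      for (k in 1:4) j[, , , k] <- array(
        as.vector(j[, , , k, drop = FALSE]) + .rcnorm(nt, sigma2), d)
      nf <- rep(sigma2, 4L)
    } else {
      nf <- rep(1e-15, 4L)
    }
    jones_volume(j,
      wavelength = spec$wavelength,
      axial_pitch = spec$axial_pitch,
      lateral_pitch = spec$lateral_pitch,
      noise_floor = nf
    )
  })
}

#' Tensile-test protocol constants
#'
#' The loading protocol this package models: 0.04 N pre-load to take up
#' slack, ten preconditioning cycles of loading and unloading over 0-6.5%
#' strain at 1.8 mm/min, a 10 s rest, then a final ramp to 18% strain at the
#' same speed, with a 5 mm clamp gauge.
#'
#' @param gauge_length_mm Clamp separation, mm.
#' @param speed_mm_min Crosshead speed, mm/min.
#' @param n_precondition Number of preconditioning cycles.
#' @param precondition_strain Strain amplitude of the cycles.
#' @param rest_s Pause between preconditioning and the final ramp, s.
#' @param max_strain Final-ramp strain.
#' @param pre_load_n Pre-load in N.
#' @param sample_rate_hz Sampling rate of the recorded channels.
#' @return List of protocol constants (class `tensile_protocol`).
#' @export
tensile_protocol <- function(gauge_length_mm = 5,
                             speed_mm_min = 1.8,
                             n_precondition = 10L,
                             precondition_strain = 0.065,
                             rest_s = 10,
                             max_strain = 0.18,
                             pre_load_n = 0.04,
                             sample_rate_hz = 10) {
  structure(
    list(gauge_length_mm = gauge_length_mm, speed_mm_min = speed_mm_min,
         n_precondition = as.integer(n_precondition),
         precondition_strain = precondition_strain, rest_s = rest_s,
         max_strain = max_strain, pre_load_n = pre_load_n,
         sample_rate_hz = sample_rate_hz),
    class = "tensile_protocol"
  )
}

#' Simulate a uniaxial stress-strain record
#'
#' Generates the displacement profile of the protocol (preconditioning
#' triangles, rest, final ramp), evaluates the pseudo-elastic force
#' \eqn{F(\varepsilon) = F_{pre} + A\,a(e^{b\varepsilon} - 1)} (same curve on
#' loading and unloading; viscoelastic memory is not modelled), and applies
#' multiplicative Gaussian force noise.
#'
#' @param a,b Constitutive parameters (MPa, unitless); both positive.
#' @param area_mm2 Initial cross-sectional area, mm^2.
#' @param protocol A [tensile_protocol()].
#' @param noise_frac Multiplicative force-noise fraction (>= 0), default 0.01.
#' @param rng_seed Integer seed.
#' @param width_mm Strip width recorded in the metadata.
#' @param region Optional region label.
#' @return A `stress_strain_record`.
#' @export
simulate_stress_strain <- function(a, b, area_mm2,
                                   protocol = tensile_protocol(),
                                   noise_frac = 0.01,
                                   rng_seed = 1L,
                                   width_mm = 4,
                                   region = NA_character_) {
  stopifnot(a > 0, b > 0, area_mm2 > 0, noise_frac >= 0)
  p <- protocol
  v <- p$speed_mm_min / 60                       # mm/s
  d_pre <- p$precondition_strain * p$gauge_length_mm
  d_max <- p$max_strain * p$gauge_length_mm
  leg <- d_pre / v
  # displacement profile nodes (time, displacement)
  tt <- 0
  dd <- 0
  for (i in seq_len(p$n_precondition)) {
    tt <- c(tt, tt[length(tt)] + leg, tt[length(tt)] + 2 * leg)
    dd <- c(dd, d_pre, 0)
  }
  tt <- c(tt, tt[length(tt)] + p$rest_s)
  dd <- c(dd, 0)
  tt <- c(tt, tt[length(tt)] + d_max / v)
  dd <- c(dd, d_max)
  # regular sampling plus the profile breakpoints, so cycle peaks and the
  # ramp endpoint appear in the record exactly
  grid <- sort(unique(c(seq(0, tt[length(tt)], by = 1 / p$sample_rate_hz), tt)))
  disp <- stats::approx(tt, dd, xout = grid)$y
  eps <- disp / p$gauge_length_mm
  force <- p$pre_load_n + area_mm2 * a * expm1(b * eps)
  force <- .with_seed(rng_seed,
    force * (1 + noise_frac * stats::rnorm(length(force))))
  stress_strain_record(
    data.frame(time_s = grid, displacement_mm = disp, force_N = force),
    gauge_length_mm = p$gauge_length_mm,
    area_mm2 = area_mm2,
    width_mm = width_mm,
    pre_load_n = p$pre_load_n,
    speed_mm_min = p$speed_mm_min,
    region = region
  )
}

#' Specification of a synthetic cohort
#'
#' A latent fiber-organization variable per (sample, region) drives both
#' birefringence and stiffness: birefringence is affine in the latent, the
#' structural-stiffness target is affine in a correlated standard normal
#' whose correlation with the latent equals `target_correlation[region]`
#' (analytic calibration of the bivariate normal construction), thickness
#' varies independently, the tangent modulus is stiffness over thickness, the
#' exponential power is negatively loaded on the latent, and `a` follows from
#' `E0 = a b`.
#'
#' Default targets follow the region-wise structural-stiffness correlations
#' of the cohort this package models; defaults for the physical scales are
#' representative of porcine sclera (birefringence ~1.5e-3, tangent modulus
#' ~0.8 MPa, thickness ~0.8 mm).
#'
#' @param n_samples Samples (eyes) per region, default 19.
#' @param regions Region labels.
#' @param target_correlation Named vector of target Pearson correlations
#'   between birefringence and structural stiffness per region, each in
#'   (-1, 1).
#' @param dn_mean,dn_sd Birefringence mean and SD.
#' @param stiffness_mean,stiffness_sd Structural-stiffness mean/SD (MPa mm).
#' @param thickness_mean,thickness_sd Thickness mean/SD (mm).
#' @param power_mean,power_sd Exponential-power mean/SD.
#' @param power_latent_corr Loading of the power on the latent (negative:
#'   more organized tissue has lower power).
#' @param width_mm Strip width (mm).
#' @param volume_dims `(z, x, y)` of the per-sample phantom volumes.
#' @param snr_db Phantom detection SNR.
#' @param force_noise_frac Multiplicative force noise of the tensile records.
#' @param protocol A [tensile_protocol()].
#' @param rng_seed Integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 19L,
                        regions = c("A", "B", "C", "D"),
                        target_correlation = c(A = 0.5389, B = 0.8242,
                                               C = 0.5630, D = 0.1222),
                        dn_mean = 1.5e-3, dn_sd = 3e-4,
                        stiffness_mean = 0.64, stiffness_sd = 0.16,
                        thickness_mean = 0.8, thickness_sd = 0.04,
                        power_mean = 40, power_sd = 6,
                        power_latent_corr = -0.5,
                        width_mm = 4,
                        volume_dims = c(40L, 24L, 1L),
                        snr_db = 30,
                        force_noise_frac = 0.01,
                        protocol = tensile_protocol(),
                        rng_seed = 1L) {
  stopifnot(all(regions %in% names(target_correlation)),
            all(abs(target_correlation) < 1),
            abs(power_latent_corr) <= 1,
            dn_sd >= 0, stiffness_sd >= 0, thickness_sd >= 0, power_sd >= 0)
  structure(
    list(n_samples = as.integer(n_samples), regions = regions,
         target_correlation = target_correlation,
         dn_mean = dn_mean, dn_sd = dn_sd,
         stiffness_mean = stiffness_mean, stiffness_sd = stiffness_sd,
         thickness_mean = thickness_mean, thickness_sd = thickness_sd,
         power_mean = power_mean, power_sd = power_sd,
         power_latent_corr = power_latent_corr,
         width_mm = width_mm, volume_dims = as.integer(volume_dims),
         snr_db = snr_db, force_noise_frac = force_noise_frac,
         protocol = protocol, rng_seed = as.integer(rng_seed)),
    class = "cohort_spec"
  )
}

#' Simulate a linked cohort with known ground truth
#'
#' Draws the per-(sample, region) ground truth (see [cohort_spec()]), then
#' emits everything the analysis stages read: a phantom specification per
#' sample (uniform-axis volume at the sample's birefringence), a tensile
#' record per sample, a rectangular cross-section polygon per sample, and the
#' ground-truth cohort table for recovery testing. Deterministic given the
#' master seed.
#'
#' @param spec A [cohort_spec()].
#' @param emit `"full"` (default) generates phantom specs, tensile records and
#'   polygons; `"truth"` returns only the ground-truth table (for fast
#'   calibration studies of the latent construction).
#' @return List with `truth` (data frame), `volumes` (list of
#'   [phantom_spec()]), `records` (list of `stress_strain_record`),
#'   `polygons` (list of vertex matrices, mm), and `spec`.
#' @export
simulate_cohort <- function(spec, emit = c("full", "truth")) {
  stopifnot(inherits(spec, "cohort_spec"))
  emit <- match.arg(emit)
  dn_cap <- 0.95 * 1.31e-6 / (4 * 8 * 6.125e-6)  # conservative wrap limit
  .with_seed(spec$rng_seed, {
    rows <- list()
    volumes <- list()
    records <- list()
    polygons <- list()
    idx <- 0L
    for (reg in spec$regions) {
      r <- spec$target_correlation[[reg]]
      for (i in seq_len(spec$n_samples)) {
        idx <- idx + 1L
        L <- stats::rnorm(1L)
        Zs <- r * L + sqrt(1 - r^2) * stats::rnorm(1L)
        Zb <- spec$power_latent_corr * L +
          sqrt(1 - spec$power_latent_corr^2) * stats::rnorm(1L)
        dn <- min(max(spec$dn_mean + spec$dn_sd * L, 2e-4), dn_cap)
        S <- max(spec$stiffness_mean + spec$stiffness_sd * Zs, 0.05)
        th <- max(spec$thickness_mean + spec$thickness_sd * stats::rnorm(1L), 0.2)
        E0 <- S / th
        bpow <- max(spec$power_mean + spec$power_sd * Zb, 5)
        a <- E0 / bpow
        seeds <- sample.int(.Machine$integer.max - 1L, 2L)
        if (emit == "full") {
          volumes[[idx]] <- phantom_spec(
            dims = spec$volume_dims, dn = dn,
            axis = list(type = "uniform", axis = c(1, 0, 0)),
            snr_db = spec$snr_db, rng_seed = seeds[1L]
          )
          records[[idx]] <- simulate_stress_strain(
            a, bpow, area_mm2 = th * spec$width_mm, protocol = spec$protocol,
            noise_frac = spec$force_noise_frac, rng_seed = seeds[2L],
            width_mm = spec$width_mm, region = reg
          )
          polygons[[idx]] <- cbind(c(0, spec$width_mm, spec$width_mm, 0),
                                   c(0, 0, th, th))
        }
        rows[[idx]] <- data.frame(
          sample_id = sprintf("S%02d", i), region = reg, latent = L,
          mean_birefringence = dn, tangent_modulus_0 = E0,
          structural_stiffness = S, power_b = bpow, thickness = th, a = a,
          stringsAsFactors = FALSE
        )
      }
    }
    list(truth = do.call(rbind, rows), volumes = volumes, records = records,
         polygons = polygons, spec = spec)
  })
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' For every (sample, region): process the Jones volume to a gated mean
#' birefringence, measure the cross section and thickness from the polygon,
#' extract the final ramp of the tensile record, fit the exponential model
#' with the pre-load as the known stress datum, and derive the tangent
#' modulus, structural stiffness and power. Then build the region-by-
#' parameter Pearson table.
#'
#' @param sim Output of [simulate_cohort()].
#' @param config A [pipeline_config()] for the birefringence stage.
#' @return List: `cohort` (measured table, one row per sample-region),
#'   `results` (correlation table from [build_results_table()]), `truth`,
#'   `config`.
#' @export
run_cohort <- function(sim, config = pipeline_config()) {
  stopifnot(is.list(sim), !is.null(sim$truth))
  n <- nrow(sim$truth)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- simulate_jones_volume(sim$volumes[[i]])
    pv <- process_volume(vol, config)
    area <- cross_section_area(boundary = sim$polygons[[i]])
    th <- mean_thickness(area, sim$spec$width_mm)
    rec <- sim$records[[i]]
    ss <- compute_stress_strain(rec)
    fit <- fit_exponential(ss$strain, ss$stress_mpa,
                           stress_datum = rec$pre_load_n / rec$area_mm2)
    e0 <- tangent_modulus(fit, 0)
    rows[[i]] <- data.frame(
      sample_id = sim$truth$sample_id[i], region = sim$truth$region[i],
      mean_birefringence = pv$mean_birefringence,
      tangent_modulus_0 = e0,
      structural_stiffness = structural_stiffness(e0, th),
      power_b = exponential_power(fit),
      thickness = th,
      n_valid_pixels = pv$n_valid,
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, rows)
  list(cohort = cohort, results = build_results_table(cohort),
       truth = sim$truth, config = config)
}
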