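#' Two-sided Pearson correlation test
#'
#' Sample Pearson product-moment correlation with the classical two-sided
#' t test, \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (via [stats::cor.test()]), plus the significance-star convention used in
#' the correlation tables: `*`, `**`, `***` for p strictly below 0.05, 0.01
#' and 0.001, and the ordinary least-squares line for plotting.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite, each with
#'   nonzero variance.
#' @return List of class `correlation_result`: `r`, `p`, `n`, `stars`,
#'   `slope`, `intercept`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  reg <- linear_regression(x, y)
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = n,
         stars = significance_stars(ct$p.value),
         slope = reg$slope, intercept = reg$intercept),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f%s (p = %.4g, n = %d)\n", x$r, x$stars, x$p, x$n))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' `***`, `**`, `*` for p strictly less than 0.001, 0.01, 0.05; otherwise "".
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Ordinary least-squares regression line
#'
#' @param x,y Numeric vectors; `n >= 2` and `x` must vary.
#' @return List with `slope` and `intercept`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::var(x) == 0) stop("degenerate x: zero variance", call. = FALSE)
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Region-by-parameter correlation table
#'
#' Assembles the cohort-level analysis: for every region and every elastic
#' parameter (tangent modulus at 0% strain, structural stiffness, exponential
#' power), the two-sided Pearson test of that parameter against mean
#' birefringence across the samples of the region. No multiple-testing
#' correction is applied by default, mirroring the per-cell reporting of the
#' analysis this package models; `adjust = "holm"` is available as the
#' rigorous opt-in (stars then follow adjusted p-values).
#'
#' @param cohort Data frame with one row per (sample, region) and columns
#'   `sample_id`, `region`, `mean_birefringence`, `tangent_modulus_0`,
#'   `structural_stiffness`, `power_b` (and optionally `thickness`).
#' @param adjust `"none"` (default) or `"holm"`.
#' @param min_n Regions with fewer complete samples are flagged, not tested
#'   (default 3).
#' @return Data frame with one row per region x parameter: `region`,
#'   `parameter`, `n`, `r`, `p`, `stars`, `slope`, `intercept`, `tested`.
#' @export
build_results_table <- function(cohort, adjust = c("none", "holm"), min_n = 3L) {
  adjust <- match.arg(adjust)
  needed <- c("region", "mean_birefringence", "tangent_modulus_0",
              "structural_stiffness", "power_b")
  stopifnot(all(needed %in% names(cohort)))
  params <- c("tangent_modulus_0", "structural_stiffness", "power_b")
  regions <- sort(unique(as.character(cohort$region)))
  rows <- list()
  for (reg in regions) {
    sub <- cohort[cohort$region == reg, , drop = FALSE]
    for (pp in params) {
      ok <- is.finite(sub$mean_birefringence) & is.finite(sub[[pp]])
      if (sum(ok) >= min_n && stats::var(sub$mean_birefringence[ok]) > 0 &&
          stats::var(sub[[pp]][ok]) > 0) {
        ct <- pearson_test(sub$mean_birefringence[ok], sub[[pp]][ok])
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, parameter = pp, n = ct$n, r = ct$r, p = ct$p,
          stars = ct$stars, slope = ct$slope, intercept = ct$intercept,
          tested = TRUE, stringsAsFactors = FALSE
        )
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, parameter = pp, n = sum(ok), r = NA_real_, p = NA_real_,
          stars = "", slope = NA_real_, intercept = NA_real_,
          tested = FALSE, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p_adjusted <- NA_real_
    out$p_adjusted[out$tested] <- stats::p.adjust(out$p[out$tested], method = "holm")
    out$stars <- ifelse(out$tested, significance_stars(out$p_adjusted), "")
  }
  out
}
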