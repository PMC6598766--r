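#' Group summary statistics
#'
#' Mean, standard deviation (unbiased, n-1 denominator) and size of a group
#' of measurements, as consumed by [ssmd()].
#'
#' @param x Numeric vector of measurements.
#' @return A list of class `"zf_group_stats"`: `mu`, `sigma`, `n`.
#' @export
group_stats <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  structure(list(mu = mean(x),
                 sigma = if (length(x) > 1) stats::sd(x) else 0,
                 n = length(x)),
            class = "zf_group_stats")
}

#' Strictly standardised mean difference (SSMD)
#'
#' Effect-size statistic for comparing two screening groups:
#' `beta = (mu1 - mu2) / sqrt(sigma1^2 + sigma2^2)`. Standard deviations use
#' the unbiased (n-1) estimator by default; pass population SDs through
#' `"zf_group_stats"` objects built by hand if required.
#'
#' Degenerate inputs: if both SDs are zero and the means are equal, beta is
#' 0; if both SDs are zero and the means differ, a signed infinity is
#' returned with a warning.
#'
#' @param g1,g2 Numeric vectors of measurements, or `"zf_group_stats"`
#'   objects.
#' @return A list of class `"zf_ssmd"` with element `beta`.
#' @export
#' @examples
#' ssmd(c(1, 2, 3), c(-1, 0, 1))$beta  # 2 / sqrt(2)
ssmd <- function(g1, g2) {
  if (!inherits(g1, "zf_group_stats")) g1 <- group_stats(g1)
  if (!inherits(g2, "zf_group_stats")) g2 <- group_stats(g2)
  denom <- sqrt(g1$sigma^2 + g2$sigma^2)
  beta <- if (denom == 0) {
    if (g1$mu == g2$mu) 0
    else {
      warning("both group SDs are zero with unequal means; returning signed Inf")
      sign(g1$mu - g2$mu) * Inf
    }
  } else {
    (g1$mu - g2$mu) / denom
  }
  structure(list(beta = beta, g1 = g1, g2 = g2), class = "zf_ssmd")
}

#' @export
print.zf_ssmd <- function(x, ...) {
  cat(sprintf("SSMD beta = %.4f  (n1 = %d, n2 = %d)\n", x$beta, x$g1$n, x$g2$n))
  invisible(x)
}

#' Normalised ear-to-ear width
#'
#' Ear-to-ear width of a dorsally mounted embryo expressed relative to head
#' width, removing embryo-size differences. Both measurements are in the
#' same units (micrometres); the ratio is dimensionless and scale-invariant.
#'
#' @param ear_to_ear_width,head_width Positive measurements (um).
#' @return `ear_to_ear_width / head_width`.
#' @export
normalize_ear_width <- function(ear_to_ear_width, head_width) {
  if (any(!is.finite(ear_to_ear_width)) || any(!is.finite(head_width)) ||
      any(ear_to_ear_width <= 0) || any(head_width <= 0)) {
    stop("widths must be positive finite numbers")
  }
  ear_to_ear_width / head_width
}

#' Per-concentration score contingency tables for a dose-response series
#'
#' Tallies, per concentration, the number of live embryos at each staining
#' intensity score (0-3) and at each projection count score (0p-3p). Dead
#' embryos are excluded from the score tables and appear in the survival
#' summary only. A Spearman correlation of mean intensity score against
#' concentration summarises monotonicity of the response.
#'
#' @param series A data.frame with columns `concentration_uM`,
#'   `intensity_score`, `projection_score`, `alive` (logical).
#' @return A list of class `"zf_dose_table"`: `intensity` and `projections`
#'   (concentration x score count matrices), `survival` (data.frame with
#'   `concentration_uM`, `n_total`, `n_dead`), and `spearman_rho`.
#' @export
dose_response_table <- function(series) {
  req <- c("concentration_uM", "intensity_score", "projection_score", "alive")
  stopifnot(all(req %in% names(series)))
  conc <- sort(unique(series$concentration_uM))
  live <- series[series$alive, , drop = FALSE]
  tab <- function(scores, concs) {
    t <- table(factor(concs, levels = conc), factor(scores, levels = 0:3))
    m <- as.matrix(unclass(t))
    dimnames(m) <- list(concentration_uM = as.character(conc),
                        score = colnames(t))
    m
  }
  intensity <- tab(live$intensity_score, live$concentration_uM)
  projections <- tab(live$projection_score, live$concentration_uM)
  colnames(projections) <- paste0(colnames(projections), "p")
  survival <- data.frame(
    concentration_uM = conc,
    n_total = as.integer(table(factor(series$concentration_uM, levels = conc))),
    n_dead = as.integer(table(factor(
      series$concentration_uM[!series$alive], levels = conc)))
  )
  mean_by_conc <- tapply(live$intensity_score, live$concentration_uM, mean)
  rho <- if (length(mean_by_conc) >= 3) {
    suppressWarnings(stats::cor(as.numeric(names(mean_by_conc)),
                                as.numeric(mean_by_conc),
                                method = "spearman"))
  } else {
    NA_real_
  }
  structure(list(intensity = intensity, projections = projections,
                 survival = survival, spearman_rho = rho),
            class = "zf_dose_table")
}

#' @export
print.zf_dose_table <- function(x, ...) {
  cat("Dose-response score counts (intensity):\n")
  print(x$intensity)
  cat(sprintf("Spearman rho (mean intensity vs concentration): %.3f\n",
              x$spearman_rho))
  invisible(x)
}
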