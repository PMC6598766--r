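#' Fit an LD50 dose-response model to embryo survival counts
#'
#' Maximum-likelihood fit of a two-parameter sigmoid (logistic by default,
#' probit optionally) of mortality against log10 concentration, the standard
#' model for acute-toxicity series. LD50 is the concentration at 50%
#' mortality; its confidence interval is obtained by profiling the deviance
#' over the location parameter (reparameterised as
#' `link(p) = slope * (log10(conc) - log10(LD50))`) against the chi-squared
#' 1-df cutoff.
#'
#' @param concentration Concentrations tested (uM), one per row.
#' @param n_total Number of embryos exposed at each concentration.
#' @param n_dead Number of dead embryos at each concentration.
#' @param method `"logistic"` or `"probit"` link.
#' @param level Confidence level for the profile interval.
#' @return An object of class `"ld50_fit"`: `ld50` (uM), `slope` (per log10
#'   unit), `ci_low`/`ci_high` (uM), `method`, `level`, the underlying `glm`
#'   and the data. Supports `print`, `coef`, `confint`, `predict` and
#'   `plot`.
#' @export
#' @examples
#' conc <- 2 * 1.5^(0:7)
#' dead <- c(0, 1, 2, 5, 10, 14, 16, 16)
#' fit <- fit_ld50(conc, rep(16, 8), dead)
#' coef(fit)
fit_ld50 <- function(concentration, n_total, n_dead,
                     method = c("logistic", "probit"), level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(concentration) == length(n_total),
            length(n_total) == length(n_dead),
            all(concentration > 0), all(n_dead <= n_total), all(n_dead >= 0))
  if (all(n_dead == n_total) || all(n_dead == 0)) {
    stop("mortality is saturated (all dead or all alive everywhere); ",
         "LD50 is not identifiable")
  }
  p <- n_dead / n_total
  if (stats::cor(concentration, p) < 0) {
    warning("mortality decreases with concentration overall; ",
            "fit attempted anyway")
  }
  link <- if (method == "logistic") "logit" else "probit"
  x <- log10(concentration)
  fit <- stats::glm(cbind(n_dead, n_total - n_dead) ~ x,
                    family = stats::binomial(link = link))
  b <- stats::coef(fit)
  m_hat <- -b[[1]] / b[[2]]
  ci <- profile_ld50_ci(x, n_total, n_dead, link, m_hat,
                        dev_min = stats::deviance(fit), level = level)
  structure(list(
    ld50 = 10^m_hat, slope = b[[2]],
    ci_low = 10^ci[1], ci_high = 10^ci[2],
    method = method, level = level, glm = fit,
    data = data.frame(concentration = concentration, n_total = n_total,
                      n_dead = n_dead)
  ), class = "ld50_fit")
}

# Profile deviance over m = log10(LD50): for fixed m, maximise the
# likelihood over the slope only, and find where the profile deviance
# crosses the chi-squared cutoff.
profile_ld50_ci <- function(x, n_total, n_dead, link, m_hat, dev_min, level) {
  linkfun <- stats::binomial(link = link)
  dev_at <- function(m) {
    nll <- function(log_slope) {
      eta <- 10^log_slope * (x - m)
      p <- pmin(pmax(linkfun$linkinv(eta), 1e-12), 1 - 1e-12)
      -2 * sum(stats::dbinom(n_dead, n_total, p, log = TRUE))
    }
    # log-slope parameterisation keeps the 1-d optimisation well conditioned
    stats::optimize(nll, c(-3, 3), tol = 1e-8)$objective
  }
  # saturated-model constant so the profile matches glm deviance
  p_obs <- pmin(pmax(n_dead / n_total, 1e-12), 1 - 1e-12)
  sat <- -2 * sum(stats::dbinom(n_dead, n_total, p_obs, log = TRUE))
  cutoff <- dev_min + stats::qchisq(level, df = 1)
  f <- function(m) (dev_at(m) - sat) - cutoff
  span <- diff(range(x)) + 2
  lo <- tryCatch(
    stats::uniroot(f, c(m_hat - span, m_hat), extendInt = "no")$root,
    error = function(e) -Inf)
  hi <- tryCatch(
    stats::uniroot(f, c(m_hat, m_hat + span), extendInt = "no")$root,
    error = function(e) Inf)
  c(lo, hi)
}

#' @export
print.ld50_fit <- function(x, ...) {
  cat(sprintf("LD50 fit (%s on log10 concentration)\n", x$method))
  cat(sprintf("  LD50 = %.3g uM  [%.0f%% profile CI %.3g, %.3g]\n",
              x$ld50, 100 * x$level, x$ci_low, x$ci_high))
  cat(sprintf("  slope = %.3f per log10 unit; %d concentrations, %d embryos\n",
              x$slope, nrow(x$data), sum(x$data$n_total)))
  invisible(x)
}

#' @export
coef.ld50_fit <- function(object, ...) {
  c(ld50 = object$ld50, slope = object$slope)
}

#' @export
confint.ld50_fit <- function(object, parm = "ld50", level = NULL, ...) {
  c(low = object$ci_low, high = object$ci_high)
}

#' @export
predict.ld50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else newdata$concentration
  stats::predict(object$glm, data.frame(x = log10(conc)), type = "response")
}

#' @export
plot.ld50_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration, d$n_dead / d$n_total, log = "x",
                 xlab = "concentration (uM)", ylab = "mortality",
                 ylim = c(0, 1), pch = 16, ...)
  grid_c <- exp(seq(log(min(d$concentration)), log(max(d$concentration)),
                    length.out = 100))
  graphics::lines(grid_c, predict(x, data.frame(concentration = grid_c)))
  graphics::abline(h = 0.5, v = x$ld50, lty = 3)
  invisible(x)
}

#' Simulate a mortality dose-response series
#'
#' Draws binomial death counts from a logistic dose-response at a known
#' LD50 and slope -- the standard design of 16 embryos per concentration on
#' a 1.5-fold dilution series -- for validating [fit_ld50()] by parameter
#' recovery.
#'
#' @param true_ld50 True LD50 (uM).
#' @param slope True slope per log10 concentration unit.
#' @param concentrations Concentrations tested; default 8-point 1.5-fold
#'   series anchored so the middle of the series sits near `true_ld50`.
#' @param n_per_conc Embryos per concentration.
#' @param seed Integer seed.
#' @return A data.frame `concentration`, `n_total`, `n_dead`.
#' @export
simulate_ld50_series <- function(true_ld50 = 10, slope = 2,
                                 concentrations = true_ld50 * 1.5^(-4:3),
                                 n_per_conc = 16L, seed = 1L) {
  p <- stats::plogis(slope * (log10(concentrations) - log10(true_ld50)))
  dead <- with_seed(seed, stats::rbinom(length(p), n_per_conc, p))
  data.frame(concentration = concentrations,
             n_total = n_per_conc, n_dead = dead)
}

#' Write an LD50 fit report as JSON
#'
#' @param fit An `"ld50_fit"`.
#' @param path Output path.
#' @export
write_ld50_report <- function(fit, path) {
  stopifnot(inherits(fit, "ld50_fit"))
  jsonlite::write_json(list(
    ld50 = fit$ld50, slope = fit$slope,
    ci_low = fit$ci_low, ci_high = fit$ci_high,
    method = fit$method, level = fit$level,
    n_per_concentration = fit$data$n_total,
    concentrations = fit$data$concentration
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
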