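#' Fit the median-effect model to a dose-response table
#'
#' The median-effect equation fa/fu = (D/Dm)^m (fu = 1 - fa) is linear in
#' log-logit coordinates: log10(fa/(1-fa)) = m*log10(D) - m*log10(Dm). The
#' fit is ordinary least squares on the transformed points; Dm (the
#' median-effect dose, i.e. the IC50) and m (the sigmoidicity of the curve)
#' are read off the line, and r is the correlation coefficient of the
#' transformed points (with exactly two points the line interpolates and r
#' is reported as 1).
#'
#' @param table a \code{\link{dose_response}} table (or a data.frame with
#'   columns \code{dose}, \code{fa})
#' @return object of class \code{median_effect}: \code{Dm}, \code{m},
#'   \code{r}, \code{n_points}, \code{drug_label}, plus the underlying
#'   \code{lm} fit
#' @export
median_effect <- function(table) {
  if (!inherits(table, "dose_response"))
    table <- dose_response(table$dose, table$fa)
  x <- log10(table$dose)
  y <- log10(table$fa / (1 - table$fa))
  if (stats::sd(x) == 0) stop("zero dose variance: cannot fit a median-effect line")
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  if (!is.finite(m) || abs(m) < 1e-12)
    stop("flat dose-response (m = 0): median-effect model undefined")
  r <- if (length(x) == 2L) 1 else stats::cor(x, y)
  structure(list(Dm = 10^(-b / m), m = m, r = r,
                 n_points = length(x),
                 drug_label = attr(table, "drug_label") %||% "",
                 lm = fit, data = data.frame(dose = table$dose, fa = table$fa)),
            class = "median_effect")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.median_effect <- function(x, digits = 4, ...) {
  cat("Median-effect fit",
      if (nzchar(x$drug_label)) paste0(" (", x$drug_label, ")"), ":\n", sep = "")
  cat("  Dm (IC50) =", signif(x$Dm, digits),
      "  m =", signif(x$m, digits),
      "  r =", signif(x$r, digits),
      "  [", x$n_points, "points ]\n")
  invisible(x)
}

#' @export
summary.median_effect <- function(object, ...) {
  out <- list(fit = object, lm_summary = summary(object$lm))
  class(out) <- "summary.median_effect"
  out
}

#' @export
print.summary.median_effect <- function(x, ...) {
  print(x$fit)
  cat("\nLeast squares on log10(fa/fu) ~ log10(dose):\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.median_effect <- function(object, ...) c(Dm = object$Dm, m = object$m)

#' @export
residuals.median_effect <- function(object, ...) stats::residuals(object$lm)

#' Predicted fraction affected at given doses
#' @param object a \code{median_effect} fit
#' @param dose positive doses; defaults to the fitted doses
#' @param ... unused
#' @return fractions affected in (0,1)
#' @export
predict.median_effect <- function(object, dose = object$data$dose, ...) {
  if (any(dose <= 0)) stop("doses must be > 0")
  ratio <- (dose / object$Dm)^object$m
  ratio / (1 + ratio)
}

#' @export
plot.median_effect <- function(x, ...) {
  lx <- log10(x$data$dose)
  ly <- log10(x$data$fa / (1 - x$data$fa))
  plot(lx, ly, xlab = "log10 dose", ylab = "log10(fa/fu)",
       main = paste("Median-effect plot", x$drug_label), ...)
  graphics::abline(x$lm, lty = 2)
  invisible(x)
}

#' Dose producing a given effect level
#'
#' Inverts the median-effect equation: D = Dm * (fa/(1-fa))^(1/m).
#' @param fit a \code{\link{median_effect}} fit
#' @param fa effect level(s) strictly inside (0,1)
#' @return dose(s)
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0,1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Dose-reduction index
#'
#' Fold-reduction of a drug's dose achievable in combination for the same
#' effect as the drug alone: DRI = D_alone / D_combo.
#' @param d_alone single-agent dose for the effect level
#' @param d_combo the drug's dose within the combination for the same effect
#' @return DRI (> 1 means the combination spares dose)
#' @export
compute_dri <- function(d_alone, d_combo) {
  if (any(d_alone <= 0) || any(d_combo <= 0)) stop("doses must be > 0")
  d_alone / d_combo
}

#' Combination index from two dose-reduction indexes
#'
#' Two-term (mutually exclusive) combination index:
#' CI = D_A,combo/D_A,alone + D_B,combo/D_B,alone = 1/DRI_A + 1/DRI_B.
#' @param dri_a,dri_b dose-reduction indexes of the two drugs
#' @return CI (< 1 synergism, = 1 additive, > 1 antagonism)
#' @export
compute_ci <- function(dri_a, dri_b) {
  if (any(dri_a <= 0) || any(dri_b <= 0)) stop("DRI values must be > 0")
  1 / dri_a + 1 / dri_b
}

#' Classify a combination index
#' @param ci combination index (> 0)
#' @param tol half-width of the additive band (default 0.02)
#' @return one of \code{"synergism"}, \code{"additive"}, \code{"antagonism"}
#' @export
classify_synergy <- function(ci, tol = 0.02) {
  if (any(ci <= 0)) stop("CI must be > 0")
  ifelse(abs(ci - 1) <= tol, "additive",
         ifelse(ci < 1, "synergism", "antagonism"))
}

#' CI and DRI across effect levels for a fixed-ratio combination
#'
#' Assumes the combination was assayed at a fixed molar ratio and fitted on
#' total dose: for each effect level the total combination dose comes from
#' \code{fit_combo} and is split into component doses by \code{ratio_a};
#' single-agent doses come from \code{fit_a}/\code{fit_b}; DRIs and the CI
#' follow.
#'
#' @param fit_a,fit_b,fit_combo \code{\link{median_effect}} fits of drug A,
#'   drug B, and the fixed-ratio combination (total dose vs fa)
#' @param ratio_a fraction of drug A in the combination dose, in (0,1]
#' @param levels effect levels to evaluate (default 0.25, 0.50, 0.75)
#' @param tol additive-call tolerance passed to \code{\link{classify_synergy}}
#' @return data.frame of class \code{synergy_curve}: one row per level with
#'   single-agent doses, component combination doses, DRIs, CI and the call
#' @export
synergy_curve <- function(fit_a, fit_b, fit_combo, ratio_a,
                          levels = c(0.25, 0.5, 0.75), tol = 0.02) {
  stopifnot(inherits(fit_a, "median_effect"), inherits(fit_b, "median_effect"),
            inherits(fit_combo, "median_effect"))
  if (ratio_a <= 0 || ratio_a > 1) stop("ratio_a must be in (0, 1]")
  rows <- lapply(levels, function(fa) {
    d_total <- dose_for_effect(fit_combo, fa)
    d_a_combo <- ratio_a * d_total
    d_b_combo <- (1 - ratio_a) * d_total
    d_a_alone <- dose_for_effect(fit_a, fa)
    d_b_alone <- dose_for_effect(fit_b, fa)
    dri_a <- compute_dri(d_a_alone, d_a_combo)
    # ratio_a = 1 degenerates to a single-agent comparison: CI = 1/dri_a
    dri_b <- if (d_b_combo > 0) compute_dri(d_b_alone, d_b_combo) else Inf
    ci <- if (is.finite(dri_b)) compute_ci(dri_a, dri_b) else 1 / dri_a
    data.frame(effect_level = fa,
               d_a_alone = d_a_alone, d_b_alone = d_b_alone,
               d_a_combo = d_a_combo, d_b_combo = d_b_combo,
               dri_a = dri_a, dri_b = dri_b, ci = ci,
               call = classify_synergy(ci, tol = tol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("synergy_curve", "data.frame")
  out
}

#' @export
print.synergy_curve <- function(x, digits = 4, ...) {
  cat("Combination index by effect level:\n")
  show <- data.frame(fa = x$effect_level,
                     DRI_A = signif(x$dri_a, digits),
                     DRI_B = signif(x$dri_b, digits),
                     CI = signif(x$ci, digits),
                     call = x$call)
  print(show, row.names = FALSE)
  invisible(x)
}
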