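# Weighted Nelson-Aalen cumulative hazard -> cumulative risk with
# delta-method pointwise Wald confidence limits on the identity scale.

# exact 97.5% normal quantile; 1.959964... rather than 1.96 so that results
# are reproducible to full precision (pass z = qnorm(0.975) replacements via
# the conf_level argument if 1.96 mimicry is wanted)
.z975 <- function(conf_level = 0.95) stats::qnorm(1 - (1 - conf_level) / 2)

new_risk_curve <- function(times, risk, se, kind, conf_level = 0.95,
                           at_risk = NULL, events = NULL, fit = NULL,
                           variance = NULL) {
  z <- .z975(conf_level)
  structure(
    list(times = times, risk = risk, se = se,
         cl_lower = risk - z * se, cl_upper = risk + z * se,
         at_risk = at_risk, events = events, kind = kind,
         conf_level = conf_level, z = z, variance = variance, fit = fit),
    class = "risk_curve"
  )
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("<risk_curve> kind = %s, %d time points, %.0f%% identity-scale Wald limits\n",
              x$kind, length(x$times), 100 * x$conf_level))
  if (length(x$times) > 0L) {
    k <- length(x$times)
    cat(sprintf("  risk %.4f at t = %.3g rising to %.4f at t = %.3g\n",
                x$risk[1L], x$times[1L], x$risk[k], x$times[k]))
  }
  invisible(x)
}

#' Weighted Nelson-Aalen cumulative risk curve
#'
#' At each distinct event time `t_i` with weighted event count `d_i` and
#' weighted at-risk count `Y_i` (the sum of case weights over subjects with
#' follow-up time `>= t_i`, so that subjects censored exactly at `t_i`
#' still count as at risk — events precede censorings in ties), the
#' cumulative hazard is `H(t_i) = sum_{j <= i} d_j / Y_j` with
#' Poisson-type variance `V(t_i) = sum_{j <= i} d_j / Y_j^2`. Cumulative
#' risk is `F = 1 - exp(-H)`; the delta-method standard error is
#' `SE(F) = exp(-H) * sqrt(V)`, and the pointwise confidence limits are
#' `F +/- z * SE(F)` on the identity scale (not log-log transformed, not
#' clipped).
#'
#' Both `H` and `F` are invariant to multiplying every weight by a common
#' constant `c > 0`, while every standard error is divided by `sqrt(c)`.
#' This exact scaling law is what makes uniform ghost weighting a pure
#' precision dial: see [apply_ghost_weights()].
#'
#' @param cohort A [cohort()] with at least one event.
#' @param conf_level Confidence level for the pointwise limits.
#' @return A `risk_curve` of kind `"nonparametric"` with components
#'   `times`, `risk`, `se`, `cl_lower`, `cl_upper`, `at_risk`, `events`.
#' @export
#' @examples
#' co <- cohort(time = c(1, 2, 3), event = c(1, 0, 1))
#' nelson_aalen_curve(co)
nelson_aalen_curve <- function(cohort, conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort"))
  tt <- cohort$time
  ev <- cohort$event
  w <- cohort$weight
  if (sum(ev) == 0L) stop("no event times in cohort", call. = FALSE)

  et <- sort(unique(tt[ev == 1L]))
  grp <- match(tt[ev == 1L], et)
  d <- as.vector(rowsum(w[ev == 1L], grp))          # weighted events per time
  Y <- vapply(et, function(t0) sum(w[tt >= t0]), numeric(1))  # weighted at risk

  H <- cumsum(d / Y)
  V <- cumsum(d / Y^2)
  risk <- -expm1(-H)
  se <- exp(-H) * sqrt(V)

  new_risk_curve(times = et, risk = risk, se = se, kind = "nonparametric",
                 conf_level = conf_level, at_risk = Y, events = d,
                 variance = "poisson")
}

#' Evaluate a step risk curve at a time point
#'
#' Right-continuous step evaluation: returns the values at the largest
#' event time `<= t`, and an all-zero quadruple for `t` before the first
#' event time.
#'
#' @param curve A `risk_curve` (step interpretation; for parametric curves
#'   prefer evaluating [parametric_risk_curve()] at the times of interest).
#' @param t A single non-negative time.
#' @return Named numeric vector `(risk, se, cl_lower, cl_upper)`.
#' @export
risk_at <- function(curve, t) {
  stopifnot(inherits(curve, "risk_curve"), length(t) == 1L, is.finite(t))
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  i <- findInterval(t, curve$times)
  if (i == 0L) {
    return(c(risk = 0, se = 0, cl_lower = 0, cl_upper = 0))
  }
  c(risk = curve$risk[i], se = curve$se[i],
    cl_lower = curve$cl_lower[i], cl_upper = curve$cl_upper[i])
}
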