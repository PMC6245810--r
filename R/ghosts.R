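# Pseudo-observation ("ghost") augmentation: fictitious observations are
# added to a cohort of nominal size N as a uniform case-weight increment of
# 1/N per ghost, so that M ghosts give every real subject weight (N + M)/N.
# The Nelson-Aalen risk estimate is exactly invariant to a uniform weight
# rescaling while every standard error shrinks by sqrt((N + M)/N); ghosts
# therefore dial precision without perturbing the shape of the risk curve.
# The ghost count at which the weighted nonparametric confidence-limit
# width first drops strictly below a parametric model's width measures the
# hidden observations implied by that model's form assumptions.

#' Spread ghost pseudo-observations uniformly over a cohort
#'
#' Multiplies every case weight by `(N + m) / N`, where `N` is the cohort's
#' nominal size — the weighted realization of adding `m` pseudo-observations
#' spread equally over the real subjects (each original observation's
#' weight grows by `1/N` per ghost, so weight 2 when the sample has been
#' doubled). The risk curve of the result is identical to the original;
#' every standard error is divided by `sqrt(1 + m/N)` exactly.
#'
#' @param cohort A [cohort()] with a uniform base weight.
#' @param m Number of pseudo-observations, integer `>= 0`.
#' @return The reweighted [cohort()] (same `n_nominal`).
#' @export
apply_ghost_weights <- function(cohort, m) {
  stopifnot(inherits(cohort, "cohort"), length(m) == 1L, is.finite(m))
  if (m < 0 || m != floor(m)) stop("m must be a non-negative integer", call. = FALSE)
  if (diff(range(cohort$weight)) != 0) {
    stop("ghost weighting requires a uniform base weight", call. = FALSE)
  }
  out <- cohort
  out$weight <- cohort$weight * (cohort$n_nominal + m) / cohort$n_nominal
  out
}

#' Confidence-limit width after ghost augmentation
#'
#' The exact scaling law for a uniform weight increase: a width `width0` at
#' `m = 0` becomes `width0 / sqrt(1 + m / n_nominal)` after `m` ghosts.
#'
#' @param width0 Baseline confidence-limit width(s), positive.
#' @param m Ghost count(s), non-negative (vectorized).
#' @param n_nominal Nominal sample size N.
#' @return Scaled width(s).
#' @export
ghost_scaled_width <- function(width0, m, n_nominal) {
  width0 / sqrt(1 + m / n_nominal)
}

# shared strict-inequality stopping predicate: < target, never <=
.ghost_done <- function(width0, m, n_nominal, target_width) {
  ghost_scaled_width(width0, m, n_nominal) < target_width
}

.as_count <- function(m) if (m <= .Machine$integer.max) as.integer(m) else round(m)

#' Closed-form minimal ghost count
#'
#' The smallest integer `M >= 0` with
#' `width0 / sqrt(1 + M/N) < target_width` (strict). The analytic solution
#' `N * ((width0/target)^2 - 1)` locates the boundary, but the returned
#' value is decided by direct evaluation of the stopping predicate at the
#' neighbouring integers, never by the formula alone, so exact-equality
#' boundaries (where equality must not stop the search) come out right.
#'
#' @param width0 Baseline (unweighted) width, positive.
#' @param target_width Width to undercut, positive.
#' @param n_nominal Nominal sample size N, positive integer.
#' @return Integer-valued ghost count `M`.
#' @export
#' @examples
#' closed_form_ghosts(0.10, 0.05, 100)  # equality at M = 300 does not stop: 301
closed_form_ghosts <- function(width0, target_width, n_nominal) {
  if (!is.finite(width0) || width0 <= 0) stop("width0 must be positive", call. = FALSE)
  if (!is.finite(target_width) || target_width <= 0) {
    stop("target_width must be positive", call. = FALSE)
  }
  if (!is.finite(n_nominal) || n_nominal < 1 || n_nominal != floor(n_nominal)) {
    stop("n_nominal must be a positive integer", call. = FALSE)
  }
  if (.ghost_done(width0, 0, n_nominal, target_width)) return(0L)
  m_star <- n_nominal * ((width0 / target_width)^2 - 1)
  cand <- max(0, floor(m_star) - 1) : (floor(m_star) + 2)
  ok <- .ghost_done(width0, cand, n_nominal, target_width)
  if (!any(ok)) stop("no candidate ghost count satisfies the predicate", call. = FALSE)
  .as_count(cand[which(ok)[1L]])
}

#' One-by-one ghost search on a known baseline width
#'
#' Walks `M = 0, 1, 2, ...`, evaluating the scaled width at every step
#' (chunked for speed, but every integer is tested in order), and returns
#' the first `M` whose width is strictly below the target. Agrees with
#' [closed_form_ghosts()] by construction; kept as the faithful stepwise
#' reference path.
#'
#' @inheritParams closed_form_ghosts
#' @param max_m Sanity ceiling on the search (the width always reaches any
#'   positive target eventually, so this only guards absurd inputs).
#' @return Integer-valued ghost count `M`.
#' @export
ghost_search_stepwise <- function(width0, target_width, n_nominal, max_m = 1e8) {
  if (!is.finite(width0) || width0 <= 0) stop("width0 must be positive", call. = FALSE)
  if (!is.finite(target_width) || target_width <= 0) {
    stop("target_width must be positive", call. = FALSE)
  }
  chunk <- 1024L
  lo <- 0
  while (lo <= max_m) {
    mm <- lo:min(lo + chunk - 1, max_m)
    ok <- .ghost_done(width0, mm, n_nominal, target_width)
    if (any(ok)) return(.as_count(mm[which(ok)[1L]]))
    lo <- lo + chunk
  }
  stop(sprintf("ghost search exceeded the sanity ceiling max_m = %g", max_m),
       call. = FALSE)
}

#' Minimal ghost count for a cohort to undercut a target width
#'
#' Computes the nonparametric Nelson-Aalen confidence-limit width at
#' `eval_time`, then finds the smallest ghost count `M` at which the
#' uniformly reweighted nonparametric width drops strictly below
#' `target_width`. The default path exploits the exact scaling law (the
#' risk estimate is weight-invariant, so no refit can change it);
#' `method = "refit"` literally re-runs the Nelson-Aalen estimator after
#' each added ghost as a validation mode. Both paths are checked against
#' [closed_form_ghosts()].
#'
#' @param cohort A [cohort()] with uniform base weights and at least one
#'   event at or before `eval_time`.
#' @param target_width Parametric confidence-limit width to undercut,
#'   positive.
#' @param eval_time Time point (years) at which widths are compared.
#' @param method `"scaling"` (exact, default) or `"refit"` (slow stepwise
#'   re-estimation, for validation).
#' @param trajectory Record the `(M, width)` sequence.
#' @param max_m Sanity ceiling for the search.
#' @return An object of class `ghost_result` with elements `m`,
#'   `n_nominal`, `weight` (= `1 + m/n_nominal`), `width0`,
#'   `target_width`, `achieved_width`, `eval_time`, and optionally
#'   `trajectory`.
#' @export
find_ghosts <- function(cohort, target_width, eval_time,
                        method = c("scaling", "refit"), trajectory = FALSE,
                        max_m = 1e8) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  if (!is.finite(target_width) || target_width <= 0) {
    stop("target_width must be positive", call. = FALSE)
  }
  if (diff(range(cohort$weight)) != 0) {
    stop("ghost search requires a uniform base weight", call. = FALSE)
  }
  n <- cohort$n_nominal
  base <- nelson_aalen_curve(cohort)
  v0 <- risk_at(base, eval_time)
  width0 <- v0[["cl_upper"]] - v0[["cl_lower"]]
  if (width0 <= 0) {
    stop("nonparametric width undefined at eval_time (no events yet)", call. = FALSE)
  }

  m_ref <- closed_form_ghosts(width0, target_width, n)
  traj <- NULL
  if (method == "refit") {
    widths <- numeric(0)
    m <- 0L
    repeat {
      cv <- nelson_aalen_curve(apply_ghost_weights(cohort, m))
      vv <- risk_at(cv, eval_time)
      wd <- vv[["cl_upper"]] - vv[["cl_lower"]]
      widths <- c(widths, wd)
      if (wd < target_width) break
      m <- m + 1L
      if (m > max_m) stop("refit ghost search exceeded max_m", call. = FALSE)
    }
    if (m != m_ref) {
      stop(sprintf("stepwise refit (M = %d) disagrees with the closed form (M = %d)",
                   m, m_ref), call. = FALSE)
    }
    achieved <- widths[length(widths)]
    if (trajectory) traj <- data.frame(m = 0:m, width = widths)
  } else {
    m <- ghost_search_stepwise(width0, target_width, n, max_m = max_m)
    if (m != m_ref) {
      stop(sprintf("stepwise search (M = %d) disagrees with the closed form (M = %d)",
                   m, m_ref), call. = FALSE)
    }
    achieved <- ghost_scaled_width(width0, m, n)
    if (trajectory) {
      traj <- data.frame(m = 0:m, width = ghost_scaled_width(width0, 0:m, n))
    }
  }

  structure(
    list(m = m, n_nominal = n, weight = 1 + m / n, width0 = width0,
         target_width = target_width, achieved_width = achieved,
         eval_time = eval_time, method = method, trajectory = traj),
    class = "ghost_result"
  )
}

#' @export
print.ghost_result <- function(x, ...) {
  cat("<ghost_result>\n")
  cat(sprintf("  M = %d pseudo-observations over N = %d (uniform weight %.6f)\n",
              x$m, x$n_nominal, x$weight))
  cat(sprintf("  width at t = %.3g: %.6f (M = 0) -> %.6f, target %.6f\n",
              x$eval_time, x$width0, x$achieved_width, x$target_width))
  invisible(x)
}
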