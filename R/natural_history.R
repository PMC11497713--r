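#' Natural-history trajectory of CDR-SB
#'
#' A natural-history trajectory maps disease time -- years since crossing the
#' amyloid-PET positivity threshold (24.1 Centiloids) -- to the mean CDR-SB
#' score of an untreated patient. The trajectory is stored as knot points and
#' interpolated with a natural cubic spline; if the natural spline is not
#' non-decreasing between the knots, a monotone cubic (Fritsch-Carlson)
#' interpolant is used instead, because downstream anchoring and milestone
#' computations require an invertible (monotone) curve.
#'
#' Outside the knot range the curve is extended by a constant at the first
#' knot score before the first knot (a pre-positivity patient cannot be less
#' progressed than the trajectory start on the CDR-SB axis) and linearly with
#' the end slope after the last knot, clipped to the CDR-SB range \[0, 18\].
#' Evaluation is supported on the window \[first knot - 2, last knot + 5\]
#' years.
#'
#' @param data A data frame of knot points.
#' @param time,score Names of the columns holding disease time (years since
#'   amyloid positivity) and mean CDR-SB score. Defaults match the on-disk
#'   schema (`time_years`, `cdr_sb`).
#' @param interpolation `"natural"` to attempt a natural cubic spline with a
#'   monotone fallback, or `"monotone"` to request Fritsch-Carlson monotone
#'   cubic interpolation directly (no warning).
#' @return An object of class `nh_trajectory`.
#' @examples
#' traj <- nh_trajectory(data.frame(time_years = c(0, 5, 10), cdr_sb = c(0, 1, 4)))
#' nh_evaluate(traj, c(2.5, 7.5))
#' @export
nh_trajectory <- function(data, time = "time_years", score = "cdr_sb",
                          interpolation = c("natural", "monotone")) {
  interpolation <- match.arg(interpolation)
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of trajectory knot points.")
  }
  for (col in c(time, score)) {
    if (!col %in% names(data)) {
      abort(paste0("Column `", col, "` not found in `data`."))
    }
  }
  t <- as.numeric(data[[time]])
  s <- as.numeric(data[[score]])
  if (length(t) < 2) abort("A trajectory needs at least two knot points.")
  if (anyNA(t) || anyNA(s) || any(!is.finite(t)) || any(!is.finite(s))) {
    abort("Trajectory knots must be finite and non-missing.")
  }
  ord <- order(t)
  t <- t[ord]; s <- s[ord]
  if (any(diff(t) <= 0)) abort("Knot times must be strictly increasing.")
  if (any(s < 0 | s > 18)) abort("Knot scores must lie in [0, 18].")
  if (any(diff(s) < 0)) abort("Knot scores must be non-decreasing.")

  method <- if (interpolation == "monotone") "monoH.FC" else "natural"
  fun <- splinefun(t, s, method = method)
  if (method == "natural" && !.is_nondecreasing(fun, range(t))) {
    warn(paste(
      "Natural cubic spline through the supplied knots has a decreasing",
      "segment; falling back to monotone (Fritsch-Carlson) interpolation."
    ))
    method <- "monoH.FC"
    fun <- splinefun(t, s, method = method)
  }

  structure(
    list(
      knot_times = t,
      knot_scores = s,
      interpolation = if (method == "natural") "natural" else "monotone",
      fun = fun
    ),
    class = "nh_trajectory"
  )
}

# Derivative check on a fine grid; tolerance absorbs round-off in the
# spline evaluation, not genuine non-monotonicity.
.is_nondecreasing <- function(fun, rng, n = 2001) {
  g <- seq(rng[1], rng[2], length.out = n)
  min(fun(g, deriv = 1)) >= -1e-8
}

.nh_window <- function(traj) {
  c(traj$knot_times[1] - 2, traj$knot_times[length(traj$knot_times)] + 5)
}

#' Evaluate a natural-history trajectory
#'
#' Returns the mean CDR-SB score at disease time `t` (years since amyloid-PET
#' positivity), applying the extrapolation rules described in
#' [nh_trajectory()] and clipping to \[0, 18\].
#'
#' @param traj An [nh_trajectory()].
#' @param t Numeric vector of disease times in years, within
#'   \[first knot - 2, last knot + 5\].
#' @return Numeric vector of mean CDR-SB scores.
#' @export
nh_evaluate <- function(traj, t) {
  stopifnot(inherits(traj, "nh_trajectory"))
  if (length(t) == 0) return(numeric(0))
  if (anyNA(t) || any(!is.finite(t))) {
    abort("Evaluation times must be finite and non-missing.")
  }
  win <- .nh_window(traj)
  if (any(t < win[1] - 1e-9 | t > win[2] + 1e-9)) {
    abort(sprintf(
      "Evaluation time outside the supported window [%.3f, %.3f] years.",
      win[1], win[2]
    ))
  }
  kt <- traj$knot_times
  ks <- traj$knot_scores
  first_t <- kt[1]; last_t <- kt[length(kt)]
  end_slope <- traj$fun(last_t, deriv = 1)
  out <- numeric(length(t))
  below <- t < first_t
  above <- t > last_t
  mid <- !below & !above
  out[below] <- ks[1]
  out[mid] <- traj$fun(t[mid])
  out[above] <- ks[length(ks)] + end_slope * (t[above] - last_t)
  pmin(18, pmax(0, out))
}

#' @export
predict.nh_trajectory <- function(object, t, ...) nh_evaluate(object, t)

#' Invert a natural-history trajectory
#'
#' Returns the earliest disease time at which the trajectory attains a given
#' CDR-SB score (flat segments resolve to their earliest time). Used to
#' anchor trial baselines on the disease timeline and to compute milestone
#' times. The search runs from the first knot to 5 years past the last knot
#' by bisection to 1e-8 years.
#'
#' @param traj An [nh_trajectory()].
#' @param score Numeric vector of CDR-SB scores within the trajectory's
#'   achieved range.
#' @return Numeric vector of disease times in years.
#' @export
nh_invert <- function(traj, score) {
  stopifnot(inherits(traj, "nh_trajectory"))
  if (anyNA(score) || any(!is.finite(score))) {
    abort("Scores must be finite and non-missing.")
  }
  lo_t <- traj$knot_times[1]
  hi_t <- .nh_window(traj)[2]
  lo_s <- traj$knot_scores[1]
  hi_s <- nh_evaluate(traj, hi_t)
  vapply(score, function(sc) {
    if (sc < lo_s - 1e-9 || sc > hi_s + 1e-9) {
      abort(sprintf(
        "Score %.4g is outside the achievable CDR-SB interval [%.4g, %.4g].",
        sc, lo_s, hi_s
      ))
    }
    sc <- min(max(sc, lo_s), hi_s)
    lo <- lo_t; hi <- hi_t
    if (nh_evaluate(traj, lo) >= sc) return(lo)
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (nh_evaluate(traj, mid) >= sc) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

#' Time from a disease stage to a CDR-SB milestone
#'
#' @param traj An [nh_trajectory()].
#' @param start_time Disease time (years since amyloid positivity) at which
#'   the clock starts.
#' @param milestone CDR-SB milestone score; 16 is the severe-dementia
#'   threshold used throughout.
#' @return Years from `start_time` until the trajectory reaches `milestone`.
#' @export
time_to_milestone <- function(traj, start_time, milestone = 16) {
  stopifnot(inherits(traj, "nh_trajectory"), length(start_time) == 1)
  current <- nh_evaluate(traj, start_time)
  if (milestone < current - 1e-6) {
    abort(sprintf(
      "Milestone %.4g is below the score %.4g already reached at start_time.",
      milestone, current
    ))
  }
  max(0, nh_invert(traj, milestone) - start_time)
}

#' Shift a trajectory along the time axis
#'
#' `nh_shift(traj, delta)` returns a trajectory with
#' `evaluate(shifted, t) == evaluate(traj, t - delta)`: positive `delta`
#' moves the whole curve toward later disease times. Used to match the
#' extrapolated natural history to a trial's placebo arm at the final visit.
#'
#' @param traj An [nh_trajectory()].
#' @param delta Shift in years.
#' @return A shifted [nh_trajectory()].
#' @export
nh_shift <- function(traj, delta) {
  stopifnot(inherits(traj, "nh_trajectory"), length(delta) == 1, is.finite(delta))
  nh_trajectory(
    data.frame(time_years = traj$knot_times + delta, cdr_sb = traj$knot_scores),
    interpolation = traj$interpolation
  )
}

#' @export
print.nh_trajectory <- function(x, ...) {
  cat(sprintf(
    "<nh_trajectory> %d knots over [%.2f, %.2f] years since amyloid positivity\n",
    length(x$knot_times), x$knot_times[1], x$knot_times[length(x$knot_times)]
  ))
  cat(sprintf(
    "  CDR-SB range [%.2f, %.2f]; interpolation: %s\n",
    x$knot_scores[1], x$knot_scores[length(x$knot_scores)], x$interpolation
  ))
  invisible(x)
}

#' @method tidy nh_trajectory
#' @export
tidy.nh_trajectory <- function(x, ...) {
  tibble(time_years = x$knot_times, cdr_sb = x$knot_scores)
}

#' Read and write trajectory files
#'
#' The on-disk trajectory format is JSON with fields `time_years`, `cdr_sb`
#' and (optionally) `positivity_threshold_centiloids`; a two-column CSV
#' (`time_years,cdr_sb`) is also accepted. Knot spacing of 0.5 years or less
#' keeps the interpolation error negligible regardless of the basis in which
#' the curve was originally estimated.
#'
#' @param path File path (`.json` or `.csv`).
#' @param traj An [nh_trajectory()] to serialize.
#' @param interpolation Passed to [nh_trajectory()] when reading.
#' @return `read_trajectory()` returns an [nh_trajectory()];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path, interpolation = c("natural", "monotone")) {
  interpolation <- match.arg(interpolation)
  if (!file.exists(path)) abort(paste0("Trajectory file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$time_years) || is.null(obj$cdr_sb)) {
      abort("Trajectory JSON must contain `time_years` and `cdr_sb` arrays.")
    }
    df <- data.frame(time_years = obj$time_years, cdr_sb = obj$cdr_sb)
  } else {
    df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE))
    if (ncol(df) < 2) abort("Trajectory CSV must have two columns: time, score.")
    names(df)[1:2] <- c("time_years", "cdr_sb")
  }
  nh_trajectory(df, interpolation = interpolation)
}

#' @rdname read_trajectory
#' @param positivity_threshold_centiloids Amyloid-PET threshold recorded in
#'   the JSON for provenance; time 0 of the trajectory is the crossing of
#'   this threshold.
#' @export
write_trajectory <- function(traj, path, positivity_threshold_centiloids = 24.1) {
  stopifnot(inherits(traj, "nh_trajectory"))
  jsonlite::write_json(
    list(
      time_years = traj$knot_times,
      cdr_sb = traj$knot_scores,
      positivity_threshold_centiloids = positivity_threshold_centiloids
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
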