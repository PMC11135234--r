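#' Classify the shape of a survey curve
#'
#' Returns the monotone trend (from the sign of `y[n] - y[1]`) and the
#' convexity, judged from the predominant side of the chord joining the two
#' endpoints on which the interior points fall: below the chord is convex,
#' above is concave. An RSS-versus-rank survey is typically
#' convex decreasing.
#'
#' @param x strictly increasing abscissas (ranks).
#' @param y curve values.
#' @return list with elements `convexity` (`"convex"`/`"concave"`) and
#'   `trend` (`"increasing"`/`"decreasing"`).
#' @export
check_curve <- function(x, y) {
  validate_curve(x, y)
  n <- length(x)
  if (diff(range(y)) == 0)
    stop("degenerate curve: y is constant", call. = FALSE)
  trend <- if (y[n] >= y[1L]) "increasing" else "decreasing"
  dev <- y - chord_line(x, y)       # negative below the chord
  dev <- dev[-c(1L, n)]
  tol <- 1e-12 * max(abs(y))
  below <- sum(dev < -tol); above <- sum(dev > tol)
  convexity <- if (below > above) "convex"
    else if (above > below) "concave"
    else if (sum(dev) <= 0) "convex" else "concave"
  list(convexity = convexity, trend = trend)
}

validate_curve <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 4L)
    stop("knee detection needs at least 4 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("curve contains non-finite values", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("x must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

chord_line <- function(x, y) {
  n <- length(x)
  y[1L] + (y[n] - y[1L]) / (x[n] - x[1L]) * (x - x[1L])
}

#' Vertical chord-distance profile of a curve
#'
#' For each point, the absolute vertical distance between the curve and the
#' straight line through its two endpoints. The endpoints themselves have
#' distance exactly 0. Vertical (rather than perpendicular) distance makes
#' the location of the profile's maximum invariant under independent
#' positive rescaling of either axis, the property that gives the knee
#' estimator its unit invariance.
#'
#' @inheritParams check_curve
#' @return nonnegative vector the length of `x`.
#' @export
chord_distances <- function(x, y) {
  validate_curve(x, y)
  d <- abs(y - chord_line(x, y))
  d[c(1L, length(d))] <- 0
  d
}

#' Unit-invariant knee (extremum chord-distance) estimator
#'
#' Locates the knee (elbow) of a monotone curve: the point where a steeply
#' changing curve turns flat. The estimator takes the chord joining the two
#' endpoints and finds where the curve is farthest from it vertically.
#' `knee_start` and `knee_end` are the first and last abscissas whose
#' distance lies within a relative band `band_tol` of the global maximum
#' (they coincide except on plateaus); the selected point is `knee_start`,
#' the first inflection of the curvature, matching the rule of taking the
#' first rank at which the RSS curve bends.
#'
#' Rescaling `x` and/or `y` by positive constants leaves the selected grid
#' index unchanged (unit invariance). With `iterative = TRUE` the chord is
#' repeatedly shortened to the window ending just past the current knee and
#' the estimate recomputed until it stabilizes, a refinement of the basic
#' single-chord extremum; the abscissa is then snapped to the nearest grid
#' point, ties toward the smaller value.
#'
#' @inheritParams check_curve
#' @param band_tol relative tolerance defining the near-maximum plateau.
#' @param iterative apply iterative chord shortening.
#' @return object of class `knee_estimate`: `curve_type`, `knee_start`,
#'   `knee_end`, `selected` (a value of `x`), `selected_index`, `distances`.
#' @examples
#' uik(1:5, c(10, 6, 3, 1.5, 1))$selected   # 3
#' @export
uik <- function(x, y, band_tol = 1e-9, iterative = FALSE) {
  validate_curve(x, y)
  if (diff(range(y)) == 0)
    stop("degenerate curve: y is constant", call. = FALSE)
  type <- check_curve(x, y)
  d <- chord_distances(x, y)
  if (max(d) <= 1e-12 * diff(range(y)))
    stop("no knee: curve is a straight line", call. = FALSE)
  band <- which(d >= max(d) * (1 - band_tol))
  first <- min(band); last <- max(band)

  sel_idx <- first
  if (iterative) {
    lo <- 1L; hi <- length(x)
    repeat {
      dd <- chord_distances(x[lo:hi], y[lo:hi])
      if (max(dd) <= 1e-12 * max(diff(range(y[lo:hi])), .Machine$double.xmin)) break
      bb <- which(dd >= max(dd) * (1 - band_tol))
      cand <- lo + min(bb) - 1L
      new_hi <- min(lo + max(bb), hi)        # window ends just past the knee
      if (cand == sel_idx || new_hi - lo + 1L < 4L || new_hi == hi) {
        sel_idx <- cand
        break
      }
      sel_idx <- cand
      hi <- new_hi
    }
    # snap to the nearest grid point, ties toward the smaller rank
    gaps <- abs(x - x[sel_idx])
    sel_idx <- which(gaps == min(gaps))[1L]
  }

  structure(list(
    curve_type = type,
    knee_start = x[first], knee_end = x[last],
    selected = x[sel_idx], selected_index = sel_idx,
    distances = d, x = x, y = y), class = "knee_estimate")
}

#' @export
#' @method print knee_estimate
print.knee_estimate <- function(x, ...) {
  cat("Knee estimate (", x$curve_type$convexity, " ", x$curve_type$trend,
      " curve)\n", sep = "")
  cat("  knee points: start ", format(x$knee_start), ", end ",
      format(x$knee_end), "\n", sep = "")
  cat("  selected: ", format(x$selected), "\n", sep = "")
  invisible(x)
}

#' Select the optimal factorization rank from a rank survey
#'
#' Applies the unit-invariant knee estimator to the (rank, RSS) curve of a
#' survey; the selected abscissa is reported as the optimal rank.
#'
#' @param survey an [nmf_rank_survey()] result.
#' @param ... passed on to [uik()].
#' @return a `knee_estimate` whose `selected` element is the optimal rank.
#' @export
select_rank <- function(survey, ...) {
  if (!inherits(survey, "nmf_survey"))
    stop("survey must be an nmf_survey object", call. = FALSE)
  if (length(survey$ranks) < 4L)
    stop("rank selection needs a survey over at least 4 ranks", call. = FALSE)
  est <- tryCatch(uik(as.numeric(survey$ranks), survey$rss_curve, ...),
                  error = function(e)
                    stop("rank selection failed on the survey RSS curve: ",
                         conditionMessage(e), call. = FALSE))
  est$selected <- as.integer(round(est$selected))
  est
}
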