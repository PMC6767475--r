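# Branching-pattern statistics at junctions: area ratio, asymmetry ratio,
# the minimum-work (Murray) compliance statistic, the junction exponent, and
# the caliper radius conversion for dissected vessels. All four junction
# statistics are dimensionless and invariant under a common rescaling of the
# radii.

#' Area ratio of a junction
#'
#' Ratio of the summed daughter cross-sectional area to the parent
#' cross-sectional area, `AR = sum(r_i^2) / r0^2` (the factor pi cancels).
#' Defined for any number of daughters, so trifurcations contribute too.
#' Under the minimum-work relation with exponent `x`, a symmetric bifurcation
#' has `AR = 2^(1 - 2/x)`: 1.26 for laminar flow (`x = 3`), 1.10 for fully
#' turbulent flow (`x = 2.33`).
#'
#' @param r0 parent radius (mm), positive.
#' @param daughters numeric vector of daughter radii (mm).
#' @return dimensionless area ratio; `NA` if `r0 <= 0`.
#' @export
area_ratio <- function(r0, daughters) {
  if (!is.finite(r0) || r0 <= 0) return(NA_real_)
  sum(daughters^2) / r0^2
}

#' Asymmetry ratio of a bifurcation
#'
#' Cross-sectional area of the smaller daughter over the larger,
#' `AS = r2^2 / r1^2` with `r1 >= r2`, so `AS` lies in (0, 1] and 1 means a
#' perfectly symmetric bifurcation. Only defined for exactly two daughters;
#' junctions with more daughters return `NA`.
#'
#' @param daughters numeric vector of daughter radii (mm).
#' @return dimensionless asymmetry ratio in (0, 1], or `NA`.
#' @export
asymmetry_ratio <- function(daughters) {
  if (length(daughters) != 2L || any(!is.finite(daughters)) ||
      any(daughters <= 0))
    return(NA_real_)
  r <- sort(daughters, decreasing = TRUE)
  (r[2L] / r[1L])^2
}

#' Minimum-work compliance statistic
#'
#' Murray's law states `r0^3 = r1^3 + r2^3` at a bifurcation; the statistic
#' `n = (r1^3 + r2^3) / r0^3` equals 1 when the junction complies with the
#' principle of minimum work. Only defined for exactly two daughters.
#'
#' @inheritParams area_ratio
#' @return dimensionless `n`, or `NA`.
#' @export
murray_n <- function(r0, daughters) {
  if (length(daughters) != 2L || !is.finite(r0) || r0 <= 0)
    return(NA_real_)
  sum(daughters^3) / r0^3
}

#' Junction exponent
#'
#' The exponent `x` solving `r0^x = r1^x + r2^x`. A laminar minimum-work
#' junction has `x = 3`; the fully turbulent optimum is `x = 2.33`. The
#' equation has a finite root only when both daughters are strictly smaller
#' than the parent; otherwise (and when the root escapes the search
#' bracket) the solve is reported as undefined — near-parent daughters push
#' the exponent towards infinity.
#'
#' Solved by bracketed root-finding on `f(x) = (r1/r0)^x + (r2/r0)^x - 1`,
#' which is strictly decreasing in `x` when both ratios are below 1.
#'
#' @inheritParams area_ratio
#' @param bracket search interval for the exponent, default `c(0.5, 50)`.
#' @param tol relative tolerance on the defect `|r0^x - r1^x - r2^x| / r0^x`.
#' @return the exponent, or `NA` with attribute `reason = "no_finite_exponent"`
#'   when no root exists in the bracket.
#' @export
junction_exponent <- function(r0, daughters, bracket = c(0.5, 50),
                              tol = 1e-10) {
  undefined <- structure(NA_real_, reason = "no_finite_exponent")
  if (length(daughters) != 2L || !is.finite(r0) || r0 <= 0 ||
      any(!is.finite(daughters)) || any(daughters <= 0))
    return(undefined)
  q <- daughters / r0
  if (any(q >= 1)) return(undefined)
  f <- function(x) q[1L]^x + q[2L]^x - 1
  if (f(bracket[1L]) < 0 || f(bracket[2L]) > 0) return(undefined)
  root <- stats::uniroot(f, bracket, tol = .Machine$double.eps^0.75)$root
  if (abs(f(root)) >= tol) return(undefined)
  root
}

#' Radius of a dissected vessel from caliper measurements
#'
#' Dissected arteries are flattened under a glass slide; the flattened width
#' and the wall thickness are measured with a caliper and the lumen radius
#' recovered as `radius = (width - 2 * wall) / pi` (the flattened lumen has
#' width equal to half its circumference).
#'
#' @param width flattened vessel width, mm.
#' @param wall vessel wall thickness, mm.
#' @return radius in mm.
#' @export
radius_from_flattened <- function(width, wall) {
  if (any(!is.finite(width)) || any(!is.finite(wall)) || any(wall < 0))
    stop("width and wall must be finite and wall non-negative")
  if (any(width <= 2 * wall))
    stop("width must exceed twice the wall thickness")
  (width - 2 * wall) / pi
}

#' Compute branching statistics for a table of bifurcation records
#'
#' Adds `AR`, `AS`, `n` and `exponent` columns to a `bifurcation_records`
#' table. `AR` uses all daughters; `AS`, `n` and the exponent are left `NA`
#' for junctions with more than two daughters and for records flagged
#' unusable.
#'
#' @param records `bifurcation_records` from [extract_bifurcations()].
#' @param exponent logical; also solve for the junction exponent (numeric
#'   root-finding per record).
#' @return the table with metric columns appended.
#' @export
bifurcation_metrics <- function(records, exponent = TRUE) {
  nr <- nrow(records)
  records$AR <- rep(NA_real_, nr)
  records$AS <- rep(NA_real_, nr)
  records$n <- rep(NA_real_, nr)
  records$exponent <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    if (!records$usable[i]) next
    dr <- records$daughter_radii[[i]]
    records$AR[i] <- area_ratio(records$r0[i], dr)
    if (length(dr) == 2L) {
      records$AS[i] <- asymmetry_ratio(dr)
      records$n[i] <- murray_n(records$r0[i], dr)
      if (exponent)
        records$exponent[i] <- junction_exponent(records$r0[i], dr)
    }
  }
  records
}
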