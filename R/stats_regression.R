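# Descriptive statistics, normality testing, parameter summaries and the two
# branching-pattern regressions (area ratio and minimum work).

#' Lilliefors-type normality test with Monte Carlo p-values
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#' with mean and SD estimated from the sample. Because the parameters are
#' estimated, the classical KS null distribution is anticonservative; the
#' p-value is therefore computed by Monte Carlo, re-simulating the statistic
#' under normal samples of the same size.
#'
#' @param values numeric vector, at least 5 finite values.
#' @param reps number of Monte Carlo replicates (default 10000).
#' @return list with `statistic` (the KS distance D), `p_value`, and `n`.
#'   Constant input is degenerate and reported non-normal (`p_value = 0`).
#' @export
ks_normality <- function(values, reps = 10000L) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 5L) stop("normality test needs at least 5 values")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p_value = 0, n = n))
  lillie_d <- function(z) {
    z <- sort((z - mean(z)) / stats::sd(z))
    p <- stats::pnorm(z)
    i <- seq_len(length(z))
    max(pmax(i / length(z) - p, p - (i - 1) / length(z)))
  }
  d <- lillie_d(x)
  sims <- vapply(seq_len(reps), function(i) lillie_d(stats::rnorm(n)),
                 numeric(1))
  list(statistic = d, p_value = (1 + sum(sims >= d)) / (reps + 1), n = n)
}

#' Descriptive summary: median, IQR, range
#'
#' The summary format used for non-normally distributed morphometric
#' parameters: median (n, IQR, min-max). Quartiles use linear interpolation
#' (type-7 convention).
#'
#' @param values numeric vector (NAs dropped).
#' @return list with `n`, `median`, `q1`, `q3`, `iqr`, `min`, `max`.
#' @export
describe <- function(values) {
  x <- values[is.finite(values)]
  if (!length(x)) stop("no finite values to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(x), median = q[2L], q1 = q[1L], q3 = q[3L],
       iqr = q[3L] - q[1L], min = min(x), max = max(x))
}

#' Area-ratio regression
#'
#' Regresses the summed squared daughter radii on the squared parent radius
#' across bifurcations, after ROUT outlier removal; the slope estimates the
#' population area ratio.
#'
#' @param bifurcations a `bifurcation_records` table with at least 10 usable
#'   (and, if present, `included`) records.
#' @param Q ROUT false-discovery budget (default 0.01).
#' @param through_origin fit without intercept (default `FALSE`, matching
#'   ordinary linear regression with intercept).
#' @return a [rout_lm()] fit with `analysis = "area_ratio"`; `x` is
#'   `r0^2`, `y` is `sum(daughter radii^2)`.
#' @export
fit_ar_regression <- function(bifurcations, Q = 0.01,
                              through_origin = FALSE) {
  rec <- .usable_records(bifurcations)
  x <- rec$r0^2
  y <- vapply(rec$daughter_radii, function(d) sum(d^2), numeric(1))
  fit <- rout_lm(x, y, Q = Q, through_origin = through_origin)
  fit$analysis <- "area_ratio"
  fit
}

#' Minimum-work (Murray's law) regression
#'
#' Regresses the summed cubed daughter radii on the cubed parent radius,
#' after ROUT outlier removal. A slope of 1 means the tree as a whole
#' complies with the principle of minimum work; `p_slope_one` in the result
#' tests that hypothesis.
#'
#' @inheritParams fit_ar_regression
#' @return a [rout_lm()] fit with `analysis = "minimum_work"`; `x` is
#'   `r0^3`, `y` is `sum(daughter radii^3)`.
#' @export
fit_minimum_work_regression <- function(bifurcations, Q = 0.01,
                                        through_origin = FALSE) {
  rec <- .usable_records(bifurcations)
  x <- rec$r0^3
  y <- vapply(rec$daughter_radii, function(d) sum(d^3), numeric(1))
  fit <- rout_lm(x, y, Q = Q, through_origin = through_origin)
  fit$analysis <- "minimum_work"
  fit
}

.usable_records <- function(bifurcations) {
  keep <- bifurcations$usable
  if (!is.null(bifurcations$included)) keep <- keep & bifurcations$included
  rec <- bifurcations[keep, , drop = FALSE]
  if (nrow(rec) < 10L) stop("need at least 10 usable bifurcation records")
  rec
}

#' Summarize branching-pattern parameters
#'
#' Builds a one-row-per-parameter summary table in the reporting format
#' median (n without outliers, IQR, range). AR, LR and T are summarized
#' after univariate ROUT outlier removal; AS is summarized without outlier
#' removal because it is bounded in (0, 1]. Outlier masks are per parameter
#' and never shared across analyses.
#'
#' @param label source label for the rows (e.g. `"7T MRI"`).
#' @param segment_metrics segment metric table (columns `LR`, `T`), or
#'   `NULL` (lengths cannot be measured on manually measured casts).
#' @param bifurcation_metrics bifurcation metric table (columns `AR`, `AS`),
#'   or `NULL`.
#' @param Q ROUT budget for the cleaned parameters.
#' @return data frame with columns `source`, `parameter`, `n_total`, `n`,
#'   `median`, `iqr`, `min`, `max`. Parameters with no finite values are
#'   omitted.
#' @export
summarize_parameters <- function(label, segment_metrics = NULL,
                                 bifurcation_metrics = NULL, Q = 0.01) {
  grab <- function(df, col, filter_col = "included") {
    if (is.null(df) || is.null(df[[col]])) return(numeric())
    v <- df[[col]]
    if (!is.null(df[[filter_col]])) v <- v[df[[filter_col]]]
    v[is.finite(v)]
  }
  specs <- list(
    AR = list(values = grab(bifurcation_metrics, "AR"), rout = TRUE),
    AS = list(values = grab(bifurcation_metrics, "AS"), rout = FALSE),
    LR = list(values = grab(segment_metrics, "LR"), rout = TRUE),
    T  = list(values = grab(segment_metrics, "T"), rout = TRUE)
  )
  rows <- lapply(names(specs), function(p) {
    v <- specs[[p]]$values
    if (!length(v)) return(NULL)
    keep <- if (specs[[p]]$rout) rout_values(v, Q = Q) else rep(TRUE, length(v))
    d <- describe(v[keep])
    data.frame(source = label, parameter = p, n_total = length(v), n = d$n,
               median = d$median, iqr = d$iqr, min = d$min, max = d$max)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(source = character(), parameter = character(),
                      n_total = integer(), n = integer(), median = numeric(),
                      iqr = numeric(), min = numeric(), max = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarize radii and lengths
#'
#' The general results table: per source, the number of bifurcations and
#' segments with descriptive summaries of the parent artery radius, the
#' proximal segment radius, and the segment length.
#'
#' @inheritParams summarize_parameters
#' @return data frame with one row per quantity (`parent_radius`,
#'   `proximal_radius`, `length`) and the `n`, `median`, `iqr`, `min`, `max`
#'   columns.
#' @export
summarize_sizes <- function(label, segment_metrics = NULL,
                            bifurcation_metrics = NULL) {
  vals <- list(
    parent_radius = if (!is.null(bifurcation_metrics)) {
      keep <- if (is.null(bifurcation_metrics$included))
        bifurcation_metrics$usable else bifurcation_metrics$included
      bifurcation_metrics$r0[keep]
    } else numeric(),
    proximal_radius = if (!is.null(segment_metrics))
      segment_metrics$r_proximal[segment_metrics$included] else numeric(),
    length = if (!is.null(segment_metrics))
      segment_metrics$L[segment_metrics$included] else numeric()
  )
  rows <- lapply(names(vals), function(q) {
    v <- vals[[q]][is.finite(vals[[q]])]
    if (!length(v)) return(NULL)
    d <- describe(v)
    data.frame(source = label, quantity = q, n = d$n, median = d$median,
               iqr = d$iqr, min = d$min, max = d$max)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Relative-frequency histogram
#'
#' Bins values at a fixed bin width and reports per-bin relative frequencies
#' in percent (summing to 100 within rounding), the presentation used for
#' morphometric parameter distributions.
#'
#' @param values numeric vector (NAs dropped).
#' @param bin_width positive bin width; bins are anchored at `origin`.
#' @param origin left edge of the bin grid (default 0).
#' @return data frame with `bin_left`, `bin_right`, `count`, `percent`.
#' @export
relative_frequency_histogram <- function(values, bin_width, origin = 0) {
  x <- values[is.finite(values)]
  if (!length(x)) stop("no finite values to bin")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  idx <- floor((x - origin) / bin_width)
  rng <- seq.int(min(idx), max(idx))
  counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  data.frame(bin_left = origin + rng * bin_width,
             bin_right = origin + (rng + 1) * bin_width,
             count = counts,
             percent = 100 * counts / length(x))
}
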