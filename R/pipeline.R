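# End-to-end orchestration: ingest -> segment metrics -> resolution filter
# -> bifurcation metrics -> statistics -> report bundle.

#' Analyze a single centerline tree
#'
#' Runs the per-tree stages: segment splitting, segment metrics, the
#' two-voxel resolution filter (when the tree carries a voxel size), and
#' bifurcation metrics.
#'
#' @param tree a [centerline_tree()].
#' @param exponent logical; also solve the junction exponent per bifurcation.
#' @return list with `segments` (metric table) and `bifurcations` (metric
#'   table with `included` flags).
#' @export
analyze_tree <- function(tree, exponent = TRUE) {
  segs <- split_into_segments(tree)
  metrics <- segment_metrics(segs)
  bifs <- extract_bifurcations(segs, metrics)
  filtered <- apply_resolution_filter(metrics, bifs, tree$voxel_size)
  filtered$bifurcations <- bifurcation_metrics(filtered$bifurcations,
                                               exponent = exponent)
  list(segments = filtered$metrics, bifurcations = filtered$bifurcations)
}

#' Run the full morphometry pipeline
#'
#' Takes one or more labeled centerline trees, analyzes each, pools inputs
#' that share a label (pooling is plain concatenation before any
#' statistics), and computes per-label descriptive summaries, parameter
#' summaries (with per-parameter ROUT cleaning, except AS), the area-ratio
#' and minimum-work regressions, and relative-frequency histograms.
#'
#' @param inputs list of inputs; each a list with elements `tree` (a
#'   [centerline_tree()]) and `label` (character source tag, e.g. `"cast"`,
#'   `"dissection"`, `"mri7t"`). Inputs sharing a label are pooled.
#' @param Q ROUT false-discovery budget used throughout (default 0.01).
#' @param bin_widths named list of histogram bin widths per parameter
#'   (defaults: radius 0.1 mm, length 1 mm, AR 0.2, AS 0.1, LR 2, T 0.05).
#' @param normality_reps Monte Carlo replicates for the normality tests;
#'   0 skips them.
#' @param out_dir optional directory; when given, TSV tables and a JSON run
#'   log are written there.
#' @param seed seed for the Monte Carlo normality p-values.
#' @return object of class `arbor_morphometry`: list with `per_label`
#'   (segment/bifurcation tables per label), `size_summary`,
#'   `parameter_summary`, `regressions` (per label: `area_ratio` and
#'   `minimum_work` [rout_lm()] fits, `NULL` when under 10 records),
#'   `normality`, `histograms`, `counts` (record conservation per stage)
#'   and `Q`.
#' @export
run_morphometry <- function(inputs, Q = 0.01, bin_widths = list(),
                            normality_reps = 0L, out_dir = NULL,
                            seed = 1L) {
  if (!length(inputs)) stop("no inputs given")
  labels <- vapply(inputs, `[[`, character(1), "label")
  if (any(!nzchar(labels))) stop("every input needs a non-empty label")
  bw <- utils::modifyList(list(radius = 0.1, length = 1, AR = 0.2,
                               AS = 0.1, LR = 2, T = 0.05), bin_widths)
  set.seed(seed)
  per_label <- list()
  for (lab in unique(labels)) {
    parts <- lapply(inputs[labels == lab], function(inp)
      analyze_tree(inp$tree))
    segs <- do.call(rbind, lapply(parts, `[[`, "segments"))
    bifs <- do.call(rbind, lapply(parts, `[[`, "bifurcations"))
    per_label[[lab]] <- list(segments = segs, bifurcations = bifs)
  }
  size_summary <- do.call(rbind, lapply(names(per_label), function(lab)
    summarize_sizes(lab, per_label[[lab]]$segments,
                    per_label[[lab]]$bifurcations)))
  parameter_summary <- do.call(rbind, lapply(names(per_label), function(lab)
    summarize_parameters(lab, per_label[[lab]]$segments,
                         per_label[[lab]]$bifurcations, Q = Q)))
  regressions <- lapply(per_label, function(d) {
    usable <- sum(d$bifurcations$included & d$bifurcations$n_daughters >= 2)
    if (usable < 10L) return(NULL)
    list(area_ratio = fit_ar_regression(d$bifurcations, Q = Q),
         minimum_work = fit_minimum_work_regression(d$bifurcations, Q = Q))
  })
  normality <- if (normality_reps > 0) {
    lapply(per_label, function(d) {
      vals <- list(AR = d$bifurcations$AR, AS = d$bifurcations$AS,
                   LR = d$segments$LR, T = d$segments$T)
      lapply(vals, function(v) {
        v <- v[is.finite(v)]
        if (length(v) >= 5 && stats::sd(v) > 0)
          ks_normality(v, reps = normality_reps) else NULL
      })
    })
  } else NULL
  histograms <- lapply(per_label, function(d) {
    mk <- function(v, w) if (sum(is.finite(v)))
      relative_frequency_histogram(v, w) else NULL
    list(parent_radius = mk(d$bifurcations$r0[d$bifurcations$included],
                            bw$radius),
         proximal_radius = mk(d$segments$r_proximal[d$segments$included],
                              bw$radius),
         length = mk(d$segments$L[d$segments$included], bw$length),
         AR = mk(d$bifurcations$AR, bw$AR), AS = mk(d$bifurcations$AS, bw$AS),
         LR = mk(d$segments$LR[d$segments$included], bw$LR),
         T = mk(d$segments$T[d$segments$included], bw$T))
  })
  counts <- do.call(rbind, lapply(names(per_label), function(lab) {
    d <- per_label[[lab]]
    data.frame(source = lab,
               segments_total = nrow(d$segments),
               segments_included = sum(d$segments$included),
               bifurcations_total = nrow(d$bifurcations),
               bifurcations_included = sum(d$bifurcations$included))
  }))
  result <- structure(list(per_label = per_label,
                           size_summary = size_summary,
                           parameter_summary = parameter_summary,
                           regressions = regressions,
                           normality = normality,
                           histograms = histograms,
                           counts = counts, Q = Q, seed = seed),
                      class = "arbor_morphometry")
  if (!is.null(out_dir)) write_bundle(result, out_dir)
  result
}

#' Write a morphometry report bundle
#'
#' Emits the pipeline tables as TSV files plus a JSON run log (package
#' version, seed, Q, per-stage record counts, regression results) into a
#' directory.
#'
#' @param result an `arbor_morphometry` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(result$per_label)) {
    d <- result$per_label[[lab]]
    write_report(d$segments, file.path(out_dir,
                                       paste0("segments_", lab, ".tsv")))
    write_report(d$bifurcations,
                 file.path(out_dir, paste0("bifurcations_", lab, ".tsv")))
  }
  write_report(result$size_summary, file.path(out_dir, "size_summary.tsv"))
  write_report(result$parameter_summary,
               file.path(out_dir, "parameter_summary.tsv"))
  reg_rows <- list()
  for (lab in names(result$regressions)) {
    for (an in names(result$regressions[[lab]])) {
      f <- result$regressions[[lab]][[an]]
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        source = lab, analysis = an,
        slope = f$coefficients[["slope"]], se = f$se[["slope"]],
        intercept = f$coefficients[["intercept"]],
        r_squared = f$r_squared, p_slope_zero = f$p_value,
        p_slope_one = f$p_slope_one, n = f$n_total,
        n_outliers = f$n_outliers)
    }
  }
  if (length(reg_rows))
    write_report(do.call(rbind, reg_rows),
                 file.path(out_dir, "regressions.tsv"))
  log <- list(package = "arbormetrics",
              version = as.character(utils::packageVersion("arbormetrics")),
              seed = result$seed, Q = result$Q,
              counts = result$counts)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.arbor_morphometry <- function(x, ...) {
  cat("Arterial-tree morphometry run (ROUT Q = ", format(100 * x$Q),
      "%)\n", sep = "")
  print(x$counts, row.names = FALSE)
  cat("\nParameter summaries (median (n, IQR, range)):\n")
  ps <- x$parameter_summary
  for (i in seq_len(nrow(ps)))
    cat(sprintf("  %-12s %-3s %.2f (%d, %.2f, %.2f-%.2f)\n",
                ps$source[i], ps$parameter[i], ps$median[i], ps$n[i],
                ps$iqr[i], ps$min[i], ps$max[i]))
  for (lab in names(x$regressions)) {
    if (is.null(x$regressions[[lab]])) next
    mw <- x$regressions[[lab]]$minimum_work
    ar <- x$regressions[[lab]]$area_ratio
    cat(sprintf("\n%s: AR slope %.3f ± %.3f (R²=%.2f); minimum-work slope %.3f ± %.3f (R²=%.2f)\n",
                lab, ar$coefficients[["slope"]], ar$se[["slope"]],
                ar$r_squared, mw$coefficients[["slope"]], mw$se[["slope"]],
                mw$r_squared))
  }
  invisible(x)
}

#' @export
summary.arbor_morphometry <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
plot.arbor_morphometry <- function(x, label = names(x$regressions)[1L],
                                   ...) {
  reg <- x$regressions[[label]]
  if (is.null(reg)) stop("no regression available for label ", label)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(reg$area_ratio, xlab = expression(r[0]^2),
       ylab = expression(r[1]^2 + r[2]^2),
       main = paste(label, "- area ratio"))
  plot(reg$minimum_work, xlab = expression(r[0]^3),
       ylab = expression(r[1]^3 + r[2]^3),
       main = paste(label, "- minimum work"))
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
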