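# Per-segment geometry: arc length, end radii via the quartile-trimmed
# linear regression, tapering, length-to-radius ratio, and the two-voxel
# resolution filter.

#' Arc length of an ordered node chain
#'
#' Length of a segment, defined as the sum of Euclidean distances between
#' consecutive nodes. Coincident nodes contribute zero, so degenerate chains
#' are allowed and give `L = 0`.
#'
#' @param positions numeric matrix (n x 3) of node positions in mm, ordered
#'   from the proximal to the distal end.
#' @return length in mm.
#' @export
segment_length <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("a segment needs at least 2 nodes")
  d <- diff(positions)
  sum(sqrt(rowSums(d * d)))
}

#' Cumulative arc length along a node chain
#'
#' Euclidean distance of every node from the first node, measured along the
#' chain. Monotone non-decreasing, starting at 0 and ending at
#' [segment_length()].
#'
#' @inheritParams segment_length
#' @return numeric vector of per-node distances in mm.
#' @export
cumulative_arclength <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("a segment needs at least 2 nodes")
  d <- diff(positions)
  c(0, cumsum(sqrt(rowSums(d * d))))
}

# 1-based indices of the middle-two-quartile nodes of an n-node chain:
# the first and last floor(n/4) nodes are dropped. Matches the rule that the
# first and last quartiles of the node list are not used.
middle_quartile_indices <- function(n) {
  k <- floor(n / 4)
  seq.int(k + 1L, n - k)
}

#' Estimate proximal and distal segment radii
#'
#' Node radii just before and after a bifurcation dip below the true vessel
#' calibre, so the end radii of a segment are not read off the end nodes.
#' Instead the first and last quartiles of the node list are discarded and an
#' ordinary least-squares line `radius ~ arclength` is fitted through the
#' middle two quartiles; the line evaluated at `s = 0` and `s = L` gives the
#' proximal and distal radius.
#'
#' Fallbacks for short chains: if the middle half holds fewer than 4 nodes
#' the window is widened symmetrically to the middle `ceiling(n/2) + 2`
#' nodes; chains with fewer than 4 nodes in total use the mean radius for
#' both ends and are flagged `too_few_nodes`.
#'
#' @param arclength per-node distance from the proximal end, mm
#'   (from [cumulative_arclength()]).
#' @param radius per-node radii, mm.
#' @return list with `r_proximal`, `r_distal` (mm), `flag` (`"none"`,
#'   `"too_few_nodes"`, or `"nonpositive_end_radius"`).
#' @export
estimate_end_radii <- function(arclength, radius) {
  n <- length(radius)
  stopifnot(length(arclength) == n)
  L <- arclength[n]
  if (n < 4L) {
    m <- mean(radius)
    return(list(r_proximal = m, r_distal = m, flag = "too_few_nodes"))
  }
  idx <- middle_quartile_indices(n)
  if (length(idx) < 4L) {
    w <- ceiling(n / 2) + 2L
    lo <- max(1L, floor((n - w) / 2) + 1L)
    idx <- seq.int(lo, min(n, lo + w - 1L))
  }
  s <- arclength[idx]
  r <- radius[idx]
  if (stats::var(s) == 0) {
    # coincident nodes in the window: no slope identifiable
    m <- mean(r)
    return(list(r_proximal = m, r_distal = m, flag = "none"))
  }
  fit <- stats::.lm.fit(cbind(1, s), r)
  a <- fit$coefficients[1L]
  b <- fit$coefficients[2L]
  rp <- a
  rd <- a + b * L
  flag <- "none"
  if (!is.finite(rp) || !is.finite(rd)) {
    flag <- "too_few_nodes"
  } else if (rp <= 0 || rd <= 0) {
    flag <- "nonpositive_end_radius"
  }
  list(r_proximal = rp, r_distal = rd, flag = flag)
}

#' Tapering of a segment
#'
#' Ratio of the distal to the proximal radius; 1 means no taper.
#'
#' @param r_proximal,r_distal end radii in mm.
#' @return `T = r_distal / r_proximal`; `NA` when `r_proximal <= 0`.
#' @export
tapering <- function(r_proximal, r_distal) {
  ifelse(is.finite(r_proximal) & r_proximal > 0, r_distal / r_proximal,
         NA_real_)
}

#' Length-to-radius ratio of a segment
#'
#' @param L segment length, mm.
#' @param r_proximal proximal radius, mm.
#' @return `LR = L / r_proximal`; `NA` when `r_proximal <= 0`.
#' @export
length_radius_ratio <- function(L, r_proximal) {
  ifelse(is.finite(r_proximal) & r_proximal > 0, L / r_proximal, NA_real_)
}

#' Compute the full per-segment metric table
#'
#' Applies [segment_length()], [estimate_end_radii()], [tapering()] and
#' [length_radius_ratio()] to every segment of a tree.
#'
#' @param segments an `arbor_segments` list from [split_into_segments()].
#' @return data frame with one row per segment: `segment`, `n_nodes`, `L`,
#'   `r_proximal`, `r_distal`, `T`, `LR`, `included` (updated by
#'   [apply_resolution_filter()]), `reason`.
#' @export
segment_metrics <- function(segments) {
  tree <- attr(segments, "tree")
  pos <- as.matrix(tree$nodes[c("x", "y", "z")])
  rows <- lapply(seq_along(segments), function(i) {
    ii <- segments[[i]]
    p <- pos[ii, , drop = FALSE]
    s <- cumulative_arclength(p)
    L <- s[length(s)]
    est <- estimate_end_radii(s, tree$nodes$radius[ii])
    data.frame(segment = i, n_nodes = length(ii), L = L,
               r_proximal = est$r_proximal, r_distal = est$r_distal,
               T = tapering(est$r_proximal, est$r_distal),
               LR = length_radius_ratio(L, est$r_proximal),
               included = est$flag %in% c("none", "too_few_nodes"),
               reason = if (est$flag == "none") "none" else est$flag)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apply the two-voxel resolution filter
#'
#' Radii measured close to the scan resolution are unreliable: a diameter of
#' at least `min_diameter_voxels` voxels (default 2) is required. Segments
#' whose proximal diameter falls below `min_diameter_voxels * voxel_size` are
#' excluded, and bifurcations are excluded unless the parent and all daughter
#' diameters meet the same bound. Trees without a `voxel_size` (dissection or
#' caliper data) skip the filter.
#'
#' @param metrics segment metric table from [segment_metrics()].
#' @param bifurcations `bifurcation_records` from [extract_bifurcations()].
#' @param voxel_size acquisition voxel size in mm, or `NULL` to skip.
#' @param min_diameter_voxels minimum diameter in voxel units, default 2.
#' @return list with updated `metrics` (rows failing the bound get
#'   `included = FALSE`, `reason = "below_two_voxel"`) and `bifurcations`
#'   (gains a logical `included` column).
#' @export
apply_resolution_filter <- function(metrics, bifurcations, voxel_size,
                                    min_diameter_voxels = 2) {
  if (is.null(voxel_size)) {
    bifurcations$included <- bifurcations$usable
    return(list(metrics = metrics, bifurcations = bifurcations))
  }
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a positive number when filtering")
  dmin <- min_diameter_voxels * voxel_size
  drop <- metrics$included & (2 * metrics$r_proximal < dmin)
  metrics$included[drop] <- FALSE
  metrics$reason[drop] <- "below_two_voxel"
  ok <- vapply(seq_len(nrow(bifurcations)), function(i) {
    all(2 * c(bifurcations$r0[i],
              unlist(bifurcations$daughter_radii[i])) >= dmin)
  }, logical(1))
  bifurcations$included <- bifurcations$usable & ok
  list(metrics = metrics, bifurcations = bifurcations)
}
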