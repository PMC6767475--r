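# Synthetic arterial trees with known ground truth.
#
# The generator grows a binary tree whose junction radii satisfy the
# minimum-work relation r0^x = r1^x + r2^x exactly (before measurement
# noise), with the asymmetry ratio drawn from a Beta distribution and
# segment length-to-radius ratios from a log-normal. Segments are
# discretized into nodes at a fixed spacing along a bounded-turning random
# walk, radii interpolated linearly from the proximal to the (optionally
# tapered) distal value, and multiplicative Gaussian noise applied per node.
# Ground truth is recorded before noise, so every pipeline stage can be
# checked against exact values.

#' Configuration for the synthetic tree generator
#'
#' Defaults emulate the measured size range of the cerebral arterial tree
#' between the large basal arteries and the pre-capillary network: a 1 mm
#' root radius, minimum-work exponent 3, a broad side-branch-heavy asymmetry
#' distribution, log-normal length-to-radius ratios with median 8, no taper,
#' and 2% multiplicative radius noise.
#'
#' @param root_radius proximal radius of the root segment, mm.
#' @param exponent branching exponent `x` in `r0^x = r1^x + r2^x`
#'   (3 = laminar minimum work).
#' @param asymmetry_shape length-2 Beta shape parameters for the asymmetry
#'   ratio AS in (0, 1].
#' @param lr_meanlog,lr_sdlog log-normal parameters of the length-to-radius
#'   ratio LR.
#' @param taper_factor distal/proximal radius ratio of every segment
#'   (1 = no taper). Values > 1 are only allowed with a finite
#'   `max_bifurcations`.
#' @param node_spacing centerline node spacing, mm.
#' @param radius_noise_sd SD of the multiplicative Gaussian radius noise, as
#'   a fraction of the true radius.
#' @param min_radius termination radius, mm: a branch whose distal radius
#'   falls to or below this stops bifurcating.
#' @param max_bifurcations cap on the number of bifurcations.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(root_radius = 1.0, exponent = 3,
                             asymmetry_shape = c(0.8, 1.2),
                             lr_meanlog = log(8), lr_sdlog = 0.6,
                             taper_factor = 1.0, node_spacing = 0.05,
                             radius_noise_sd = 0.02, min_radius = 0.02,
                             max_bifurcations = 250L, seed = 1L) {
  cfg <- list(root_radius = root_radius, exponent = exponent,
              asymmetry_shape = asymmetry_shape, lr_meanlog = lr_meanlog,
              lr_sdlog = lr_sdlog, taper_factor = taper_factor,
              node_spacing = node_spacing, radius_noise_sd = radius_noise_sd,
              min_radius = min_radius,
              max_bifurcations = as.numeric(max_bifurcations),
              seed = as.integer(seed))
  stopifnot(root_radius > 0, exponent > 0, node_spacing > 0,
            min_radius >= 0, min_radius < root_radius,
            radius_noise_sd >= 0, taper_factor > 0,
            length(asymmetry_shape) == 2L, all(asymmetry_shape > 0))
  if (!is.finite(cfg$max_bifurcations) &&
      (taper_factor > 1 || min_radius == 0))
    stop("unbounded growth: an infinite max_bifurcations needs ",
         "taper_factor <= 1 and min_radius > 0 to terminate")
  structure(cfg, class = "generator_config")
}

#' Daughter radii under the minimum-work relation
#'
#' Given a parent radius, a target asymmetry ratio and the branching
#' exponent, returns the unique daughter pair with
#' `r0^x = r1^x + r2^x` and `(r2/r1)^2 = AS` exactly:
#' `r1 = r0 / (1 + AS^(x/2))^(1/x)` and `r2 = r1 * sqrt(AS)`.
#'
#' @param r0 parent radius, mm.
#' @param AS asymmetry ratio in (0, 1].
#' @param x branching exponent.
#' @return named numeric vector `c(r1, r2)` with `r1 >= r2`.
#' @export
sample_daughters <- function(r0, AS, x) {
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be positive")
  if (!is.finite(AS) || AS <= 0 || AS > 1) stop("AS must be in (0, 1]")
  if (!is.finite(x) || x <= 0) stop("x must be positive")
  r1 <- r0 / (1 + AS^(x / 2))^(1 / x)
  c(r1 = r1, r2 = r1 * sqrt(AS))
}

.unit <- function(v) v / sqrt(sum(v * v))

#' Generate a synthetic centerline tree with ground truth
#'
#' Grows the tree breadth-first from the root. Each queued branch draws an
#' LR, lays down `round(L / node_spacing)` equal steps along a
#' bounded-turning random walk, interpolates radii from the proximal value
#' to `taper_factor` times it, then (if the distal radius is above
#' `min_radius` and the bifurcation budget remains) splits into two
#' daughters via [sample_daughters()] with a Beta-drawn asymmetry ratio.
#' Per-node multiplicative Gaussian noise is applied after truth is
#' recorded.
#'
#' @param cfg a [generator_config()].
#' @return object of class `arbor_synthetic`: list with `tree` (the noisy
#'   [centerline_tree()]), `true_radius` (per-node noiseless radii, aligned
#'   with `tree$nodes`), `node_segment` (segment id owning each node),
#'   `segments_truth` (per-segment truth: `seg`, `parent_seg`, `first_node`,
#'   `last_node`, `L`, `r_proximal`, `r_distal`, `T`, `LR`),
#'   `bifurcations_truth` (per-bifurcation truth: `node`, `seg_in`, `r0`,
#'   `r1`, `r2`, `AS`, `AR`, `n`), and `config`.
#' @export
generate_tree <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  spacing <- cfg$node_spacing
  noisy <- function(r) {
    if (cfg$radius_noise_sd == 0) return(r)
    pmax(r * (1 + stats::rnorm(length(r), 0, cfg$radius_noise_sd)), 1e-9)
  }
  # growing node store
  cap <- 4096L
  nx <- ny <- nz <- rt <- rn <- numeric(cap)
  npar <- nseg <- integer(cap)
  n_nodes <- 0L
  add_node <- function(x, y, z, r_true, parent, seg) {
    if (n_nodes + 1L > cap) {
      cap <<- cap * 2L
      length(nx) <<- cap; length(ny) <<- cap; length(nz) <<- cap
      length(rt) <<- cap; length(rn) <<- cap
      length(npar) <<- cap; length(nseg) <<- cap
    }
    n_nodes <<- n_nodes + 1L
    nx[n_nodes] <<- x; ny[n_nodes] <<- y; nz[n_nodes] <<- z
    rt[n_nodes] <<- r_true; rn[n_nodes] <<- noisy(r_true)
    npar[n_nodes] <<- parent; nseg[n_nodes] <<- seg
    n_nodes
  }
  root <- add_node(0, 0, 0, cfg$root_radius, NA_integer_, 1L)
  segs <- list()
  bifs <- list()
  n_bif <- 0L
  queue <- list(list(start = root, r_prox = cfg$root_radius,
                     dir = .unit(stats::rnorm(3)), parent_seg = NA_integer_))
  head <- 1L
  while (head <= length(queue)) {
    job <- queue[[head]]; head <- head + 1L
    seg_id <- length(segs) + 1L
    lr <- stats::rlnorm(1, cfg$lr_meanlog, cfg$lr_sdlog)
    # at least 5 steps (6 nodes): the junction node shared with the parent
    # carries the parent's radius, and quartile trimming only excludes it
    # once the chain has 6+ nodes
    n_steps <- max(5L, as.integer(round(lr * job$r_prox / spacing)))
    L <- n_steps * spacing
    r_dist <- cfg$taper_factor * job$r_prox
    dir <- job$dir
    prev <- job$start
    px <- nx[prev]; py <- ny[prev]; pz <- nz[prev]
    for (k in seq_len(n_steps)) {
      dir <- .unit(dir + 0.25 * stats::rnorm(3))
      px <- px + spacing * dir[1L]
      py <- py + spacing * dir[2L]
      pz <- pz + spacing * dir[3L]
      r_k <- job$r_prox + (r_dist - job$r_prox) * (k / n_steps)
      prev <- add_node(px, py, pz, r_k, prev, seg_id)
    }
    segs[[seg_id]] <- data.frame(
      seg = seg_id, parent_seg = job$parent_seg, first_node = job$start,
      last_node = prev, L = L, r_proximal = job$r_prox, r_distal = r_dist,
      T = cfg$taper_factor, LR = L / job$r_prox)
    if (n_bif < cfg$max_bifurcations && r_dist > cfg$min_radius) {
      n_bif <- n_bif + 1L
      as_draw <- min(max(stats::rbeta(1, cfg$asymmetry_shape[1L],
                                      cfg$asymmetry_shape[2L]), 1e-6), 1)
      d <- sample_daughters(r_dist, as_draw, cfg$exponent)
      bifs[[n_bif]] <- data.frame(
        node = prev, seg_in = seg_id, r0 = r_dist, r1 = d[["r1"]],
        r2 = d[["r2"]], AS = as_draw,
        AR = (d[["r1"]]^2 + d[["r2"]]^2) / r_dist^2,
        n = (d[["r1"]]^3 + d[["r2"]]^3) / r_dist^3)
      for (rr in c(d[["r1"]], d[["r2"]]))
        queue[[length(queue) + 1L]] <-
          list(start = prev, r_prox = rr,
               dir = .unit(dir + 0.8 * stats::rnorm(3)),
               parent_seg = seg_id)
    }
  }
  idx <- seq_len(n_nodes)
  nodes <- data.frame(id = idx, x = nx[idx], y = ny[idx], z = nz[idx],
                      radius = rn[idx], parent = npar[idx])
  structure(list(
    tree = centerline_tree(nodes),
    true_radius = rt[idx],
    node_segment = nseg[idx],
    segments_truth = do.call(rbind, c(segs, list(make.row.names = FALSE))),
    bifurcations_truth = if (n_bif)
      do.call(rbind, c(bifs, list(make.row.names = FALSE)))
    else data.frame(node = integer(), seg_in = integer(), r0 = numeric(),
                    r1 = numeric(), r2 = numeric(), AS = numeric(),
                    AR = numeric(), n = numeric()),
    config = cfg
  ), class = "arbor_synthetic")
}

#' @export
print.arbor_synthetic <- function(x, ...) {
  cat("Synthetic arterial tree (exponent ", x$config$exponent, ", seed ",
      x$config$seed, ")\n", sep = "")
  cat("  ", nrow(x$tree$nodes), " nodes, ", nrow(x$segments_truth),
      " segments, ", nrow(x$bifurcations_truth), " bifurcations\n", sep = "")
  invisible(x)
}

#' Censor a synthetic tree at a detection radius
#'
#' Emulates the resolution limit of an imaging modality: every subtree whose
#' true proximal radius is below `censor_radius` is removed, as its branch
#' would not be detected. Branch points left with a single daughter become
#' pass-through nodes: their inbound and surviving outbound segments merge
#' into one, and the corresponding bifurcation record disappears. Surviving
#' bifurcation records keep their metrics unchanged. Censoring
#' preferentially removes small side branches, so the asymmetry and area
#' ratios of the surviving junctions drift upward — the mechanism behind the
#' ordering of AS across measurement modalities of increasing resolution.
#'
#' @param synth an `arbor_synthetic` from [generate_tree()].
#' @param censor_radius detection limit in mm; 0 returns the input
#'   unchanged.
#' @return a censored `arbor_synthetic` with merged segment truth and the
#'   surviving subset of bifurcation truth.
#' @export
censor_tree <- function(synth, censor_radius) {
  stopifnot(inherits(synth, "arbor_synthetic"), censor_radius >= 0)
  if (censor_radius == 0) return(synth)
  st <- synth$segments_truth
  ns <- nrow(st)
  surv <- logical(ns)
  for (i in seq_len(ns)) {   # parents precede children in creation order
    p <- st$parent_seg[i]
    surv[i] <- st$r_proximal[i] >= censor_radius &&
      (is.na(p) || surv[p])
  }
  if (!surv[1L]) stop("root segment falls below the censor radius")
  kids <- split(st$seg, factor(st$parent_seg, levels = st$seg))
  n_surv_kids <- vapply(st$seg, function(s) {
    k <- kids[[as.character(s)]]
    sum(surv[k])
  }, numeric(1))
  bt <- synth$bifurcations_truth
  bt_keep <- surv[bt$seg_in] & n_surv_kids[bt$seg_in] == 2L
  # merge surviving segments through pass-through junctions
  starts <- which(surv & (is.na(st$parent_seg) |
                            n_surv_kids[st$parent_seg] >= 2))
  merged <- lapply(starts, function(s) {
    chain <- s
    while (n_surv_kids[chain[length(chain)]] == 1L) {
      k <- kids[[as.character(chain[length(chain)])]]
      chain <- c(chain, k[surv[k]])
    }
    first <- chain[1L]; last <- chain[length(chain)]
    data.frame(seg = NA_integer_, parent_seg = st$parent_seg[first],
               first_node = st$first_node[first],
               last_node = st$last_node[last],
               L = sum(st$L[chain]),
               r_proximal = st$r_proximal[first],
               r_distal = st$r_distal[last],
               T = st$r_distal[last] / st$r_proximal[first],
               LR = sum(st$L[chain]) / st$r_proximal[first])
  })
  merged <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  merged$seg <- seq_len(nrow(merged))
  # prune the node-level tree
  keep_node <- surv[synth$node_segment]
  nodes <- synth$tree$nodes[keep_node, , drop = FALSE]
  out <- synth
  out$tree <- centerline_tree(nodes, voxel_size = synth$tree$voxel_size)
  out$true_radius <- synth$true_radius[keep_node]
  out$node_segment <- synth$node_segment[keep_node]
  out$segments_truth <- merged
  out$bifurcations_truth <- bt[bt_keep, , drop = FALSE]
  out$config$censor_radius <- censor_radius
  out
}

#' Rasterize a straight-tube phantom volume
#'
#' Builds a 3D intensity volume containing a straight tube of known radius
#' rendered as a signal void (low intensity) in a bright background, the
#' appearance of a resin cast embedded in gadolinium-doped gelatine. Voxels
#' are supersampled so partial-volume edge blur is realistic.
#'
#' @param radius tube radius, mm.
#' @param voxel_size isotropic voxel size, mm.
#' @param shape integer vector of 3 array dimensions (default 41^3).
#' @param direction tube axis (3-vector, normalized internally); the tube
#'   passes through the volume centre.
#' @param background,vessel intensity levels of gel and lumen.
#' @param supersample linear supersampling factor per voxel edge.
#' @param noise_sd SD of additive Gaussian intensity noise (0 = noiseless);
#'   uses the current RNG state.
#' @return object of class `vessel_phantom`: list with `intensity` (3D
#'   array), `voxel_size`, `center` (mm), `direction`, `radius`, and
#'   `reliable` (`FALSE` when the diameter is under two voxels).
#' @export
generate_vessel_phantom <- function(radius, voxel_size,
                                    shape = c(41L, 41L, 41L),
                                    direction = c(0, 0, 1),
                                    background = 100, vessel = 0,
                                    supersample = 3L, noise_sd = 0) {
  stopifnot(radius > 0, voxel_size > 0, length(shape) == 3L)
  d <- .unit(direction)
  center <- shape * voxel_size / 2
  ss <- supersample
  off <- (seq_len(ss) - (ss + 1) / 2) / ss * voxel_size
  cx <- (seq_len(shape[1L]) - 0.5) * voxel_size
  cy <- (seq_len(shape[2L]) - 0.5) * voxel_size
  cz <- (seq_len(shape[3L]) - 0.5) * voxel_size
  frac <- array(0, dim = shape)
  for (ox in off) for (oy in off) for (oz in off) {
    gx <- cx + ox - center[1L]
    gy <- cy + oy - center[2L]
    gz <- cz + oz - center[3L]
    # squared distance from the axis through the origin along d
    t <- outer(outer(gx * d[1L], gy * d[2L], "+"), gz * d[3L], "+")
    r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+") - t^2
    frac <- frac + (r2 <= radius^2)
  }
  frac <- frac / ss^3
  intensity <- background + (vessel - background) * frac
  if (noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(intensity), 0, noise_sd)
  structure(list(intensity = intensity, voxel_size = voxel_size,
                 center = center, direction = d, radius = radius,
                 reliable = 2 * radius >= 2 * voxel_size),
            class = "vessel_phantom")
}
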