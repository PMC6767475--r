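test_that("segment length sums Euclidean steps", {
  expect_equal(segment_length(cbind(0:2, 0, 0)), 2)
  expect_equal(segment_length(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))), 7)
  expect_error(segment_length(cbind(1, 1, 1)), "at least 2")
})

test_that("polyline length approaches the analytic helix arc length", {
  # helix radius a, pitch 2*pi*b per turn: arc length = t * sqrt(a^2 + b^2)
  a <- 2; b <- 0.5; tmax <- 4 * pi
  t <- seq(0, tmax, length.out = 100)
  pos <- cbind(a * cos(t), a * sin(t), b * t)
  exact <- tmax * sqrt(a^2 + b^2)
  expect_lt(segment_length(pos), exact)        # chords under-measure
  expect_equal(segment_length(pos), exact, tolerance = 1e-3)
})

test_that("cumulative arc length is a monotone prefix sum", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0), c(3, 4, 2))
  s <- cumulative_arclength(pos)
  expect_equal(s, c(0, 3, 7, 9))
  set.seed(1)
  rnd <- matrix(rnorm(30), ncol = 3)
  s2 <- cumulative_arclength(rnd)
  steps <- sqrt(rowSums(diff(rnd)^2))          # independent prefix-sum oracle
  expect_equal(s2, c(0, cumsum(steps)))
  expect_true(all(diff(s2) >= 0))
  expect_equal(s2[length(s2)], segment_length(rnd))
})

test_that("end radii come from the middle-quartile regression", {
  # constant radius: zero-slope line
  s <- seq(0, 5, length.out = 17)
  est <- estimate_end_radii(s, rep(0.5, 17))
  expect_equal(est$r_proximal, 0.5)
  expect_equal(est$r_distal, 0.5)
  expect_equal(est$flag, "none")

  # exact linear taper over 40 evenly spaced nodes, checked against an
  # independent normal-equation solve on the trimmed window
  s <- seq(0, 10, length.out = 40)
  r <- 1.0 - 0.05 * s
  est <- estimate_end_radii(s, r)
  expect_equal(est$r_proximal, 1.0, tolerance = 1e-12)
  expect_equal(est$r_distal, 0.5, tolerance = 1e-12)
  idx <- 11:30                                   # middle two quartiles of 40
  X <- cbind(1, s[idx])
  beta <- solve(t(X) %*% X, t(X) %*% r[idx])
  expect_equal(est$r_proximal, beta[1], tolerance = 1e-12)
  expect_equal(est$r_distal, beta[1] + beta[2] * 10, tolerance = 1e-12)
})

test_that("perturbations confined to the outer quartiles never move the estimates", {
  set.seed(42)
  for (n in c(8, 21, 40, 55)) {
    s <- sort(runif(n, 0, 10)); s[1] <- 0
    r <- 1 + 0.03 * s + rnorm(n, sd = 0.01)
    base <- estimate_end_radii(s, r)
    k <- floor(n / 4)
    r2 <- r
    r2[seq_len(k)] <- r2[seq_len(k)] + runif(k, -0.5, 0.5)
    r2[seq.int(n - k + 1, n)] <- r2[seq.int(n - k + 1, n)] + runif(k, -0.5, 0.5)
    pert <- estimate_end_radii(s, r2)
    expect_identical(pert$r_proximal, base$r_proximal)
    expect_identical(pert$r_distal, base$r_distal)
  }
  # a symmetric bump entirely inside the first quartile leaves the pure
  # linear fit untouched
  s <- seq(0, 10, length.out = 40)
  r <- 1 - 0.05 * s
  bump <- r
  bump[3:8] <- bump[3:8] + dnorm(3:8, mean = 5.5, sd = 1)
  est <- estimate_end_radii(s, bump)
  expect_equal(est$r_proximal, 1.0, tolerance = 1e-12)
  expect_equal(est$r_distal, 0.5, tolerance = 1e-12)
})

test_that("short chains fall back with an audit flag", {
  est <- estimate_end_radii(c(0, 1, 2), c(1, 2, 3))
  expect_equal(est$flag, "too_few_nodes")
  expect_equal(est$r_proximal, 2)
  expect_equal(est$r_distal, 2)
  # 5 nodes: widened middle window still yields the exact line
  s <- 0:4
  est5 <- estimate_end_radii(s, 1 + 0.1 * s)
  expect_equal(est5$r_proximal, 1, tolerance = 1e-12)
  expect_equal(est5$r_distal, 1.4, tolerance = 1e-12)
})

test_that("tapering and LR behave at the boundaries", {
  expect_equal(tapering(1, 1), 1)
  expect_equal(tapering(1, 0.5), 0.5)
  expect_true(is.na(tapering(0, 1)))
  expect_equal(length_radius_ratio(10, 1), 10)
  expect_equal(length_radius_ratio(0, 1), 0)
  expect_true(is.na(length_radius_ratio(5, 0)))
})

test_that("the two-voxel filter excludes by proximal diameter", {
  diam <- c(0.10, 0.15, 0.20, 0.25, 0.30)
  metrics <- data.frame(segment = 1:5, n_nodes = 10, L = 1,
                        r_proximal = diam / 2, r_distal = diam / 2,
                        T = 1, LR = 1 / diam, included = TRUE,
                        reason = "none")
  bifs <- records_from_radii(c(0.12, 0.2), list(c(0.10, 0.095),
                                                c(0.15, 0.12)))
  out <- apply_resolution_filter(metrics, bifs, voxel_size = 0.1)
  expect_equal(sum(out$metrics$included), 3)
  expect_equal(out$metrics$reason[1:2], rep("below_two_voxel", 2))
  # first bifurcation has a 0.19 mm daughter diameter -> excluded
  expect_equal(out$bifurcations$included, c(FALSE, TRUE))
  # no voxel size: filter skipped
  skip <- apply_resolution_filter(metrics, bifs, voxel_size = NULL)
  expect_equal(sum(skip$metrics$included), 5)
})

test_that("shrinking the voxel never excludes a previously included item", {
  set.seed(7)
  metrics <- data.frame(segment = 1:50, n_nodes = 10, L = 1,
                        r_proximal = runif(50, 0.02, 0.5), r_distal = 0.1,
                        T = 1, LR = 1, included = TRUE, reason = "none")
  bifs <- records_from_radii(runif(20, 0.05, 0.5),
                             replicate(20, runif(2, 0.02, 0.4),
                                       simplify = FALSE))
  vox <- c(0.2, 0.1, 0.05, 0.025)
  prev_m <- rep(FALSE, 50); prev_b <- rep(FALSE, 20)
  for (v in vox) {
    out <- apply_resolution_filter(metrics, bifs, voxel_size = v)
    expect_true(all(out$metrics$included | !prev_m))
    expect_true(all(out$bifurcations$included | !prev_b))
    prev_m <- out$metrics$included
    prev_b <- out$bifurcations$included
  }
})

test_that("endpoint-radius errors on noisy generator trees are below the node noise", {
  sd_noise <- 0.02
  syn <- generate_tree(generator_config(seed = 21, max_bifurcations = 150,
                                        radius_noise_sd = sd_noise))
  segs <- split_into_segments(syn$tree)
  metrics <- segment_metrics(segs)
  first <- vapply(segs, `[`, integer(1), 1)
  last <- vapply(segs, function(s) s[length(s)], integer(1))
  tr <- syn$segments_truth
  m <- match(paste(first, last), paste(tr$first_node, tr$last_node))
  rel_err <- abs(metrics$r_proximal - tr$r_proximal[m]) / tr$r_proximal[m]
  expect_lt(mean(rel_err), sd_noise)   # regression averages node noise
})
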