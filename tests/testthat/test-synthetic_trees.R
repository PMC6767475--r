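test_that("sample_daughters inverts the branching relation exactly", {
  d <- sample_daughters(1, 1, 3)
  expect_equal(unname(d), rep(2^(-1 / 3), 2), tolerance = 1e-15)
  d2 <- sample_daughters(1, 0.25, 3)
  expect_equal(d2[["r1"]]^3 + d2[["r2"]]^3, 1, tolerance = 1e-12)
  expect_equal((d2[["r2"]] / d2[["r1"]])^2, 0.25, tolerance = 1e-12)
  expect_equal(murray_n(1, unname(d2)), 1, tolerance = 1e-12)
  # general exponent
  d3 <- sample_daughters(0.7, 0.6, 2.6)
  expect_equal(d3[["r1"]]^2.6 + d3[["r2"]]^2.6, 0.7^2.6, tolerance = 1e-12)
  expect_error(sample_daughters(1, 1.5, 3), "AS")
  expect_error(sample_daughters(-1, 0.5, 3), "r0")
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(seed = 77, max_bifurcations = 20,
                          radius_noise_sd = 0.05)
  a <- generate_tree(cfg)
  b <- generate_tree(cfg)
  p1 <- withr::local_tempfile(fileext = ".swc")
  p2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(a$tree, p1); write_swc(b$tree, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(a$bifurcations_truth, b$bifurcations_truth)
})

test_that("generated junctions satisfy the branching relation before noise", {
  for (x in c(2.33, 3)) {
    syn <- generate_tree(generator_config(seed = 13, exponent = x,
                                          max_bifurcations = 60,
                                          radius_noise_sd = 0.1))
    bt <- syn$bifurcations_truth
    defect <- abs(bt$r0^x - bt$r1^x - bt$r2^x) / bt$r0^x
    expect_lt(max(defect), 1e-12)
    # exponent recovery from noiseless truth radii
    xs <- vapply(seq_len(nrow(bt)), function(i)
      junction_exponent(bt$r0[i], c(bt$r1[i], bt$r2[i])), numeric(1))
    expect_lt(max(abs(xs - x)), 1e-8)
  }
})

test_that("ground truth is internally consistent and matches the config", {
  cfg <- generator_config(seed = 31, max_bifurcations = 40,
                          taper_factor = 0.95, radius_noise_sd = 0)
  syn <- generate_tree(cfg)
  st <- syn$segments_truth
  expect_true(all(abs(st$T - 0.95) < 1e-12))
  expect_equal(st$LR, st$L / st$r_proximal)
  expect_equal(st$r_distal, 0.95 * st$r_proximal)
  bt <- syn$bifurcations_truth
  expect_equal(bt$AS, (bt$r2 / bt$r1)^2, tolerance = 1e-12)
  expect_equal(bt$AR, (bt$r1^2 + bt$r2^2) / bt$r0^2, tolerance = 1e-12)
  # per-node truth equals the noiseless tree radii when noise is off
  expect_equal(syn$tree$nodes$radius, syn$true_radius)
  validate_centerline_tree(syn$tree)
})

test_that("unbounded configurations are rejected", {
  expect_error(generator_config(taper_factor = 1.1,
                                max_bifurcations = Inf), "terminate")
  expect_error(generator_config(min_radius = 0, max_bifurcations = Inf),
               "terminate")
  expect_silent(generator_config(taper_factor = 1.1,
                                 max_bifurcations = 50))
})

test_that("censoring at zero is the identity and pruning only removes records", {
  syn <- generate_tree(generator_config(seed = 41, max_bifurcations = 80,
                                        radius_noise_sd = 0.02))
  expect_identical(censor_tree(syn, 0), syn)
  cz <- censor_tree(syn, 0.08)
  validate_centerline_tree(cz$tree)
  expect_lt(nrow(cz$tree$nodes), nrow(syn$tree$nodes))
  # surviving bifurcation records keep their metrics bit-for-bit
  keys <- paste(cz$bifurcations_truth$node)
  orig <- syn$bifurcations_truth[match(keys, syn$bifurcations_truth$node), ]
  expect_equal(cz$bifurcations_truth$AS, orig$AS)
  expect_equal(cz$bifurcations_truth$AR, orig$AR)
  expect_equal(cz$bifurcations_truth$r0, orig$r0)
  # no surviving daughter radius below the detection limit
  expect_true(all(c(cz$bifurcations_truth$r1, cz$bifurcations_truth$r2) >=
                    0.08))
  # pass-through junctions were merged: re-splitting the pruned tree gives
  # exactly the merged segment truth
  segs <- split_into_segments(cz$tree)
  expect_equal(length(segs), nrow(cz$segments_truth))
  expect_error(censor_tree(syn, 2), "root")
})

test_that("censored trees keep segment truth consistent after merging", {
  syn <- generate_tree(generator_config(seed = 51, max_bifurcations = 60,
                                        radius_noise_sd = 0))
  cz <- censor_tree(syn, 0.1)
  segs <- split_into_segments(cz$tree)
  metrics <- segment_metrics(segs)
  first <- vapply(segs, `[`, integer(1), 1)
  last <- vapply(segs, function(s) s[length(s)], integer(1))
  st <- cz$segments_truth
  m <- match(paste(cz$tree$nodes$id[first], cz$tree$nodes$id[last]),
             paste(st$first_node, st$last_node))
  expect_false(anyNA(m))
  expect_equal(metrics$L, st$L[m], tolerance = 1e-9)
})

test_that("tube phantoms have the right void volume and reproducible noise", {
  ph <- generate_vessel_phantom(0.3, 0.1, shape = c(25, 25, 9))
  # voxel-count oracle: void area per axial slice ~ pi r^2
  void <- (100 - ph$intensity[, , 5]) / 100
  expect_equal(sum(void) * 0.1^2, pi * 0.3^2, tolerance = 0.02)
  # far corners are pure background
  expect_equal(ph$intensity[1, 1, 5], 100)
  expect_false(generate_vessel_phantom(0.05, 0.1)$reliable)
  set.seed(1); n1 <- generate_vessel_phantom(0.3, 0.1, noise_sd = 2)
  set.seed(1); n2 <- generate_vessel_phantom(0.3, 0.1, noise_sd = 2)
  expect_identical(n1$intensity, n2$intensity)
})
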