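test_that("a minimal SWC chain parses into one segment", {
  path <- swc_lines(chain_tree(3))
  tree <- read_swc(path)
  expect_equal(nrow(tree$nodes), 3)
  segs <- split_into_segments(tree)
  expect_length(segs, 1)
  expect_equal(segs[[1]], 1:3)
})

test_that("SWC parse and structure errors are reported", {
  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# header", "1 0 0 0 0 1.0 -1", "2 0 1 0 0 1.0"), bad)
  expect_error(read_swc(bad), "line 3")

  orphan <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1.0 -1", "2 0 1 0 0 1.0 99"), orphan)
  expect_error(read_swc(orphan), "parent id")

  negr <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1.0 -1", "2 0 1 0 0 -0.5 1"), negr)
  expect_error(read_swc(negr), "radii")

  two_roots <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 -1"), two_roots)
  expect_error(read_swc(two_roots), "root")
})

test_that("a Y-shaped tree has one branch node and three segments", {
  path <- swc_lines(y_tree(trunk = 3, arm = 2))
  tree <- read_swc(path)
  segs <- split_into_segments(tree)
  expect_length(segs, 3)
  expect_length(attr(segs, "branch_nodes"), 1)
  # branch node is the trunk end and starts both daughter segments
  firsts <- vapply(segs, `[`, integer(1), 1)
  expect_equal(sum(firsts == attr(segs, "branch_nodes")), 2)
})

test_that("SWC round-trips node ids, positions and radii", {
  syn <- generate_tree(generator_config(seed = 3, max_bifurcations = 10))
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(syn$tree, path)
  back <- read_swc(path)
  expect_equal(back$nodes$id, syn$tree$nodes$id)
  expect_equal(back$nodes$radius, syn$tree$nodes$radius, tolerance = 1e-7)
  expect_equal(back$nodes$x, syn$tree$nodes$x, tolerance = 1e-7)
  expect_equal(back$nodes$parent, syn$tree$nodes$parent)
})

test_that("the CSV node-table dialect matches SWC, including unit conversion", {
  tree <- y_tree()
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tree$nodes, csv, row.names = FALSE)
  expect_equal(read_node_table(csv)$nodes, tree$nodes)
  # same table expressed in micrometres
  um <- tree$nodes
  um[c("x", "y", "z", "radius")] <- um[c("x", "y", "z", "radius")] * 1000
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(um, csv2, row.names = FALSE)
  expect_equal(read_node_table(csv2, units = "um")$nodes$radius,
               tree$nodes$radius)
})

test_that("segmentation partitions edges on random trees", {
  for (seed in 1:4) {
    syn <- generate_tree(generator_config(seed = seed,
                                          max_bifurcations = 25))
    segs <- split_into_segments(syn$tree)
    n_edges <- sum(!is.na(syn$tree$nodes$parent))
    # edge conservation: each segment covers len-1 edges, none shared
    expect_equal(sum(lengths(segs) - 1L), n_edges)
    covered <- unlist(lapply(segs, function(s) s[-1L]))
    expect_equal(sort(covered), sort(which(!is.na(syn$tree$nodes$parent))))
    # binary tree with B branch nodes -> 2B + 1 segments
    B <- length(attr(segs, "branch_nodes"))
    expect_equal(length(segs), 2 * B + 1)
    # interior nodes of a segment never branch
    interior <- unlist(lapply(segs, function(s) s[-c(1L, length(s))]))
    expect_false(any(interior %in% attr(segs, "branch_nodes")))
  }
})

test_that("bifurcation extraction pairs segment-end radii", {
  tree <- y_tree(trunk = 8, arm = 8, r_trunk = 1, r_arm1 = 0.8,
                 r_arm2 = 0.6)
  segs <- split_into_segments(tree)
  metrics <- segment_metrics(segs)
  bifs <- extract_bifurcations(segs, metrics)
  expect_equal(nrow(bifs), 1)
  expect_true(bifs$usable)
  expect_equal(bifs$r0, 1)
  expect_equal(bifs$r1, 0.8)
  expect_equal(bifs$r2, 0.6)
  # record count equals internal branch node census on random trees
  syn <- generate_tree(generator_config(seed = 11, max_bifurcations = 30))
  s2 <- split_into_segments(syn$tree)
  b2 <- extract_bifurcations(s2, segment_metrics(s2))
  ch <- table(syn$tree$nodes$parent)
  expect_equal(nrow(b2), sum(ch >= 2))
})

test_that("trifurcations are recorded but flagged not-a-bifurcation downstream", {
  # trunk of 3, three daughters of 2 nodes each
  nodes <- data.frame(
    id = 1:9,
    x = c(0, 1, 2, 3, 4, 3, 4, 3, 4),
    y = c(0, 0, 0, 1, 2, 0, 0, -1, -2),
    z = 0,
    radius = c(1, 1, 1, rep(0.7, 6)),
    parent = c(NA, 1, 2, 3, 4, 3, 6, 3, 8))
  tree <- centerline_tree(nodes)
  segs <- split_into_segments(tree)
  expect_length(segs, 4)
  bifs <- bifurcation_metrics(extract_bifurcations(segs, segment_metrics(segs)))
  expect_equal(bifs$n_daughters, 3)
  expect_false(is.na(bifs$AR))
  expect_true(is.na(bifs$AS))
  expect_true(is.na(bifs$n))
})

test_that("reports are deterministic TSV", {
  tab <- data.frame(source = "syn", n = 2L, median = c(1.5, 2.5),
                    iqr = c(0.5, 1), min = 0, max = 3)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, p1)
  write_report(tab, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[1], "source\tn\tmedian")
  # empty table -> header only
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab[0, ], p3)
  expect_length(readLines(p3), 1)
})
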