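# Fixture builders shared across test files. All trees are built in code.

# straight chain of n nodes along x, constant radius
chain_tree <- function(n = 3, radius = 1, spacing = 1) {
  centerline_tree(data.frame(
    id = seq_len(n), x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    radius = radius, parent = c(NA, seq_len(n - 1))))
}

# Y tree: trunk of `trunk` nodes then two daughter chains of `arm` nodes.
# Radii constant per branch.
y_tree <- function(trunk = 3, arm = 2, r_trunk = 1, r_arm1 = 0.8,
                   r_arm2 = 0.8) {
  ids <- seq_len(trunk + 2 * arm)
  trunk_ids <- seq_len(trunk)
  a1 <- trunk + seq_len(arm)
  a2 <- trunk + arm + seq_len(arm)
  nodes <- data.frame(
    id = ids,
    x = c((trunk_ids - 1), trunk - 1 + seq_len(arm), trunk - 1 + seq_len(arm)),
    y = c(rep(0, trunk), seq_len(arm), -seq_len(arm)),
    z = 0,
    radius = c(rep(r_trunk, trunk), rep(r_arm1, arm), rep(r_arm2, arm)),
    parent = c(NA, trunk_ids[-trunk], trunk, if (arm > 1) a1[-arm],
               trunk, if (arm > 1) a2[-arm]))
  centerline_tree(nodes)
}

swc_lines <- function(tree) {
  path <- withr::local_tempfile(fileext = ".swc",
                                .local_envir = parent.frame())
  write_swc(tree, path)
  path
}

# bifurcation_records table built directly from radii (bypasses a tree)
records_from_radii <- function(r0, daughters) {
  rec <- data.frame(node_id = seq_along(r0), r0 = r0,
                    r1 = vapply(daughters, max, numeric(1)),
                    r2 = vapply(daughters, function(d) sort(d, TRUE)[2],
                                numeric(1)),
                    n_daughters = lengths(daughters),
                    usable = TRUE)
  rec$daughter_radii <- lapply(daughters, sort, decreasing = TRUE)
  class(rec) <- c("bifurcation_records", "data.frame")
  rec
}
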