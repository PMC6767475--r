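# Reading, validating and decomposing centerline trees.
#
# A centerline tree is a rooted tree of 3D nodes, each carrying a radius in
# mm; edges run from a node to its parent. Trees come from SWC files (the
# standard 7-column dialect used for radius-bearing centerlines) or from CSV
# node tables with the same columns.

#' Construct a centerline tree from a node table
#'
#' The canonical in-memory representation of a measured arterial tree: a
#' rooted tree of 3D nodes, each with a radius in millimetres. Node ids need
#' not be consecutive; the parent of the root is `NA`.
#'
#' @param nodes data frame with columns `id` (integer), `x`, `y`, `z`
#'   (positions, mm), `radius` (mm, positive) and `parent` (id of the parent
#'   node, `NA` or `-1` for the root).
#' @param voxel_size optional acquisition voxel size in mm (isotropic);
#'   records the resolution provenance and drives the two-voxel exclusion
#'   filter. Leave `NULL` for dissection or cast-caliper data.
#' @param units units of the `radius`/position columns, `"mm"` (default) or
#'   `"um"`; micrometre input is converted to mm.
#' @return an object of class `centerline_tree`: a list with elements
#'   `nodes` (validated node data frame, positions and radii in mm) and
#'   `voxel_size`.
#' @seealso [read_swc()], [split_into_segments()]
#' @export
centerline_tree <- function(nodes, voxel_size = NULL, units = c("mm", "um")) {
  units <- match.arg(units)
  required <- c("id", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols))
    stop("node table lacks columns: ", paste(missing_cols, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- suppressWarnings(as.integer(nodes$parent))
  nodes$parent[!is.na(nodes$parent) & nodes$parent < 0] <- NA_integer_
  for (cc in c("x", "y", "z", "radius"))
    nodes[[cc]] <- as.numeric(nodes[[cc]])
  if (units == "um") {
    nodes[c("x", "y", "z", "radius")] <- nodes[c("x", "y", "z", "radius")] / 1000
    if (!is.null(voxel_size)) voxel_size <- voxel_size / 1000
  }
  tree <- structure(list(nodes = nodes, voxel_size = voxel_size),
                    class = "centerline_tree")
  validate_centerline_tree(tree)
}

#' Validate a centerline tree
#'
#' Checks the structural invariants: positive radii, unique ids, exactly one
#' root, every parent id present, and no cycles (every node reaches the root).
#'
#' @param tree a `centerline_tree`.
#' @return the tree, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_centerline_tree <- function(tree) {
  nodes <- tree$nodes
  if (!nrow(nodes)) stop("tree has no nodes")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0))
    stop("all radii must be positive and finite")
  if (any(!is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    stop("non-finite node positions")
  root <- which(is.na(nodes$parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root, found ", length(root))
  known <- nodes$parent[!is.na(nodes$parent)]
  orphan <- setdiff(known, nodes$id)
  if (length(orphan))
    stop("parent id(s) not present in tree: ", paste(orphan, collapse = ", "))
  # cycle / connectivity check: follow parents with a depth bound
  idx <- match(nodes$parent, nodes$id)
  depth <- rep.int(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  pending <- which(is.na(depth))
  guard <- 0L
  while (length(pending)) {
    ready <- pending[!is.na(depth[idx[pending]])]
    if (!length(ready)) stop("tree contains a cycle or disconnected component")
    depth[ready] <- depth[idx[ready]] + 1L
    pending <- setdiff(pending, ready)
    guard <- guard + 1L
    if (guard > nrow(nodes)) stop("tree contains a cycle")
  }
  if (!is.null(tree$voxel_size) &&
      (!is.finite(tree$voxel_size) || tree$voxel_size <= 0))
    stop("voxel_size must be a positive number")
  invisible(tree)
}

#' @export
print.centerline_tree <- function(x, ...) {
  deg <- tabulate(match(x$nodes$parent, x$nodes$id), nbins = nrow(x$nodes))
  cat("Centerline tree: ", nrow(x$nodes), " nodes, ",
      sum(deg >= 2), " branch point(s), ", sum(deg == 0), " terminal(s)\n",
      sep = "")
  cat("  radius range [mm]: ",
      format(min(x$nodes$radius), digits = 3), " - ",
      format(max(x$nodes$radius), digits = 3), "\n", sep = "")
  if (!is.null(x$voxel_size))
    cat("  voxel size [mm]: ", x$voxel_size, "\n", sep = "")
  invisible(x)
}

#' Read a centerline tree from an SWC file
#'
#' Parses the standard 7-column SWC dialect (id, type, x, y, z, radius,
#' parent; `#` starts a comment) into a validated [centerline_tree()]. The
#' radius column is taken as a radius in mm unless `units = "um"`.
#'
#' @param path path to the SWC file.
#' @inheritParams centerline_tree
#' @return a `centerline_tree`.
#' @export
read_swc <- function(path, voxel_size = NULL, units = c("mm", "um")) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data lines in SWC file: ", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", rows[bad[1L]], ": expected 7 fields, got ",
         lengths(fields)[bad[1L]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  nn <- which(apply(m, 1L, function(r) any(is.na(r))))
  if (length(nn))
    stop("malformed SWC line ", rows[nn[1L]], ": non-numeric field")
  nodes <- data.frame(id = as.integer(m[, 1L]), x = m[, 3L], y = m[, 4L],
                      z = m[, 5L], radius = m[, 6L],
                      parent = as.integer(m[, 7L]))
  centerline_tree(nodes, voxel_size = voxel_size, units = units)
}

#' Write a centerline tree to an SWC file
#'
#' @param tree a `centerline_tree`.
#' @param path output path.
#' @param type SWC type code to write in column 2 (vasculature has no
#'   standard code; 0 by default).
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path, type = 0L) {
  nodes <- tree$nodes
  parent <- ifelse(is.na(nodes$parent), -1L, nodes$parent)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   nodes$id, type, nodes$x, nodes$y, nodes$z,
                   nodes$radius, parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' Read a centerline tree from a CSV node table
#'
#' Accepts a comma-separated table with header columns `id,x,y,z,radius,parent`
#' (any order, extra columns ignored) as an alternative to SWC.
#'
#' @inheritParams read_swc
#' @return a `centerline_tree`.
#' @export
read_node_table <- function(path, voxel_size = NULL, units = c("mm", "um")) {
  nodes <- utils::read.csv(path)
  centerline_tree(nodes, voxel_size = voxel_size, units = units)
}

# children ids of each node, as a list indexed like tree$nodes
.children <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)
  ch <- vector("list", nrow(nodes))
  for (i in which(!is.na(idx))) ch[[idx[i]]] <- c(ch[[idx[i]]], i)
  ch
}

#' Split a centerline tree into inter-bifurcation segments
#'
#' A segment is the chain of nodes between two consecutive branch points (or
#' between the root / a terminal and the nearest branch point). Branch points
#' are nodes with two or more children; they are shared between the inbound
#' segment (as its last node) and each outbound segment (as its first node),
#' so every edge belongs to exactly one segment.
#'
#' @param tree a `centerline_tree`.
#' @return a list of class `arbor_segments`; each element is a segment given
#'   as an integer vector of row indices into `tree$nodes`, ordered from the
#'   proximal (upstream) to the distal end. Attributes `branch_nodes`
#'   (row indices of branch points) and `tree` (the input) are attached.
#' @export
split_into_segments <- function(tree) {
  validate_centerline_tree(tree)
  nodes <- tree$nodes
  ch <- .children(nodes)
  nch <- lengths(ch)
  root <- which(is.na(nodes$parent))
  starts <- c(root, which(nch >= 2L))
  segs <- list()
  for (s in starts) {
    for (child in ch[[s]]) {
      chain <- c(s, child)
      cur <- child
      while (nch[cur] == 1L) {
        cur <- ch[[cur]][1L]
        chain <- c(chain, cur)
      }
      segs[[length(segs) + 1L]] <- chain
    }
  }
  structure(segs, class = "arbor_segments",
            branch_nodes = which(nch >= 2L), tree = tree)
}

#' Extract bifurcation records from a segmented tree
#'
#' One record per branch point. The parent radius `r0` is the distal radius
#' of the inbound segment and the daughter radii are the proximal radii of
#' the outbound segments, all as estimated by the quartile-trimmed segment
#' regression — node radii at the junction itself are distrusted because the
#' radius dips just before and after a bifurcation. Daughters are sorted in
#' non-increasing order so `r1 >= r2`.
#'
#' @param segments an `arbor_segments` list from [split_into_segments()].
#' @param metrics per-segment metrics from [segment_metrics()]; aligned with
#'   `segments`.
#' @return data frame of class `bifurcation_records` with one row per branch
#'   point: `node_id`, `r0`, `r1`, `r2`, `n_daughters`, `daughter_radii`
#'   (list column, all daughters, non-increasing), and `usable` (`FALSE` when
#'   the branch point has no inbound segment, e.g. the root, or any incident
#'   segment radius is missing).
#' @export
extract_bifurcations <- function(segments, metrics) {
  if (length(segments) != nrow(metrics))
    stop("metrics must have one row per segment")
  tree <- attr(segments, "tree")
  last <- vapply(segments, function(s) s[length(s)], integer(1))
  first <- vapply(segments, function(s) s[1L], integer(1))
  branch <- attr(segments, "branch_nodes")
  if (!length(branch)) {
    out <- data.frame(node_id = integer(), r0 = numeric(), r1 = numeric(),
                      r2 = numeric(), n_daughters = integer(),
                      usable = logical())
    out$daughter_radii <- list()
    class(out) <- c("bifurcation_records", "data.frame")
    return(out)
  }
  recs <- lapply(branch, function(b) {
    inbound <- which(last == b)
    outbound <- which(first == b)
    r0 <- if (length(inbound) == 1L) metrics$r_distal[inbound] else NA_real_
    dr <- sort(metrics$r_proximal[outbound], decreasing = TRUE)
    data.frame(node_id = tree$nodes$id[b],
               r0 = r0,
               r1 = dr[1L],
               r2 = if (length(dr) >= 2L) dr[2L] else NA_real_,
               n_daughters = length(dr),
               usable = length(inbound) == 1L && is.finite(r0) &&
                 all(is.finite(dr)) && r0 > 0 && all(dr > 0))
  })
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(node_id = integer(), r0 = numeric(), r1 = numeric(),
                      r2 = numeric(), n_daughters = integer(),
                      usable = logical())
  out$daughter_radii <- lapply(branch, function(b)
    sort(metrics$r_proximal[which(first == b)], decreasing = TRUE))
  class(out) <- c("bifurcation_records", "data.frame")
  out
}

#' Write a result table as TSV
#'
#' Writes a data frame as a tab-separated file with a fixed column order, so
#' that repeated runs with the same inputs produce byte-identical reports.
#'
#' @param table data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  tab <- as.data.frame(table)
  tab <- tab[!vapply(tab, is.list, logical(1))]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 9, format = "g"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
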