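#' Build the colour-coded cluster map of a core
#'
#' The lattice cell (row, col) holds the cluster index of the retained patch
#' tiled there; cells without a retained patch are background (NA). The
#' rendering is a display concern only: permuting the palette changes
#' colours, never the lattice.
#'
#' @param grid the `patch_grid` of the core.
#' @param assignment a `cluster_assignment` covering exactly this grid's
#'   patches (same order).
#' @param model the `cluster_model` (palette source).
#' @return a `cluster_map`: `core_id`, `patient_id`, `lattice` (integer
#'   matrix with NA off-tissue), `palette`.
#' @export
build_cluster_map <- function(grid, assignment, model) {
  e <- grid$entries
  ok <- nrow(e) == length(assignment$cluster) &&
    all(assignment$ids$row == e$row) && all(assignment$ids$col == e$col)
  if (!ok) {
    stop_input("assignment does not cover the grid entries one-to-one",
               "renograph_consistency")
  }
  lattice <- matrix(NA_integer_, max(1L, grid$n_rows), max(1L, grid$n_cols))
  lattice[cbind(e$row, e$col)] <- assignment$cluster
  structure(
    list(core_id = grid$core$core_id, patient_id = grid$core$patient_id,
         lattice = lattice, palette = model$palette),
    class = "cluster_map"
  )
}

#' Render a cluster map as an RGB image
#'
#' @param map a `cluster_map`.
#' @param cell_px display size of one lattice cell in pixels.
#' @param background background colour (hex) for off-tissue cells.
#' @return H x W x 3 array on the 0..1 scale (ready for [png::writePNG()]).
#' @export
render_cluster_map <- function(map, cell_px = 8L, background = "#FFFFFF") {
  lat <- map$lattice
  cols <- c(map$palette, background)
  idx <- lat
  idx[is.na(idx)] <- length(cols)
  rgb <- grDevices::col2rgb(cols) / 255
  big <- idx[rep(seq_len(nrow(lat)), each = cell_px),
             rep(seq_len(ncol(lat)), each = cell_px), drop = FALSE]
  out <- array(0, dim = c(dim(big), 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, big], nrow(big), ncol(big))
  out
}

#' Convert a cluster map into a spatial graph
#'
#' One node per tissue lattice cell in deterministic row-major order; an
#' undirected edge joins every pair of cells adjacent under the chosen rule
#' (`rook` = 4-neighbourhood, `queen` = 8). Node features are the MDS
#' coordinates of the cell's cluster (shared by all patches of a cluster);
#' optionally a one-hot cluster indicator is appended. Fragmented cores
#' yield one graph with several components.
#'
#' @param map a `cluster_map`.
#' @param model the `cluster_model` supplying MDS coordinates.
#' @param adjacency `"rook"` or `"queen"`.
#' @param label optional core-level outcome in `{-1, +1}`.
#' @param onehot append a one-hot cluster indicator to the node features.
#' @return a `core_graph`: `core_id`, `patient_id`, `nodes` (tibble: row,
#'   col, cluster, feature columns x1..xm), `edges` (2-column matrix of node
#'   indices, i < j), `label` (or NA).
#' @export
build_core_graph <- function(map, model, adjacency = c("rook", "queen"),
                             label = NULL, onehot = FALSE) {
  adjacency <- match.arg(adjacency)
  lat <- map$lattice
  cells <- which(!is.na(lat), arr.ind = TRUE)
  if (nrow(cells) == 0) stop_input("empty cluster map", "renograph_empty")
  # row-major canonical node order
  ord <- order(cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]
  cl <- lat[cells]
  feat <- model$mds_coords[cl, , drop = FALSE]
  if (onehot) {
    oh <- matrix(0, nrow(cells), model$k)
    oh[cbind(seq_len(nrow(cells)), cl)] <- 1
    feat <- cbind(feat, oh)
  }
  nodeindex <- matrix(NA_integer_, nrow(lat), ncol(lat))
  nodeindex[cells] <- seq_len(nrow(cells))
  offs <- rbind(c(0L, 1L), c(1L, 0L))
  if (adjacency == "queen") offs <- rbind(offs, c(1L, 1L), c(1L, -1L))
  ee <- list()
  for (k in seq_len(nrow(offs))) {
    rr <- cells[, 1] + offs[k, 1]; cc <- cells[, 2] + offs[k, 2]
    ok <- rr >= 1 & rr <= nrow(lat) & cc >= 1 & cc <= ncol(lat)
    j <- rep(NA_integer_, nrow(cells))
    j[ok] <- nodeindex[cbind(rr[ok], cc[ok])]
    keep <- !is.na(j)
    ee[[k]] <- cbind(which(keep), j[keep])
  }
  edges <- do.call(rbind, ee)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
  nodes <- tibble(row = cells[, 1], col = cells[, 2], cluster = cl)
  fdf <- stats::setNames(as.data.frame(feat), paste0("x", seq_len(ncol(feat))))
  structure(
    list(core_id = map$core_id, patient_id = map$patient_id,
         nodes = as_tibble(cbind(nodes, fdf)), edges = edges,
         label = if (is.null(label)) NA_integer_ else as.integer(label)),
    class = "core_graph"
  )
}

#' @export
print.core_graph <- function(x, ...) {
  cat("<core_graph>", x$core_id, ":", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges, label", x$label, "\n")
  invisible(x)
}

graph_feature_cols <- function(g) grep("^x\\d+$", names(g$nodes), value = TRUE)

# Node feature matrix of a core_graph.
graph_features <- function(g) {
  as.matrix(g$nodes[, graph_feature_cols(g), drop = FALSE])
}

#' Write a core graph to GraphML
#'
#' Node attributes: row, col, cluster and the feature vector; graph
#' attributes: core_id, patient_id and (when labelled) the outcome label.
#'
#' @param g a `core_graph`.
#' @param path output file.
#' @export
write_core_graph <- function(g, path) {
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  if (nrow(g$edges) > 0) ig <- igraph::add_edges(ig, t(g$edges))
  igraph::V(ig)$row <- g$nodes$row
  igraph::V(ig)$col <- g$nodes$col
  igraph::V(ig)$cluster <- g$nodes$cluster
  for (fc in graph_feature_cols(g)) {
    ig <- igraph::set_vertex_attr(ig, fc, value = g$nodes[[fc]])
  }
  ig <- igraph::set_graph_attr(ig, "core_id", g$core_id)
  ig <- igraph::set_graph_attr(ig, "patient_id", g$patient_id)
  if (!is.na(g$label)) ig <- igraph::set_graph_attr(ig, "label", g$label)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a core graph from GraphML
#' @param path file written by [write_core_graph()].
#' @return a `core_graph`; the label attribute, when absent in the file, is
#'   read back as unlabelled (NA).
#' @export
read_core_graph <- function(path) {
  ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                 error = function(e) {
                   stop_input(paste0("malformed GraphML '", path, "': ",
                                     conditionMessage(e)), "renograph_parse")
                 })
  va <- igraph::vertex_attr(ig)
  fcols <- sort(grep("^x\\d+$", names(va), value = TRUE))
  nodes <- tibble(row = as.integer(va$row), col = as.integer(va$col),
                  cluster = as.integer(va$cluster))
  for (fc in fcols) nodes[[fc]] <- as.numeric(va[[fc]])
  edges <- igraph::as_edgelist(ig, names = FALSE)
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0) {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
  }
  lab <- igraph::graph_attr(ig, "label")
  structure(
    list(core_id = igraph::graph_attr(ig, "core_id"),
         patient_id = igraph::graph_attr(ig, "patient_id"),
         nodes = nodes, edges = edges,
         label = if (is.null(lab)) NA_integer_ else as.integer(round(as.numeric(lab)))),
    class = "core_graph"
  )
}
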