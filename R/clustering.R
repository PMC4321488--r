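# Single-linkage clustering of per-frame unit cells, threshold cutting,
# cluster summaries and exports.

#' Single-linkage hierarchical clustering of a distance matrix
#'
#' Thin wrapper over [stats::hclust()] with `method = "single"`: the
#' inter-cluster distance is the minimum pairwise member distance, so merge
#' heights are a non-decreasing sequence.
#'
#' @param d A `stats::dist` object.
#' @return An `hclust` object.
#' @export
single_linkage <- function(d) {
  if (!inherits(d, "dist")) abort("single_linkage() expects a stats::dist object")
  if (attr(d, "Size") < 2L) abort("need at least two observations to cluster")
  hclust(d, method = "single")
}

#' Cut a dendrogram at a distance threshold
#'
#' Flat clusters are the connected components formed by merges *strictly
#' below* the threshold (a merge exactly at the threshold does not join).
#' Clusters are labelled in order of decreasing size (ties broken by the
#' smallest member index); single-member clusters are flagged as singletons.
#'
#' @param hc An `hclust` object (or a `cell_clusters` object to re-cut).
#' @param threshold Cut height in A^2 (default 5000).
#' @return Tibble with columns `frame_id`, `cluster` (integer label),
#'   `singleton` (logical).
#' @export
cut_threshold <- function(hc, threshold = 5000) {
  if (inherits(hc, "cell_clusters")) hc <- hc$hclust
  if (!inherits(hc, "hclust")) abort("cut_threshold() expects an hclust or cell_clusters object")
  if (!is.numeric(threshold) || threshold <= 0) abort("threshold must be positive")
  n <- length(hc$order)
  labels <- hc$labels %||% as.character(seq_len(n))

  comp <- seq_len(n)                      # component id per leaf
  members <- as.list(seq_len(n))          # leaves under each merge node
  for (k in seq_len(n - 1L)) {
    kids <- hc$merge[k, ]
    mem <- unlist(lapply(kids, function(x) if (x < 0) -x else members[[n + x]]))
    members[[n + k]] <- mem
    if (hc$height[k] < threshold) {
      comp[mem] <- min(comp[mem])
    }
  }

  sizes <- table(comp)
  first_member <- vapply(split(seq_len(n), comp), min, integer(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  cluster <- as.integer(relabel[as.character(comp)])
  tibble(
    frame_id = labels,
    cluster = cluster,
    singleton = as.integer(sizes[as.character(comp)]) == 1L
  )
}

#' Summarize clusters of unit cells
#'
#' Component-wise medians and (unscaled) median absolute deviations of the
#' Niggli-reduced cell parameters per cluster, ordered by descending size.
#' The per-cluster median cell is the natural re-indexing target for the
#' corresponding crystal form.
#'
#' @param data Data frame of cells; reduced internally.
#' @param assignment Tibble from [cut_threshold()] (row order must match).
#' @param reduce Reduce cells before summarizing (default TRUE; set FALSE if
#'   `data` is already reduced).
#' @return Tibble with one row per cluster: `cluster`, `n_members`,
#'   `singleton`, median parameters `a`..`gamma`, and spreads `mad_a`..`mad_gamma`.
#' @export
summarize_clusters <- function(data, assignment, reduce = TRUE) {
  data <- as_cells_tbl(data)
  stopifnot(nrow(data) == nrow(assignment))
  if (reduce) data <- reduce_cells(data)
  data$cluster <- assignment$cluster
  out <- data |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      dplyr::across(dplyr::all_of(CELL_PARS), stats::median),
      dplyr::across(dplyr::all_of(CELL_PARS), ~ stats::mad(.x, constant = 1),
                    .names = "mad_{.col}"),
      .groups = "drop"
    ) |>
    dplyr::mutate(singleton = .data$n_members == 1L, .after = "n_members") |>
    dplyr::arrange(dplyr::desc(.data$n_members), .data$cluster)
  out
}

#' Cluster per-frame unit cells
#'
#' The full unit-cell variation diagnostic: Niggli-reduce all cells, build
#' the pairwise lattice distance matrix, run single-linkage clustering, cut
#' at the threshold, and summarize each cluster. Frames sharing a cluster
#' below the threshold are candidates for joint merging; cluster medians are
#' re-indexing target cells.
#'
#' @param data Data frame of frames or cells (needs columns `a`..`gamma`;
#'   `frame_id` used for labels when present).
#' @param metric Distance metric, `"ncdist"` (symmetry-aware, default) or
#'   `"euclidean"`.
#' @param threshold Cut height in A^2 (default 5000).
#' @param tol Niggli reduction tolerance.
#' @return A `cell_clusters` object: list with `hclust`, `merges` (tibble of
#'   merge steps), `assignment`, `summary`, `cells` (reduced), `metric`,
#'   `threshold`.
#' @examples
#' frames <- generate_frames(two_form_config(n_frames = 40, seed = 1))$frames
#' cl <- cluster_cells(frames)
#' glance(cl)
#' @export
cluster_cells <- function(data, metric = c("ncdist", "euclidean"),
                          threshold = 5000, tol = 1e-5) {
  metric <- match.arg(metric)
  data <- as_cells_tbl(data)
  if (nrow(data) < 2L) abort("need at least two frames to cluster")
  reduced <- reduce_cells(data, tol = tol)
  D <- cell_distance_matrix(reduced, metric = metric, tol = tol)
  hc <- single_linkage(D)
  n <- nrow(data)
  sizes <- integer(n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- hc$merge[k, ]
    sizes[k] <- sum(vapply(kids, function(x) if (x < 0) 1L else sizes[x], integer(1)))
  }
  merges <- tibble(
    step = seq_len(n - 1L),
    node_i = hc$merge[, 1], node_j = hc$merge[, 2],
    height = hc$height, member_count = sizes
  )
  assignment <- cut_threshold(hc, threshold)
  summary <- summarize_clusters(reduced, assignment, reduce = FALSE)
  structure(
    list(hclust = hc, merges = merges, assignment = assignment,
         summary = summary, cells = reduced, metric = metric,
         threshold = threshold),
    class = "cell_clusters"
  )
}

#' @export
print.cell_clusters <- function(x, ...) {
  ns <- x$summary
  cat(sprintf("Unit-cell clustering (%s metric, threshold %g A^2)\n", x$metric, x$threshold))
  cat(sprintf("  %d frames, %d clusters (%d singletons)\n",
              nrow(x$assignment),
              nrow(ns), sum(ns$singleton)))
  print(ns, ...)
  invisible(x)
}

#' @describeIn cluster_cells Per-frame membership tibble (frame id, cluster,
#'   singleton flag, reduced cell parameters).
#' @param x A `cell_clusters` object.
#' @param ... Unused.
#' @export
tidy.cell_clusters <- function(x, ...) {
  dplyr::bind_cols(x$assignment, x$cells[setdiff(names(x$cells), names(x$assignment))])
}

#' @describeIn cluster_cells One-row overview: frame count, cluster count,
#'   singleton count, threshold, metric, largest-cluster size.
#' @export
glance.cell_clusters <- function(x, ...) {
  tibble(
    n_frames = nrow(x$assignment),
    n_clusters = nrow(x$summary),
    n_nonsingleton = sum(!x$summary$singleton),
    n_singletons = sum(x$summary$singleton),
    largest_cluster = max(x$summary$n_members),
    threshold = x$threshold,
    metric = x$metric
  )
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths encode merge heights: a leaf's branch length is its
#' parent's merge height, an internal node's is the height difference to its
#' parent, so leaf-to-root path length equals the root merge height and the
#' whole merge structure is recoverable from the parsed tree.
#'
#' @param hc An `hclust` or `cell_clusters` object.
#' @return Newick string (terminated by ";").
#' @export
dendrogram_to_newick <- function(hc) {
  if (inherits(hc, "cell_clusters")) hc <- hc$hclust
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  labels <- hc$labels %||% as.character(seq_len(n))
  node_str <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.10g", labels[-node], parent_height)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s):%.10g",
              node_str(hc$merge[node, 1], h),
              node_str(hc$merge[node, 2], h),
              parent_height - h)
    }
  }
  root <- n - 1L
  h <- hc$height[root]
  paste0("(", node_str(hc$merge[root, 1], h), ",",
         node_str(hc$merge[root, 2], h), ");")
}

#' Write a plain-text clustering log
#'
#' Mirrors the structure of a full clustering log: global counts, then per
#' cluster the member count, median cell, parameter spreads and member frame
#' ids.
#'
#' @param clusters A `cell_clusters` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clustering_log <- function(clusters, path) {
  stopifnot(inherits(clusters, "cell_clusters"))
  con <- file(path, "w")
  on.exit(close(con))
  g <- glance(clusters)
  writeLines(sprintf("serialdx unit-cell clustering log"), con)
  writeLines(sprintf("metric: %s   threshold: %g A^2", g$metric, g$threshold), con)
  writeLines(sprintf("frames: %d   clusters: %d (%d non-singleton, %d singletons)",
                     g$n_frames, g$n_clusters, g$n_nonsingleton, g$n_singletons), con)
  writeLines("", con)
  members <- split(clusters$assignment$frame_id, clusters$assignment$cluster)
  for (i in seq_len(nrow(clusters$summary))) {
    s <- clusters$summary[i, ]
    writeLines(sprintf(
      "cluster %d: %d member(s)%s", s$cluster, s$n_members,
      if (s$singleton) " [singleton]" else ""), con)
    writeLines(sprintf(
      "  median cell: %.3f %.3f %.3f A  %.3f %.3f %.3f deg",
      s$a, s$b, s$c, s$alpha, s$beta, s$gamma), con)
    writeLines(sprintf(
      "  MAD:         %.4f %.4f %.4f A  %.4f %.4f %.4f deg",
      s$mad_a, s$mad_b, s$mad_c, s$mad_alpha, s$mad_beta, s$mad_gamma), con)
    writeLines(paste0("  members: ", paste(members[[as.character(s$cluster)]], collapse = " ")), con)
  }
  invisible(path)
}

#' @describeIn cluster_cells Dendrogram plot (set `log_height = TRUE` for a
#'   log distance axis); merges below the threshold are colored by cluster.
#' @param object A `cell_clusters` object.
#' @param log_height Use a log10 height axis.
#' @export
autoplot.cell_clusters <- function(object, log_height = FALSE, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  xpos <- numeric(2 * n - 1)                       # leaves then merge nodes
  xpos[hc$order] <- seq_len(n)
  ypos <- numeric(2 * n - 1)
  node_x <- function(node) if (node < 0) xpos[-node] else xpos[n + node]
  node_y <- function(node) if (node < 0) 0 else hc$height[node]
  segs <- vector("list", n - 1L)
  comp_cluster <- function(node) {
    ids <- if (node < 0) -node else leaf_sets[[node]]
    cl <- unique(object$assignment$cluster[ids])
    if (length(cl) == 1L) cl else NA_integer_
  }
  leaf_sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- hc$merge[k, ]
    leaf_sets[[k]] <- unlist(lapply(kids, function(x) if (x < 0) -x else leaf_sets[[x]]))
    x1 <- node_x(kids[1]); x2 <- node_x(kids[2])
    y1 <- node_y(kids[1]); y2 <- node_y(kids[2])
    h <- hc$height[k]
    xpos[n + k] <- (x1 + x2) / 2
    cl <- if (h < object$threshold) comp_cluster(k) else NA_integer_
    segs[[k]] <- tibble(
      x = c(x1, x2, x1), xend = c(x1, x2, x2),
      y = c(y1, y2, h), yend = c(h, h, h),
      cluster = cl
    )
  }
  df <- dplyr::bind_rows(segs)
  if (log_height) {
    pos <- hc$height[hc$height > 0]
    floor_y <- if (length(pos) > 0) min(pos) / 10 else 1e-6
    df$y <- pmax(df$y, floor_y)
    df$yend <- pmax(df$yend, floor_y)
  }
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend,
      color = factor(.data$cluster))) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "lattice distance (Å²)",
                  color = "cluster",
                  title = sprintf("Single-linkage unit-cell clustering (%s)", object$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
  if (log_height) p <- p + ggplot2::scale_y_log10()
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
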