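# Shared fixtures and independent oracles for the test suite.

# Random valid triclinic cell, moderately skewed angles.
random_cell <- function(edge_range = c(5, 50), angle_range = c(70, 110)) {
  repeat {
    p <- c(runif(3, edge_range[1], edge_range[2]),
           runif(3, angle_range[1], angle_range[2]))
    ok <- tryCatch({
      serialdx:::validate_cell(p)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(stats::setNames(p, c("a", "b", "c", "alpha", "beta", "gamma")))
  }
}

# Random integer matrix with determinant +-1 (entries in -max_entry..max_entry).
random_gl3z <- function(max_entry = 2) {
  repeat {
    T <- matrix(sample(-max_entry:max_entry, 9, replace = TRUE), 3, 3)
    if (abs(round(det(T))) == 1) return(T)
  }
}

# Same lattice, different basis: apply T to the metric tensor.
rebase_cell <- function(cell, T) {
  G <- metric_tensor(cell)
  cell_from_g6(serialdx:::g6_from_metric(t(T) %*% G %*% T))
}

.oracle_env <- new.env()

# Brute-force transform stack: ALL integer 3x3 matrices with entries in
# {-1, 0, 1} and det +-1, as stacked G6 linear maps. Independent of (and
# much larger than) the set ncdist() minimizes over.
oracle_transform_stack <- function() {
  if (!is.null(.oracle_env$W)) return(.oracle_env$W)
  combos <- as.matrix(expand.grid(rep(list(-1:1), 9)))
  d <- combos[, 1] * (combos[, 5] * combos[, 9] - combos[, 6] * combos[, 8]) -
       combos[, 4] * (combos[, 2] * combos[, 9] - combos[, 3] * combos[, 8]) +
       combos[, 7] * (combos[, 2] * combos[, 6] - combos[, 3] * combos[, 5])
  keep <- abs(d) == 1
  maps <- apply(combos[keep, , drop = FALSE], 1, function(v) {
    serialdx:::g6_transform_map(matrix(v, 3, 3))
  })
  # each column of `maps` is a vectorized 6x6 map; stack them row-wise
  W <- do.call(rbind, lapply(seq_len(ncol(maps)), function(i) matrix(maps[, i], 6, 6)))
  .oracle_env$W <- W
  W
}

# Brute-force symmetry-aware distance: reduce both cells, minimize the G6
# Euclidean distance over the full small-coefficient transform set.
oracle_ncdist <- function(c1, c2) {
  g1 <- g6_from_cell(niggli_reduce(c1)$reduced)
  g2 <- g6_from_cell(niggli_reduce(c2)$reduced)
  W <- oracle_transform_stack()
  d_dir <- function(gf, gt) {
    V <- matrix(W %*% gf, ncol = 6, byrow = TRUE)
    sqrt(min(rowSums(sweep(V, 2, gt)^2)))
  }
  min(d_dir(g2, g1), d_dir(g1, g2))
}

# Naive O(n^3) single linkage: rescan the minimum inter-cluster distance at
# every step. Returns the merge heights in order.
naive_single_linkage_heights <- function(D) {
  M <- as.matrix(D)
  n <- nrow(M)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- min(M[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Cheap frames tibble without orientations/reflections, for clustering tests.
cells_frames <- function(cells_mat, ids = NULL) {
  ids <- ids %||% sprintf("f%03d", seq_len(nrow(cells_mat)))
  frames_tbl(ids, as_cells_tbl(cells_mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
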