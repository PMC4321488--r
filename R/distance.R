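# Inter-lattice distances in G6 space.
#
# Both metrics Niggli-reduce their operands first and measure Euclidean
# distance between six-component G6 vectors (units A^2). The symmetry-aware
# metric additionally minimizes over a fixed set of lattice-preserving basis
# transforms applied to one operand, which absorbs the residual ambiguity of
# the reduced setting (axis permutation/sign conventions and Niggli-cone
# boundary crossings) that a plain Euclidean comparison is blind to.

# g6(t(T) %*% G %*% T) is linear in g6(G); return the 6x6 matrix of that map.
g6_transform_map <- function(T) {
  L <- matrix(0, 6, 6)
  for (i in 1:6) {
    e <- numeric(6); e[i] <- 1
    L[, i] <- g6_from_metric(t(T) %*% metric_from_g6_raw(e) %*% T)
  }
  L
}

signed_permutation_matrices <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- vector("list", 48L)
  k <- 0L
  for (p in perms) {
    for (s in seq_len(nrow(signs))) {
      T <- matrix(0, 3, 3)
      for (j in 1:3) T[p[j], j] <- signs[s, j]
      k <- k + 1L
      out[[k]] <- T
    }
  }
  out
}

unit_shear_matrices <- function() {
  out <- list()
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    for (s in c(-1, 1)) {
      T <- diag(3); T[i, j] <- s
      out[[length(out) + 1L]] <- T
    }
  }
  out
}

.serialdx_cache <- new.env(parent = emptyenv())

# Stacked (n_transforms * 6) x 6 matrix of G6 maps for the ncdist transform
# set: every signed permutation composed with identity or a single unit
# shear, deduplicated by their action on G6.
ncdist_transform_stack <- function() {
  if (!is.null(.serialdx_cache$W)) return(.serialdx_cache$W)
  perms <- signed_permutation_matrices()
  shears <- c(list(diag(3)), unit_shear_matrices())
  maps <- list()
  seen <- character()
  for (P in perms) {
    for (S in shears) {
      L <- g6_transform_map(P %*% S)
      key <- paste(round(L, 9), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        maps[[length(maps) + 1L]] <- L
      }
    }
  }
  W <- do.call(rbind, maps)
  .serialdx_cache$W <- W
  W
}

# Minimum distance from target g6 vector `g_to` to the transform orbit of
# `g_from` (squared-distance minimization, returns the distance).
min_orbit_distance <- function(g_from, g_to, W) {
  V <- matrix(W %*% g_from, ncol = 6, byrow = TRUE)
  sqrt(min(rowSums(sweep(V, 2, g_to)^2)))
}

#' Euclidean G6 distance between two unit cells
#'
#' Both cells are Niggli-reduced, embedded in G6, and compared with the
#' Euclidean norm. Units are squared angstroms, consistent with the default
#' 5000 A^2 clustering threshold.
#'
#' @param c1,c2 Unit cells.
#' @param tol Reduction tolerance.
#' @return Distance in A^2.
#' @export
g6_distance_euclidean <- function(c1, c2, tol = 1e-5) {
  g1 <- g6_from_cell(niggli_reduce(c1, tol = tol)$reduced)
  g2 <- g6_from_cell(niggli_reduce(c2, tol = tol)$reduced)
  sqrt(sum((g1 - g2)^2))
}

#' Symmetry-aware lattice distance between two unit cells
#'
#' Niggli-reduces both cells and returns the minimum G6 Euclidean distance
#' over a fixed set of lattice-preserving transforms (signed axis
#' permutations composed with unit shears) applied to either operand. This
#' is a finite-transform approximation to the Andrews-Bernstein NCDist
#' metric: it is symmetric, vanishes for any two parameterizations of the
#' same lattice, and never exceeds [g6_distance_euclidean()].
#'
#' @inheritParams g6_distance_euclidean
#' @return Distance in A^2.
#' @examples
#' ncdist(unit_cell(10, 10, 10), unit_cell(10, 10, 10.5))
#' @export
ncdist <- function(c1, c2, tol = 1e-5) {
  g1 <- g6_from_cell(niggli_reduce(c1, tol = tol)$reduced)
  g2 <- g6_from_cell(niggli_reduce(c2, tol = tol)$reduced)
  W <- ncdist_transform_stack()
  min(min_orbit_distance(g2, g1, W), min_orbit_distance(g1, g2, W))
}

#' Distance between two unit cells
#'
#' Dispatches to [ncdist()] (default) or [g6_distance_euclidean()].
#'
#' @inheritParams g6_distance_euclidean
#' @param metric `"ncdist"` or `"euclidean"`.
#' @return Distance in A^2.
#' @export
cell_distance <- function(c1, c2, metric = c("ncdist", "euclidean"), tol = 1e-5) {
  metric <- match.arg(metric)
  switch(metric,
    ncdist = ncdist(c1, c2, tol = tol),
    euclidean = g6_distance_euclidean(c1, c2, tol = tol)
  )
}

#' Pairwise lattice distance matrix
#'
#' Niggli-reduces every cell once, then computes all pairwise distances with
#' the chosen metric. Reduction failures are reported with the offending
#' frame id.
#'
#' @param data Data frame of cells (see [as_cells_tbl()]); a `frame_id`
#'   column, if present, becomes the distance labels.
#' @param metric `"ncdist"` or `"euclidean"`.
#' @param tol Reduction tolerance.
#' @return A `stats::dist` object (condensed form) in A^2.
#' @export
cell_distance_matrix <- function(data, metric = c("ncdist", "euclidean"), tol = 1e-5) {
  metric <- match.arg(metric)
  data <- as_cells_tbl(data)
  n <- nrow(data)
  if (n < 2L) abort("need at least two cells to compute a distance matrix")
  reduced <- reduce_cells(data, tol = tol)
  G6 <- t(apply(reduced[CELL_PARS], 1, function(p) g6_from_cell(as_cell(p))))
  labels <- if ("frame_id" %in% names(data)) data$frame_id else as.character(seq_len(n))

  if (metric == "euclidean") {
    D <- dist(G6)
  } else {
    W <- ncdist_transform_stack()
    m <- nrow(W) / 6L
    sq <- matrix(NA_real_, n, n)
    for (j in seq_len(n)) {
      # orbit of cell j under all transforms: m x 6
      V <- matrix(W %*% G6[j, ], ncol = 6, byrow = TRUE)
      cross <- tcrossprod(V, G6)                       # m x n inner products
      d2 <- outer(rowSums(V^2), rowSums(G6^2), "+") - 2 * cross
      sq[, j] <- apply(d2, 2, min)
    }
    sq <- pmax(pmin(sq, t(sq)), 0)                     # symmetrize directions
    # the inner-product expansion above cancels catastrophically near zero
    # (entries ~ |g6|^2 ~ 1e10); recompute tiny entries with exact differences
    small <- which(sq < 1, arr.ind = TRUE)
    small <- small[small[, 1] < small[, 2], , drop = FALSE]
    for (r in seq_len(nrow(small))) {
      i <- small[r, 1]; j <- small[r, 2]
      d <- min(min_orbit_distance(G6[j, ], G6[i, ], W),
               min_orbit_distance(G6[i, ], G6[j, ], W))
      sq[i, j] <- sq[j, i] <- d^2
    }
    D <- as.dist(sqrt(sq))
  }
  attr(D, "Labels") <- labels
  D
}
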