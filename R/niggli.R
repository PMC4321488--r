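# Niggli reduction (Krivy-Gruber steps with epsilon-stabilized comparisons).
#
# The reduction works on the real-space metric tensor G and accumulates the
# integer change-of-basis matrix M (column convention: new basis = old basis
# %*% M, so G' = t(M) %*% G %*% M). Conditions are tested with a tolerance
# relative to the mean squared edge, which keeps the decision sequence stable
# for cells that sit numerically on a Niggli-cone boundary.

# Basis-operation matrices. Column j holds the expression of the j-th new
# basis vector in the old basis.
.niggli_swap_ab <- matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3)
.niggli_swap_bc <- matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, 3)

.eps_sign <- function(x, eps) {
  if (x > eps) 1L else if (x < -eps) -1L else 0L
}

# One Krivy-Gruber decision pass. Returns the 3x3 transform to apply, or
# NULL if the cell already satisfies every Niggli condition.
niggli_step <- function(G, eps) {
  A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
  xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]

  # ordering of the squared edges (ties broken on the angle terms)
  if (A > B + eps || (abs(A - B) <= eps && abs(xi) > abs(eta) + eps)) {
    return(.niggli_swap_ab)
  }
  if (B > C + eps || (abs(B - C) <= eps && abs(eta) > abs(zeta) + eps)) {
    return(.niggli_swap_bc)
  }

  # canonical sign configuration: all angle terms positive (type I) or all
  # non-positive (type II)
  l <- .eps_sign(xi, eps); m <- .eps_sign(eta, eps); n <- .eps_sign(zeta, eps)
  if (l * m * n == 1L) {
    ijk <- c(m * n, l * n, l * m)
  } else {
    ijk <- c(1L, 1L, 1L); r <- 0L
    if (l == 1L) ijk[1] <- -1L else if (l == 0L) r <- 1L
    if (m == 1L) ijk[2] <- -1L else if (m == 0L) r <- 2L
    if (n == 1L) ijk[3] <- -1L else if (n == 0L) r <- 3L
    if (prod(ijk) == -1L) {
      if (r == 0L) abort("Niggli sign normalization failed (degenerate cell)")
      ijk[r] <- -1L
    }
  }
  if (any(ijk != 1L)) return(diag(ijk))

  # main-condition shears
  if (abs(xi) > B + eps ||
      (abs(xi - B) <= eps && 2 * eta < zeta - eps) ||
      (abs(xi + B) <= eps && zeta < -eps)) {
    s <- if (xi > 0) 1 else -1
    T <- diag(3); T[2, 3] <- -s
    return(T)
  }
  if (abs(eta) > A + eps ||
      (abs(eta - A) <= eps && 2 * xi < zeta - eps) ||
      (abs(eta + A) <= eps && zeta < -eps)) {
    s <- if (eta > 0) 1 else -1
    T <- diag(3); T[1, 3] <- -s
    return(T)
  }
  if (abs(zeta) > A + eps ||
      (abs(zeta - A) <= eps && 2 * xi < eta - eps) ||
      (abs(zeta + A) <= eps && eta < -eps)) {
    s <- if (zeta > 0) 1 else -1
    T <- diag(3); T[1, 2] <- -s
    return(T)
  }
  if (xi + eta + zeta + A + B < -eps ||
      (abs(xi + eta + zeta + A + B) <= eps && 2 * (A + eta) + zeta > eps)) {
    T <- diag(3); T[1, 3] <- 1; T[2, 3] <- 1
    return(T)
  }
  NULL
}

#' Niggli-reduce a unit cell
#'
#' Transforms a cell to its Niggli-reduced setting: the canonical basis with
#' `a <= b <= c` and the standard angle sign/tie conventions. The reduced
#' cell describes the same lattice as the input; the returned
#' `change_of_basis` is an integer matrix with determinant +-1 mapping the
#' original basis to the reduced one (column convention, so
#' `t(M) %*% G_original %*% M = G_reduced`).
#'
#' @param cell A unit cell.
#' @param tol Relative tolerance for the reduction condition checks.
#' @param max_iter Iteration cap; exceeding it signals a degenerate cell.
#' @return List with elements `reduced` (unit cell), `change_of_basis`
#'   (integer 3x3 matrix), and `iterations`.
#' @examples
#' niggli_reduce(unit_cell(5, 3, 4))$reduced
#' @export
niggli_reduce <- function(cell, tol = 1e-5, max_iter = 100) {
  cell <- as_cell(cell)
  validate_cell(cell)
  G <- metric_tensor_unchecked(cell)
  M <- diag(3)
  eps <- tol * mean(diag(G))
  it <- 0L
  repeat {
    T <- niggli_step(G, eps)
    if (is.null(T)) break
    it <- it + 1L
    if (it > max_iter) {
      abort(sprintf("Niggli reduction failed to terminate within %d steps (degenerate cell)", max_iter))
    }
    G <- t(T) %*% G %*% T
    M <- M %*% T
  }
  reduced <- cell_from_g6(g6_from_metric(G))
  storage.mode(M) <- "integer"
  list(reduced = reduced, change_of_basis = M, iterations = it)
}

#' Is a cell already Niggli-reduced?
#'
#' @inheritParams niggli_reduce
#' @return Logical scalar.
#' @export
is_niggli_reduced <- function(cell, tol = 1e-5) {
  cell <- as_cell(cell)
  validate_cell(cell)
  G <- metric_tensor_unchecked(cell)
  is.null(niggli_step(G, tol * mean(diag(G))))
}

#' Niggli-reduce every cell in a table
#'
#' Data-frame-first wrapper: replaces the `a`..`gamma` columns of `data` with
#' the Niggli-reduced parameters, keeping all other columns. On failure the
#' error names the offending row (via a `frame_id` column when present).
#'
#' @param data Data frame with unit-cell columns (see [as_cells_tbl()]).
#' @param tol Relative tolerance passed to [niggli_reduce()].
#' @return Tibble of the same shape with reduced cell parameters.
#' @export
reduce_cells <- function(data, tol = 1e-5) {
  data <- as_cells_tbl(data)
  ids <- if ("frame_id" %in% names(data)) data$frame_id else as.character(seq_len(nrow(data)))
  for (i in seq_len(nrow(data))) {
    red <- tryCatch(
      niggli_reduce(unlist(data[i, CELL_PARS]), tol = tol)$reduced,
      error = function(e) {
        abort(sprintf("Niggli reduction failed for frame '%s': %s", ids[i], conditionMessage(e)))
      }
    )
    data[i, CELL_PARS] <- as.list(red)
  }
  data
}
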