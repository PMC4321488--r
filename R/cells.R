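# Unit-cell algebra: metric tensors, G6 embedding, conversions.
#
# A unit cell is six numbers (a, b, c, alpha, beta, gamma): edge lengths in
# angstroms and inter-axial angles in degrees. Internally all trigonometry is
# done in radians; degrees appear only at the API surface.

CELL_PARS <- c("a", "b", "c", "alpha", "beta", "gamma")

#' Construct a unit cell
#'
#' A unit cell is a named numeric vector with elements `a`, `b`, `c`
#' (angstroms) and `alpha`, `beta`, `gamma` (degrees). The constructor
#' validates positivity of the edges, the angle range (0, 180), and that the
#' metric tensor has strictly positive determinant (i.e. the cell encloses a
#' real volume).
#'
#' @param a,b,c Edge lengths in angstroms.
#' @param alpha,beta,gamma Angles in degrees (default 90).
#' @return Named numeric vector of length 6.
#' @examples
#' unit_cell(69, 169, 288)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  validate_cell(cell)
  cell
}

# Coerce a length-6 numeric vector or one-row data frame to a cell vector.
as_cell <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[CELL_PARS])
  }
  x <- as.numeric(x)
  if (length(x) != 6L) {
    abort("a unit cell needs exactly six parameters (a, b, c, alpha, beta, gamma)")
  }
  setNames(x, CELL_PARS)
}

validate_cell <- function(cell) {
  cell <- as_cell(cell)
  if (any(!is.finite(cell))) abort("unit-cell parameters must be finite")
  if (any(cell[1:3] <= 0)) abort("unit-cell edges must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    abort("unit-cell angles must lie strictly between 0 and 180 degrees")
  }
  G <- metric_tensor_unchecked(cell)
  if (det(G) <= 0) abort("invalid unit cell: metric tensor is not positive definite")
  invisible(cell)
}

metric_tensor_unchecked <- function(cell) {
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  ca <- cospi(cell[[4]] / 180)
  cb <- cospi(cell[[5]] / 180)
  cg <- cospi(cell[[6]] / 180)
  matrix(c(
    a * a,      a * b * cg, a * cc * cb,
    a * b * cg, b * b,      b * cc * ca,
    a * cc * cb, b * cc * ca, cc * cc
  ), 3, 3, byrow = TRUE)
}

#' Real-space metric tensor of a unit cell
#'
#' Returns the 3x3 Gram matrix of the real-space basis vectors, in squared
#' angstroms: `G[1,1] = a^2`, `G[1,2] = ab cos(gamma)`, `G[2,3] = bc
#' cos(alpha)`, and so on. Its determinant equals the squared cell volume.
#'
#' @param cell A unit cell (see [unit_cell()]).
#' @return 3x3 symmetric numeric matrix.
#' @export
metric_tensor <- function(cell) {
  cell <- as_cell(cell)
  validate_cell(cell)
  metric_tensor_unchecked(cell)
}

#' Unit-cell volume
#'
#' @param cell A unit cell.
#' @return Volume in cubic angstroms (square root of the metric determinant).
#' @export
cell_volume <- function(cell) {
  sqrt(det(metric_tensor(cell)))
}

g6_from_metric <- function(G) {
  c(G[1, 1], G[2, 2], G[3, 3], 2 * G[2, 3], 2 * G[1, 3], 2 * G[1, 2])
}

# No validity requirements: used for linear-map bookkeeping on arbitrary
# symmetric matrices as well as genuine cells.
metric_from_g6_raw <- function(g) {
  matrix(c(
    g[1],     g[6] / 2, g[5] / 2,
    g[6] / 2, g[2],     g[4] / 2,
    g[5] / 2, g[4] / 2, g[3]
  ), 3, 3, byrow = TRUE)
}

#' G6 embedding of a unit cell
#'
#' The G6 vector is (a^2, b^2, c^2, 2bc cos(alpha), 2ac cos(beta),
#' 2ab cos(gamma)), all in squared angstroms. Lattice distances in this
#' package (and the default 5000 A^2 clustering threshold) are measured in
#' this space.
#'
#' @param cell A unit cell.
#' @return Numeric vector of length 6 (A^2).
#' @seealso [cell_from_g6()]
#' @export
g6_from_cell <- function(cell) {
  g6_from_metric(metric_tensor(cell))
}

#' Unit cell from a G6 vector
#'
#' Inverse of [g6_from_cell()]. Errors if the components do not describe a
#' positive-volume lattice (non-positive squared edges, or implied
#' |cos(angle)| >= 1).
#'
#' @param g Numeric vector of length 6.
#' @return A unit cell.
#' @export
cell_from_g6 <- function(g) {
  g <- as.numeric(g)
  if (length(g) != 6L) abort("a G6 vector has exactly six components")
  if (any(!is.finite(g))) abort("invalid G6 vector: non-finite components")
  if (any(g[1:3] <= 0)) abort("invalid G6 vector: g1, g2, g3 must be positive")
  a <- sqrt(g[1]); b <- sqrt(g[2]); cc <- sqrt(g[3])
  cosines <- c(g[4] / (2 * b * cc), g[5] / (2 * a * cc), g[6] / (2 * a * b))
  if (any(abs(cosines) >= 1)) {
    abort("invalid G6 vector: implied |cos(angle)| >= 1")
  }
  cell <- c(a, b, cc, acos(cosines) * 180 / pi)
  cell <- setNames(cell, CELL_PARS)
  validate_cell(cell)
  cell
}

#' Tidy a set of cells into a tibble
#'
#' Accepts a data frame containing columns `a`..`gamma` (extra columns are
#' kept), a numeric matrix with six columns, or a list of cell vectors.
#'
#' @param x Cells in any of the forms above.
#' @return Tibble with columns `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @export
as_cells_tbl <- function(x) {
  if (is.data.frame(x)) {
    missing <- setdiff(CELL_PARS, names(x))
    if (length(missing) > 0) {
      abort(paste0("missing unit-cell columns: ", paste(missing, collapse = ", ")))
    }
    return(as_tibble(x))
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 6L)
    colnames(x) <- CELL_PARS
    return(as_tibble(x))
  }
  if (is.list(x)) {
    return(as_tibble(do.call(rbind, lapply(x, as_cell))))
  }
  as_tibble(as.list(as_cell(x)))
}
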