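# Laboratory-frame orientation diagnostics.
#
# Frame convention (fixed, right-handed): beam = +z, up = +y, right when
# looking along the beam = +x. Latitude/longitude of a unit vector v:
# latitude = asin(v_y), longitude = atan2(v_x, v_z), both in degrees, so
# (0, 0) is along the beam, North/South are up/down, East/West right/left.
# Crystal axes are directions without sign, so every axis is emitted as an
# antipodal pair; density maps and the Bingham orientation tensor are
# computed on the sign-invariant representation.

#' Real-space axis directions from a reciprocal orientation matrix
#'
#' The orientation matrix holds the reciprocal basis vectors a*, b*, c* in
#' laboratory coordinates (1/angstrom) as its rows. Real axes follow from
#' duality: a = (b* x c*)/V*, b = (c* x a*)/V*, c = (a* x b*)/V* with
#' V* = a* . (b* x c*), then each is normalized to unit length.
#'
#' @param m 3x3 numeric matrix, rows a*, b*, c*.
#' @return 3x3 matrix with rows the unit vectors of the real a, b, c axes.
#' @export
real_axes_from_reciprocal <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  bc <- cross(m[2, ], m[3, ])
  vstar <- sum(m[1, ] * bc)
  if (!is.finite(vstar) || abs(vstar) <= 1e-12 * max(max(abs(m))^3, 1)) {
    abort("singular orientation matrix: reciprocal basis does not span 3D")
  }
  axes <- rbind(bc, cross(m[3, ], m[1, ]), cross(m[1, ], m[2, ])) / vstar
  axes <- axes / sqrt(rowSums(axes^2))
  rownames(axes) <- c("a", "b", "c")
  axes
}

#' Latitude/longitude of a laboratory-frame unit vector
#'
#' @param v Unit vector (length 3, |v| = 1 within 1e-9).
#' @return Named numeric: `lat` in \[-90, 90\], `lon` in (-180, 180\], degrees.
#' @examples
#' latlong_of_vector(c(0, 0, 1))  # (0, 0): along the beam
#' @export
latlong_of_vector <- function(v) {
  v <- as.numeric(v)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort("cannot project the zero vector")
  if (abs(nrm - 1) > 1e-9) abort("expected a unit vector (|v| = 1 within 1e-9)")
  lat <- asin(max(-1, min(1, v[2]))) * 180 / pi
  lon <- atan2(v[1], v[3]) * 180 / pi
  if (lon <= -180) lon <- lon + 360
  c(lat = lat, lon = lon)
}

latlong_to_vector <- function(lat, lon) {
  latr <- lat * pi / 180; lonr <- lon * pi / 180
  cbind(x = cos(latr) * sin(lonr), y = sin(latr), z = cos(latr) * cos(lonr))
}

#' Real-axis directions for every frame
#'
#' One row per frame and axis, sign-free representation kept explicit: each
#' axis contributes both antipodes (`hemisphere` +1/-1). Frames without an
#' orientation matrix are skipped; the skipped count is reported via a
#' message and an attribute.
#'
#' @param frames A frames tibble (see [frames_tbl()]) with an `orientation`
#'   list-column.
#' @return Tibble with columns `frame_id`, `axis` (a/b/c), `hemisphere`,
#'   `x`, `y`, `z`, `lat`, `lon`; attribute `n_skipped`.
#' @export
project_axes <- function(frames) {
  stopifnot(is.data.frame(frames), "orientation" %in% names(frames))
  has_ori <- !vapply(frames$orientation, is.null, logical(1))
  n_skipped <- sum(!has_ori)
  if (n_skipped > 0) {
    inform(sprintf("project_axes: skipped %d frame(s) without an orientation matrix", n_skipped))
  }
  rows <- purrr::map(which(has_ori), function(i) {
    axes <- real_axes_from_reciprocal(frames$orientation[[i]])
    purrr::map(c(1, -1), function(s) {
      v <- s * axes
      ll <- t(apply(v, 1, latlong_of_vector))
      tibble(frame_id = frames$frame_id[i], axis = c("a", "b", "c"),
             hemisphere = s, x = unname(v[, 1]), y = unname(v[, 2]),
             z = unname(v[, 3]), lat = unname(ll[, 1]), lon = unname(ll[, 2]))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(frame_id = character(), axis = character(),
                                    hemisphere = numeric(), x = numeric(), y = numeric(),
                                    z = numeric(), lat = numeric(), lon = numeric())
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Averaged axis density on the sphere
#'
#' von Mises-Fisher kernel density estimate of the projected axis directions
#' on a regular latitude/longitude grid:
#' f(u) = (1/N) sum_i c(kappa) exp(kappa u . v_i), with
#' c(kappa) = kappa / (4 pi sinh kappa). The default kappa = 50 gives a
#' kernel FWHM of roughly 20 degrees. The density integrates to 1 over the
#' sphere (checkable with equal-area `cos(lat)` quadrature weights).
#'
#' @param projections Tibble from [project_axes()] (or any table with `lat`,
#'   `lon` columns); all rows are pooled, so filter by `axis` first for
#'   per-axis maps.
#' @param kappa Kernel concentration (> 0, default 50).
#' @param spacing Grid spacing in degrees (default 2); nodes sit at cell
#'   centers, e.g. -89, -87, ... for latitude.
#' @return Tibble `lat`, `lon`, `density` (per steradian).
#' @export
spherical_density <- function(projections, kappa = 50, spacing = 2) {
  stopifnot(kappa > 0, spacing > 0)
  if (nrow(projections) == 0) abort("no projections to estimate a density from")
  V <- latlong_to_vector(projections$lat, projections$lon)
  lat <- seq(-90 + spacing / 2, 90 - spacing / 2, by = spacing)
  lon <- seq(-180 + spacing / 2, 180 - spacing / 2, by = spacing)
  grid <- tidyr::expand_grid(lat = lat, lon = lon)
  U <- latlong_to_vector(grid$lat, grid$lon)
  # c(kappa) exp(kappa u.v) written stably as kappa/(2 pi (1 - exp(-2 kappa)))
  # * exp(kappa (u.v - 1))
  const <- kappa / (2 * pi * (1 - exp(-2 * kappa)))
  dens <- numeric(nrow(U))
  chunk <- 4000L
  for (start in seq(1L, nrow(U), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(U))
    M <- U[idx, , drop = FALSE] %*% t(V)
    dens[idx] <- const * rowMeans(exp(kappa * (M - 1)))
  }
  grid$density <- dens
  grid
}

#' Bingham test of uniformity for axial data
#'
#' Tests whether a sample of axes (sign-free directions) is uniformly
#' distributed on the sphere. The orientation tensor T = (1/N) sum v_i v_i'
#' is sign-invariant; under uniformity its eigenvalues are all 1/3 and the
#' statistic S = (15 N / 2) (trace(T^2) - 1/3) is asymptotically chi-squared
#' with 5 degrees of freedom.
#'
#' @param axes Numeric matrix with one unit axis per row (n x 3), or a tibble
#'   with `x`, `y`, `z` columns. Supply one representative per axis
#'   observation (antipodes are redundant; if both are present each pair
#'   counts twice).
#' @return One-row tibble: `n`, `tau1` >= `tau2` >= `tau3` (eigenvalues,
#'   summing to 1), `statistic`, `p_value`.
#' @export
bingham_test <- function(axes) {
  if (is.data.frame(axes)) axes <- as.matrix(axes[, c("x", "y", "z")])
  stopifnot(is.matrix(axes), ncol(axes) == 3L)
  axes <- axes / sqrt(rowSums(axes^2))
  n <- nrow(axes)
  if (n < 10L) abort("Bingham test needs at least 10 axes")
  T <- crossprod(axes) / n
  ev <- sort(eigen(T, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  S <- (15 * n / 2) * (sum(T * T) - 1 / 3)
  tibble(n = n, tau1 = ev[1], tau2 = ev[2], tau3 = ev[3],
         statistic = S, p_value = pchisq(S, df = 5, lower.tail = FALSE))
}

#' Per-axis Bingham uniformity tests for a frame set
#'
#' Runs [bingham_test()] on the a, b and c real-axis directions (one
#' representative per frame).
#'
#' @inheritParams project_axes
#' @return Tibble with one row per axis label.
#' @export
bingham_tests <- function(frames) {
  proj <- project_axes(frames)
  proj |>
    dplyr::filter(.data$hemisphere == 1) |>
    dplyr::group_by(.data$axis) |>
    dplyr::group_modify(~ bingham_test(.x)) |>
    dplyr::ungroup()
}

#' Uniform random rotation matrices
#'
#' Drawn from the Haar measure on SO(3) via normalized 4-component Gaussian
#' quaternions.
#'
#' @param n Number of rotations.
#' @return List of 3x3 rotation matrices.
#' @export
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  purrr::map(seq_len(n), function(i) quaternion_to_rotation(q[i, ]))
}

quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Sample from a von Mises-Fisher distribution on the sphere
#'
#' @param n Number of draws.
#' @param mu Mean direction (normalized internally).
#' @param kappa Concentration (> 0).
#' @return n x 3 matrix of unit vectors.
#' @export
sample_vmf <- function(n, mu = c(0, 0, 1), kappa = 5) {
  stopifnot(kappa > 0)
  mu <- mu / sqrt(sum(mu^2))
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  theta <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(theta), s * sin(theta), w)
  R <- rotation_from_z(mu)
  local %*% t(R)
}

# Rotation taking +z to the given unit vector (Rodrigues).
rotation_from_z <- function(to) {
  from <- c(0, 0, 1)
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  cth <- sum(from * to)
  if (cth < -1 + 1e-12) return(diag(c(1, -1, -1)))       # antiparallel
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

#' Orientation map figure
#'
#' Three-panel latitude/longitude map (a top, b middle, c bottom): axis
#' directions (both antipodes) overlaid on the von Mises-Fisher density
#' color map.
#'
#' @param projections Tibble from [project_axes()].
#' @param kappa,spacing Passed to [spherical_density()].
#' @return A ggplot object.
#' @export
plot_orientation_map <- function(projections, kappa = 50, spacing = 2) {
  dens <- projections |>
    dplyr::group_by(.data$axis) |>
    dplyr::group_modify(~ spherical_density(.x, kappa = kappa, spacing = spacing)) |>
    dplyr::ungroup()
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = dens,
                         ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$density)) +
    ggplot2::geom_point(data = projections,
                        ggplot2::aes(x = .data$lon, y = .data$lat),
                        color = "yellow", size = 0.4, alpha = 0.7) +
    ggplot2::facet_wrap(~ axis, ncol = 1) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(x = "longitude (°; 0 = along beam, E/W = right/left)",
                  y = "latitude (°; N/S = up/down)",
                  fill = "density\n(1/sr)") +
    ggplot2::theme_minimal()
}
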