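# Synthetic serial-crystallography datasets with ground truth.
#
# The generator emulates the statistical structure this toolkit diagnoses:
# a mixture of unit-cell populations (multiple crystal forms), orientation
# distributions with optional preferred-axis bias, Wilson-model partial
# intensities with per-frame scale and temperature factor, and a
# mis-indexed contaminant fraction. It does not attempt physically
# realistic diffraction (spot shapes, detector noise, absorption).

#' Configuration for the synthetic frame generator
#'
#' @param populations Tibble with columns `a`..`gamma` (median cells) and
#'   `weight` (mixture weights, normalized internally).
#' @param n_frames Number of frames.
#' @param jitter_edge,jitter_angle Gaussian jitter SDs applied to the
#'   reduced-cell parameters (A / degrees).
#' @param orientation_model `"uniform"` (Haar-random rotations) or `"vmf"`
#'   (the crystal c axis concentrated around `orientation_mean` with a von
#'   Mises-Fisher distribution, random spin about it).
#' @param orientation_mean Mean direction for the vmf model (lab frame).
#' @param orientation_kappa Concentration for the vmf model.
#' @param b_mean,b_sd Per-frame pseudo-Wilson temperature factor B ~
#'   Normal(b_mean, b_sd^2), A^2.
#' @param log_g_mean,log_g_sd Per-frame log scale ln G ~ Normal.
#' @param n_reflections Reflections per frame.
#' @param s2_range Range of squared scattering vector (1/A^2) covered by the
#'   reflections (near-uniform in s^2).
#' @param noise_sd SD of the multiplicative lognormal intensity noise.
#' @param partiality_range Range of the uniform per-reflection partiality.
#' @param misindex_fraction Fraction of frames carrying a wrong-lattice
#'   indexing solution: the *reported* cell is drawn from a different
#'   population and the recorded spots carry scrambled Miller indices, while
#'   the intensities follow the true cell.
#' @param seed Integer seed; fixes the full output.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(populations,
                             n_frames = 318,
                             jitter_edge = 0.5, jitter_angle = 0.1,
                             orientation_model = c("uniform", "vmf"),
                             orientation_mean = c(0, 1, 0),
                             orientation_kappa = 5,
                             b_mean = 15, b_sd = 2,
                             log_g_mean = log(100), log_g_sd = 0.3,
                             n_reflections = 200,
                             s2_range = c(0.001, 0.08),
                             noise_sd = 0.3,
                             partiality_range = c(0.3, 1),
                             misindex_fraction = 0,
                             seed = 1L) {
  populations <- as_tibble(populations)
  stopifnot(all(c(CELL_PARS, "weight") %in% names(populations)),
            nrow(populations) >= 1)
  for (i in seq_len(nrow(populations))) validate_cell(unlist(populations[i, CELL_PARS]))
  if (any(populations$weight <= 0)) abort("population weights must be positive")
  populations$weight <- populations$weight / sum(populations$weight)
  orientation_model <- match.arg(orientation_model)
  stopifnot(
    n_frames >= 0, jitter_edge >= 0, jitter_angle >= 0,
    orientation_kappa > 0, b_sd >= 0, log_g_sd >= 0,
    n_reflections >= 1, length(s2_range) == 2, s2_range[1] > 0,
    s2_range[2] >= s2_range[1], noise_sd >= 0,
    length(partiality_range) == 2, partiality_range[1] > 0,
    partiality_range[2] >= partiality_range[1], partiality_range[2] <= 1,
    misindex_fraction >= 0, misindex_fraction < 1
  )
  structure(list(
    populations = populations, n_frames = as.integer(n_frames),
    jitter_edge = jitter_edge, jitter_angle = jitter_angle,
    orientation_model = orientation_model,
    orientation_mean = orientation_mean / sqrt(sum(orientation_mean^2)),
    orientation_kappa = orientation_kappa,
    b_mean = b_mean, b_sd = b_sd,
    log_g_mean = log_g_mean, log_g_sd = log_g_sd,
    n_reflections = as.integer(n_reflections), s2_range = s2_range,
    noise_sd = noise_sd, partiality_range = partiality_range,
    misindex_fraction = misindex_fraction, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Two-crystal-form demo configuration
#'
#' The flagship configuration emulating a goniometer-based XFEL dataset with
#' two orthorhombic crystal forms: population medians (69, 169, 288) and
#' (69, 146, 170) A with all angles 90 degrees, mixture weights 249/318 and
#' 69/318, 318 frames, 0.5 A / 0.1 degree cell jitter, a preferred-axis
#' (vmf, kappa = 5) orientation bias, and 10% mis-indexed contaminants.
#' Inspired by published serial datasets of this kind; not a reproduction of
#' any deposited data.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @examples
#' cfg <- two_form_config(n_frames = 50, seed = 7)
#' @export
two_form_config <- function(...) {
  pops <- tibble(
    a = c(69, 69), b = c(169, 146), c = c(288, 170),
    alpha = 90, beta = 90, gamma = 90,
    weight = c(249 / 318, 69 / 318)
  )
  defaults <- list(populations = pops, n_frames = 318,
                   orientation_model = "vmf", misindex_fraction = 0.1)
  do.call(synthetic_config, modifyList(defaults, list(...)))
}

# Real-space basis vectors (columns a, b, c) in a crystal-fixed Cartesian
# frame: a along x, b in the xy plane.
real_basis_from_cell <- function(cell) {
  cell <- as_cell(cell)
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  ca <- cospi(cell[[4]] / 180); cb <- cospi(cell[[5]] / 180)
  cg <- cospi(cell[[6]] / 180); sg <- sinpi(cell[[6]] / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  cbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(cc * cb, cc * (ca - cb * cg) / sg, cc * v / sg)
  )
}

#' Generate a synthetic dataset
#'
#' Draws per-frame cells (population median + Gaussian jitter), orientations
#' (uniform or vmf-biased), and Wilson-model reflections:
#' I = G exp(-2 B s^2) p eps with partiality p uniform on its range and eps
#' lognormal. Reflection hkl are integer lattice points chosen so that s^2
#' (under the *true* cell) is near-uniform on `s2_range`. Mis-indexed frames
#' report a cell drawn from a different population and carry scrambled
#' per-reflection Miller indices (a wrong-lattice solution mislabels the
#' recorded spots), so s^2 recomputed from the reported cell is unrelated to
#' the intensities -- the mechanism that produces aberrant pseudo-Wilson
#' fits downstream.
#'
#' Fully deterministic given `config$seed` (the global RNG state is left
#' untouched).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset`: list with `frames` (frames tibble) and
#'   `truth` (tibble: `frame_id`, `population` = population of the reported
#'   cell, `true_population`, `misindexed`, `b`, `g`).
#' @export
generate_frames <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_frames_impl(config))
}

generate_frames_impl <- function(cfg) {
  n <- cfg$n_frames
  npop <- nrow(cfg$populations)
  empty_refl <- tibble(h = integer(), k = integer(), l = integer(),
                       i_partial = numeric(), sigma_i = numeric())
  if (n == 0L) {
    frames <- frames_tbl(character(0), as_cells_tbl(matrix(numeric(0), 0, 6)))
    truth <- tibble(frame_id = character(), population = integer(),
                    true_population = integer(), misindexed = logical(),
                    b = numeric(), g = numeric())
    return(structure(list(frames = frames, truth = truth), class = "synthetic_dataset"))
  }

  ids <- sprintf("frame_%04d", seq_len(n))
  true_pop <- sample.int(npop, n, replace = TRUE, prob = cfg$populations$weight)
  jitter_cell <- function(pop) {
    med <- unlist(cfg$populations[pop, CELL_PARS])
    med + c(rnorm(3, 0, cfg$jitter_edge), rnorm(3, 0, cfg$jitter_angle))
  }
  true_cells <- t(vapply(true_pop, jitter_cell, numeric(6)))
  colnames(true_cells) <- CELL_PARS

  n_mis <- round(cfg$misindex_fraction * n)
  mis_idx <- if (n_mis > 0) sample.int(n, n_mis) else integer(0)
  misindexed <- seq_len(n) %in% mis_idx
  reported_pop <- true_pop
  reported_cells <- true_cells
  for (i in mis_idx) {
    others <- setdiff(seq_len(npop), true_pop[i])
    wrong <- if (length(others) > 1) sample(others, 1) else if (length(others) == 1) others else 1L
    reported_pop[i] <- wrong
    reported_cells[i, ] <- jitter_cell(wrong)
  }

  b_true <- rnorm(n, cfg$b_mean, cfg$b_sd)
  g_true <- exp(rnorm(n, cfg$log_g_mean, cfg$log_g_sd))

  ori_list <- vector("list", n)
  refl_list <- vector("list", n)
  for (i in seq_len(n)) {
    true_cell <- true_cells[i, ]
    M0 <- real_basis_from_cell(true_cell)
    if (cfg$orientation_model == "uniform") {
      Q <- random_rotations(1)[[1]]
    } else {
      d <- sample_vmf(1, cfg$orientation_mean, cfg$orientation_kappa)[1, ]
      c_dir <- M0[, 3] / sqrt(sum(M0[, 3]^2))
      Q <- rotation_from_z(d) %*% rotation_about(c(0, 0, 1), runif(1, 0, 2 * pi)) %*%
        t(rotation_from_z(c_dir))
    }
    real_lab <- Q %*% M0
    ori_list[[i]] <- solve(real_lab)      # rows a*, b*, c* in lab coordinates

    hkl <- sample_hkl(true_cell, M0, cfg$n_reflections, cfg$s2_range)
    s2_true <- reflection_s2(true_cell, hkl)
    p <- runif(cfg$n_reflections, cfg$partiality_range[1], cfg$partiality_range[2])
    eps <- if (cfg$noise_sd > 0) exp(rnorm(cfg$n_reflections, 0, cfg$noise_sd)) else 1
    I <- g_true[i] * exp(-2 * b_true[i] * s2_true) * p * eps
    if (misindexed[i]) {
      # A wrong-lattice indexing solution assigns wrong Miller indices to the
      # recorded spots: scramble the index-to-intensity pairing, so s^2
      # recomputed from the reported cell is unrelated to the intensities.
      hkl <- hkl[sample.int(nrow(hkl)), , drop = FALSE]
    }
    refl_list[[i]] <- tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                             i_partial = I, sigma_i = 0.1 * abs(I))
  }

  frames <- frames_tbl(ids, as_cells_tbl(reported_cells),
                       orientation = ori_list, reflections = refl_list,
                       wavelength = 1.3, source_file = "synthetic")
  truth <- tibble(frame_id = ids, population = reported_pop,
                  true_population = true_pop, misindexed = misindexed,
                  b = b_true, g = g_true)
  structure(list(frames = frames, truth = truth), class = "synthetic_dataset")
}

# Integer hkl whose s^2 under `cell` is near-uniform on s2_range: draw a
# target |q| uniform in s^2, a random direction, and round to the nearest
# lattice point (dense reciprocal lattices of macromolecular cells make the
# rounding error in s^2 small). Rejects (0,0,0) and out-of-range rounds.
sample_hkl <- function(cell, M0, n, s2_range) {
  out <- matrix(0L, 0, 3)
  while (nrow(out) < n) {
    m <- 2L * (n - nrow(out)) + 8L
    s2 <- runif(m, s2_range[1], s2_range[2])
    u <- matrix(rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    q <- u * (2 * sqrt(s2))                       # |q| = 1/d
    hkl <- round(q %*% M0)                        # h = q . a etc.
    keep <- rowSums(hkl != 0) > 0
    hkl <- hkl[keep, , drop = FALSE]
    if (nrow(hkl) > 0) {
      s2h <- reflection_s2(cell, hkl)
      hkl <- hkl[s2h >= s2_range[1] & s2h <= s2_range[2], , drop = FALSE]
      out <- rbind(out, hkl)
    }
  }
  storage.mode(out) <- "integer"
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic serial dataset: %d frames, %d population(s), %d mis-indexed\n",
              nrow(x$frames), length(unique(x$truth$true_population)),
              sum(x$truth$misindexed)))
  invisible(x)
}
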