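# Readers/writers for per-frame serial data.
#
# The canonical interchange format is "det-frames-v1", a versioned JSON
# document:
#
#   {
#     "format": "det-frames-v1",
#     "frames": [
#       {
#         "frame_id": "img_0001",
#         "cell": {"a": 69, "b": 169, "c": 288,
#                  "alpha": 90, "beta": 90, "gamma": 90},
#         "orientation": {"astar": [..3..], "bstar": [..3..],
#                         "cstar": [..3..]},            // 1/A, optional
#         "wavelength": 1.3,                            // A, optional
#         "reflections": {"h": [...], "k": [...], "l": [...],
#                         "i_partial": [...], "sigma_i": [...]}, // optional
#         "source_file": "..."                          // optional
#       }, ...
#     ]
#   }
#
# Unknown per-frame fields are preserved on a read/write round trip.

#' Build a frames tibble
#'
#' The frames tibble is the package's unit of data: one row per diffraction
#' image with columns `frame_id` (character, unique), `a`..`gamma` (unit
#' cell), `orientation` (list of 3x3 matrices with rows a*, b*, c* in lab
#' coordinates, or NULL), `reflections` (list of tibbles with columns `h`,
#' `k`, `l`, `i_partial`, `sigma_i`, or NULL), `wavelength` (A, NA allowed)
#' and `source_file`.
#'
#' @param frame_id Character vector of unique ids.
#' @param cells Cells in any form accepted by [as_cells_tbl()].
#' @param orientation List of 3x3 matrices (or NULLs).
#' @param reflections List of reflection tibbles (or NULLs).
#' @param wavelength Numeric vector (A).
#' @param source_file Character vector.
#' @return A validated frames tibble.
#' @export
frames_tbl <- function(frame_id, cells, orientation = NULL, reflections = NULL,
                       wavelength = NA_real_, source_file = NA_character_) {
  cells <- as_cells_tbl(cells)
  n <- length(frame_id)
  stopifnot(nrow(cells) == n)
  out <- dplyr::bind_cols(
    tibble(frame_id = as.character(frame_id)),
    cells[CELL_PARS]
  )
  out$orientation <- orientation %||% rep(list(NULL), n)
  out$reflections <- reflections %||% rep(list(NULL), n)
  out$wavelength <- rep_len(wavelength, n)
  out$source_file <- rep_len(source_file, n)
  validate_frames(out)
  out
}

#' Validate a frames tibble
#'
#' Checks id uniqueness, cell validity, orientation matrix shape, and
#' reflection-table invariants (integer hkl, never (0,0,0)).
#'
#' @param frames A frames tibble.
#' @return `frames`, invisibly.
#' @export
validate_frames <- function(frames) {
  stopifnot(is.data.frame(frames))
  need <- c("frame_id", CELL_PARS, "orientation", "reflections")
  missing <- setdiff(need, names(frames))
  if (length(missing)) abort(paste0("frames tibble lacks columns: ", paste(missing, collapse = ", ")))
  if (anyDuplicated(frames$frame_id)) abort("frame_id values must be unique within a dataset")
  for (i in seq_len(nrow(frames))) {
    id <- frames$frame_id[i]
    tryCatch(validate_cell(unlist(frames[i, CELL_PARS])),
             error = function(e) abort(sprintf("frame '%s': %s", id, conditionMessage(e))))
    ori <- frames$orientation[[i]]
    if (!is.null(ori) && (!is.matrix(ori) || !all(dim(ori) == 3L))) {
      abort(sprintf("frame '%s': orientation must be a 3x3 matrix", id))
    }
    refl <- frames$reflections[[i]]
    if (!is.null(refl)) {
      if (!all(c("h", "k", "l", "i_partial") %in% names(refl))) {
        abort(sprintf("frame '%s': reflections need columns h, k, l, i_partial", id))
      }
      hkl <- as.matrix(refl[, c("h", "k", "l")])
      if (any(hkl != round(hkl))) abort(sprintf("frame '%s': non-integer hkl", id))
      if (any(rowSums(hkl != 0) == 0)) abort(sprintf("frame '%s': reflection (0,0,0) is invalid", id))
    }
  }
  invisible(frames)
}

FRAME_KNOWN_FIELDS <- c("frame_id", "cell", "orientation", "wavelength",
                        "reflections", "source_file")

#' Read frames from a det-frames-v1 JSON file
#'
#' @param path Path to a JSON file.
#' @return A frames tibble. Unknown per-frame fields are kept in an `extra`
#'   list-column and written back by [write_frames_json()].
#' @export
read_frames_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "det-frames-v1")) {
    abort(sprintf("'%s' is not a det-frames-v1 document (format field: %s)",
                  path, doc$format %||% "absent"))
  }
  fl <- doc$frames
  n <- length(fl)
  if (n == 0) {
    return(frames_tbl(character(0), as_cells_tbl(matrix(numeric(0), 0, 6))))
  }
  get_cell <- function(f, i) {
    cl <- f$cell
    if (is.null(cl) || !all(CELL_PARS %in% names(cl))) {
      abort(sprintf("frame %d: missing or incomplete 'cell' field", i))
    }
    unlist(cl[CELL_PARS])
  }
  cells <- do.call(rbind, purrr::imap(fl, get_cell))
  ori <- purrr::imap(fl, function(f, i) {
    o <- f$orientation
    if (is.null(o)) return(NULL)
    if (!all(c("astar", "bstar", "cstar") %in% names(o))) {
      abort(sprintf("frame %d: orientation needs astar, bstar, cstar", i))
    }
    m <- rbind(unlist(o$astar), unlist(o$bstar), unlist(o$cstar))
    if (!all(dim(m) == 3L)) abort(sprintf("frame %d: orientation vectors must have 3 components", i))
    m
  })
  refl <- purrr::imap(fl, function(f, i) {
    r <- f$reflections
    if (is.null(r)) return(NULL)
    cols <- c("h", "k", "l", "i_partial", "sigma_i")
    if (!all(c("h", "k", "l", "i_partial") %in% names(r))) {
      abort(sprintf("frame %d: reflections need h, k, l, i_partial", i))
    }
    tibble(
      h = as.integer(unlist(r$h)), k = as.integer(unlist(r$k)),
      l = as.integer(unlist(r$l)),
      i_partial = as.numeric(unlist(r$i_partial)),
      sigma_i = if (is.null(r$sigma_i)) NA_real_ else as.numeric(unlist(r$sigma_i))
    )
  })
  out <- frames_tbl(
    frame_id = purrr::imap_chr(fl, function(f, i) f$frame_id %||% abort(sprintf("frame %d: missing frame_id", i))),
    cells = cells, orientation = ori, reflections = refl,
    wavelength = purrr::map_dbl(fl, ~ .x$wavelength %||% NA_real_),
    source_file = purrr::map_chr(fl, ~ .x$source_file %||% NA_character_)
  )
  out$extra <- purrr::map(fl, function(f) {
    ex <- f[setdiff(names(f), FRAME_KNOWN_FIELDS)]
    if (length(ex) == 0) NULL else ex
  })
  out
}

#' Write frames to a det-frames-v1 JSON file
#'
#' Lossless counterpart of [read_frames_json()]: numbers are written at full
#' precision, so write-read-write is byte-identical.
#'
#' @param frames A frames tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames_json <- function(frames, path) {
  validate_frames(frames)
  fl <- purrr::map(seq_len(nrow(frames)), function(i) {
    f <- list(
      frame_id = frames$frame_id[i],
      cell = as.list(frames[i, CELL_PARS])
    )
    ori <- frames$orientation[[i]]
    if (!is.null(ori)) {
      f$orientation <- list(astar = ori[1, ], bstar = ori[2, ], cstar = ori[3, ])
    }
    wl <- frames$wavelength[i]
    if (!is.null(wl) && is.finite(wl)) f$wavelength <- wl
    refl <- frames$reflections[[i]]
    if (!is.null(refl)) {
      f$reflections <- list(h = refl$h, k = refl$k, l = refl$l,
                            i_partial = refl$i_partial, sigma_i = refl$sigma_i)
    }
    sf <- frames$source_file[i]
    if (!is.null(sf) && !is.na(sf)) f$source_file <- sf
    if ("extra" %in% names(frames) && !is.null(frames$extra[[i]])) {
      f <- c(f, frames$extra[[i]])
    }
    f
  })
  doc <- list(format = "det-frames-v1", frames = fl)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a subset of a CrystFEL stream file
#'
#' Parses `Begin chunk`/`End chunk` blocks: per-chunk cell parameters
#' (nm and degrees, converted to angstroms: lengths x10), reciprocal axis
#' rows `astar`/`bstar`/`cstar` (1/nm, converted to 1/A: x0.1), and the
#' reflection list columns h, k, l, I, sigma(I). Chunks without a crystal
#' yield no frame; malformed chunks are skipped with a message naming the
#' line. Panel and geometry records are ignored.
#'
#' @param path Path to a `.stream` text file.
#' @return A frames tibble; attribute `n_skipped` counts skipped chunks.
#' @export
read_crystfel_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("----- Begin chunk -----", lines, fixed = TRUE)
  end <- grep("----- End chunk -----", lines, fixed = TRUE)
  if (length(begin) != length(end)) abort("unbalanced chunk markers in stream file")
  frames <- list()
  n_skipped <- 0L
  for (ci in seq_along(begin)) {
    chunk <- lines[begin[ci]:end[ci]]
    parsed <- tryCatch(parse_stream_chunk(chunk, ci), error = function(e) {
      inform(sprintf("read_crystfel_stream: skipping malformed chunk %d (line %d): %s",
                     ci, begin[ci], conditionMessage(e)))
      n_skipped <<- n_skipped + 1L
      NULL
    })
    if (!is.null(parsed)) frames[[length(frames) + 1L]] <- parsed
  }
  if (length(frames) == 0) abort(sprintf("no indexed chunks parsed from '%s'", path))
  ids <- purrr::map_chr(frames, "frame_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  out <- frames_tbl(
    frame_id = ids,
    cells = do.call(rbind, purrr::map(frames, "cell")),
    orientation = purrr::map(frames, "orientation"),
    reflections = purrr::map(frames, "reflections"),
    wavelength = purrr::map_dbl(frames, "wavelength"),
    source_file = rep(path, length(frames))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

# Returns NULL (no crystal) or a list(frame_id, cell, orientation,
# reflections, wavelength). Errors for malformed crystal records.
parse_stream_chunk <- function(chunk, index) {
  has_crystal <- any(grepl("Begin crystal", chunk, fixed = TRUE))
  if (!has_crystal) return(NULL)
  num <- function(x) suppressWarnings(as.numeric(x))

  cell_line <- grep("^Cell parameters", chunk, value = TRUE)
  if (length(cell_line) == 0) abort("crystal without 'Cell parameters' record")
  tok <- regmatches(cell_line[1], gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", cell_line[1]))[[1]]
  vals <- num(tok)
  if (length(vals) < 6 || any(is.na(vals[1:6]))) abort("unparseable cell parameters")
  cell <- c(vals[1:3] * 10, vals[4:6])     # nm -> A

  ori <- NULL
  stars <- purrr::map(c("astar", "bstar", "cstar"), function(ax) {
    ln <- grep(paste0("^", ax, " ="), chunk, value = TRUE)
    if (length(ln) == 0) return(NULL)
    v <- num(regmatches(ln[1], gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", ln[1]))[[1]])
    if (length(v) < 3 || any(is.na(v[1:3]))) abort(sprintf("unparseable %s row", ax))
    v[1:3] * 0.1                           # 1/nm -> 1/A
  })
  if (!any(vapply(stars, is.null, logical(1)))) ori <- do.call(rbind, stars)

  wl <- NA_real_
  wl_line <- grep("^wavelength =", chunk, value = TRUE)
  if (length(wl_line) > 0) {
    wl <- num(regmatches(wl_line[1], gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", wl_line[1]))[[1]][1])
  }

  refl <- NULL
  rstart <- grep("Reflections measured after indexing", chunk, fixed = TRUE)
  rend <- grep("End of reflections", chunk, fixed = TRUE)
  if (length(rstart) > 0 && length(rend) > 0 && rend[1] > rstart[1] + 2) {
    body <- chunk[(rstart[1] + 2):(rend[1] - 1)]    # skip column header line
    fields <- strsplit(trimws(body), "\\s+")
    ok <- vapply(fields, length, integer(1)) >= 5
    if (!all(ok)) abort("short reflection row")
    mat <- do.call(rbind, purrr::map(fields, ~ num(.x[1:5])))
    if (any(is.na(mat))) abort("unparseable reflection row")
    if (any(mat[, 1:3] != round(mat[, 1:3]))) abort("non-integer hkl in reflection list")
    refl <- tibble(h = as.integer(mat[, 1]), k = as.integer(mat[, 2]),
                   l = as.integer(mat[, 3]), i_partial = mat[, 4], sigma_i = mat[, 5])
  }

  fn_line <- grep("^Image filename:", chunk, value = TRUE)
  ev_line <- grep("^Event:", chunk, value = TRUE)
  id <- if (length(fn_line) > 0) trimws(sub("^Image filename:", "", fn_line[1])) else sprintf("chunk_%d", index)
  if (length(ev_line) > 0) id <- paste0(id, trimws(sub("^Event:", "", ev_line[1])))

  list(frame_id = id, cell = cell, orientation = ori, reflections = refl,
       wavelength = wl)
}

#' Write / read a reflection table as CSV
#'
#' Columns `h`, `k`, `l`, `i_partial`, `sigma_i`; numeric round trip is
#' lossless at full double precision.
#'
#' @param frame One-row frames tibble (or a reflection tibble directly).
#' @param path CSV path.
#' @return `path` invisibly (write); a reflection tibble (read).
#' @export
write_reflections_csv <- function(frame, path) {
  refl <- if (is.data.frame(frame) && "reflections" %in% names(frame)) {
    stopifnot(nrow(frame) == 1L)
    frame$reflections[[1]]
  } else frame
  if (is.null(refl)) refl <- tibble(h = integer(), k = integer(), l = integer(),
                                    i_partial = numeric(), sigma_i = numeric())
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  if (any(hkl != round(hkl))) abort("non-integer hkl")
  readr::write_csv(refl[, c("h", "k", "l", "i_partial", "sigma_i")], path)
  invisible(path)
}

#' @rdname write_reflections_csv
#' @export
read_reflections_csv <- function(path) {
  refl <- readr::read_csv(path, col_types = readr::cols(
    h = readr::col_double(), k = readr::col_double(), l = readr::col_double(),
    i_partial = readr::col_double(), sigma_i = readr::col_double()
  ))
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  if (any(hkl != round(hkl))) abort("non-integer hkl in reflection CSV")
  refl$h <- as.integer(refl$h); refl$k <- as.integer(refl$k); refl$l <- as.integer(refl$l)
  as_tibble(refl)
}

#' Read a unit-cell table from CSV
#'
#' Convenience reader for clustering-only workflows: a CSV with columns
#' `frame_id` (optional) and `a`..`gamma` becomes a frames tibble without
#' orientations or reflections.
#'
#' @param path CSV path.
#' @return A frames tibble.
#' @export
read_cells_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- if ("frame_id" %in% names(df)) as.character(df$frame_id) else sprintf("frame_%04d", seq_len(nrow(df)))
  frames_tbl(ids, as_cells_tbl(df), source_file = path)
}
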