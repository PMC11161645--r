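# ---- 32-bit float TIFF ------------------------------------------------------
#
# Reading goes through tiff::readTIFF (libtiff handles the IEEE-float
# sample format). Writing uses a minimal baseline-TIFF emitter below:
# the CRAN tiff package only writes integer sample formats at 32 bits,
# which quantizes and breaks lossless round-trips, so float32 output is
# produced directly (uncompressed, one strip per page, little-endian).
# Doubles are rounded to float32 once on the first save; thereafter
# save -> load -> save is bit-identical.

sidecar_path <- function(path) paste0(path, ".json")

# write matrices as a multi-page 32-bit float TIFF
write_float_tiff <- function(pages, path) {
  stopifnot(length(pages) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  n_ifd_entries <- 10L
  ifd_size <- 2L + n_ifd_entries * 12L + 4L
  nbytes <- vapply(pages, function(m) 4L * length(m), integer(1))
  data_off <- integer(length(pages))
  ifd_off <- integer(length(pages))
  off <- 8L
  for (k in seq_along(pages)) {
    data_off[k] <- off
    off <- off + nbytes[k]
    ifd_off[k] <- off
    off <- off + ifd_size
  }
  # header: little-endian magic, version 42, offset of first IFD
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2)
  wb(ifd_off[1], 4)
  entry <- function(tag, type, count, value) {
    wb(as.integer(tag), 2); wb(as.integer(type), 2)
    wb(as.integer(count), 4)
    if (type == 3L) {          # SHORT: left-justified in the 4-byte slot
      wb(as.integer(value), 2); wb(0L, 2)
    } else {
      wb(as.integer(value), 4)
    }
  }
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    # strip data, row-major as TIFF expects
    wb(as.numeric(t(m)), 4)
    wb(n_ifd_entries, 2)
    entry(256, 4, 1, ncol(m))          # ImageWidth
    entry(257, 4, 1, nrow(m))          # ImageLength
    entry(258, 3, 1, 32)               # BitsPerSample
    entry(259, 3, 1, 1)                # Compression: none
    entry(262, 3, 1, 1)                # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[k])      # StripOffsets
    entry(277, 3, 1, 1)                # SamplesPerPixel
    entry(278, 4, 1, nrow(m))          # RowsPerStrip
    entry(279, 4, 1, nbytes[k])        # StripByteCounts
    entry(339, 3, 1, 3)                # SampleFormat: IEEE float
    wb(if (k < length(pages)) ifd_off[k + 1] else 0L, 4)
  }
  invisible(path)
}

write_float_pages <- function(pages, path, meta) {
  vals <- unlist(lapply(pages, as.numeric))
  if (!all(is.finite(vals)))
    stop("TIFF payload must be finite")
  write_float_tiff(pages, path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_float_pages <- function(path, default_meta = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    warning("missing sidecar ", sc, "; using default metadata")
    meta <- default_meta
  }
  list(pages = pages, meta = meta)
}

config_to_list <- function(config) unclass(config)

config_from_list <- function(lst) {
  if (is.null(lst)) return(NULL)
  keep <- intersect(names(lst), names(formals(optical_config)))
  args <- lst[keep]
  # JSON/YAML nulls come back as NULL, NA or empty; any means "default"
  args <- args[vapply(args, function(v)
    is.atomic(v) && length(v) == 1 && !is.na(v), logical(1))]
  do.call(optical_config, args)
}

#' Save / load a phase mask as 32-bit float TIFF with a JSON sidecar
#'
#' The wrapped phase grid is written as a single-page 32-bit float TIFF;
#' the sidecar carries the label, the scale factor of the float
#' encoding, and (optionally) the optical configuration. Loading without
#' a sidecar warns and falls back to defaults; loading against an
#' expected grid size that does not match is an error -- masks are never
#' silently resampled.
#'
#' @param mask A \code{\link{phase_mask}}.
#' @param path Output TIFF path (sidecar at \code{<path>.json}).
#' @param config Optional \code{\link{optical_config}} stored alongside.
#' @return \code{save_mask}: the path, invisibly. \code{load_mask}: a
#'   \code{\link{phase_mask}} with attribute \code{config} (an
#'   \code{optical_config} or \code{NULL}).
#' @export
save_mask <- function(mask, path, config = NULL) {
  stopifnot(inherits(mask, "phase_mask"))
  meta <- list(type = "phase_mask", label = mask$label,
               grid_n = nrow(mask$phase))
  if (!is.null(config)) meta$config <- config_to_list(config)
  write_float_pages(list(mask$phase), path, meta)
}

#' @rdname save_mask
#' @param expect_grid_n Optional grid size the caller requires; a
#'   mismatch is an explicit error.
#' @export
load_mask <- function(path, expect_grid_n = NULL) {
  r <- read_float_pages(path, default_meta = list(type = "phase_mask",
                                                  label = ""))
  m <- phase_mask(r$pages[[1]], label = r$meta$label %||% "")
  if (!is.null(expect_grid_n) && nrow(m$phase) != expect_grid_n)
    stop(sprintf("mask grid is %d px but %d px was requested; not resampling",
                 nrow(m$phase), as.integer(expect_grid_n)))
  attr(m, "config") <- config_from_list(r$meta$config)
  m
}

#' Save / load an image or PSF stack as multi-page float TIFF
#'
#' One TIFF page per axial position, in ascending z; the sidecar carries
#' the z grid, the pixel pitch, and the float-encoding scale. On load,
#' a sidecar whose z grid length does not match the page count is an
#' error.
#'
#' @param stack A \code{psf_stack}, or a 3D array (z x y x x) with
#'   attributes \code{z_positions} (or \code{z_grid}) and
#'   \code{pixel_pitch}.
#' @param path Output TIFF path.
#' @return \code{save_stack}: the path, invisibly. \code{load_stack}:
#'   a \code{psf_stack}.
#' @export
save_stack <- function(stack, path) {
  if (inherits(stack, "psf_stack")) {
    values <- stack$values; z <- stack$z_grid; pitch <- stack$pixel_pitch
  } else {
    values <- stack
    z <- attr(stack, "z_positions") %||% attr(stack, "z_grid")
    pitch <- attr(stack, "pixel_pitch")
    if (is.null(z)) stop("stack must carry z positions")
  }
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be ascending")
  pages <- lapply(seq_len(dim(values)[1]), function(k) values[k, , ])
  write_float_pages(pages, path,
                    list(type = "stack", z_grid = z, pixel_pitch = pitch))
}

#' @rdname save_stack
#' @export
load_stack <- function(path) {
  r <- read_float_pages(path, default_meta = list(type = "stack"))
  z <- as.numeric(r$meta$z_grid %||% seq_along(r$pages))
  if (length(z) != length(r$pages))
    stop(sprintf("sidecar z grid has %d entries but the TIFF has %d pages",
                 length(z), length(r$pages)))
  side_y <- nrow(r$pages[[1]]); side_x <- ncol(r$pages[[1]])
  values <- array(0, dim = c(length(r$pages), side_y, side_x))
  for (k in seq_along(r$pages)) values[k, , ] <- r$pages[[k]]
  structure(list(values = values, z_grid = z,
                 pixel_pitch = as.numeric(r$meta$pixel_pitch %||% 1)),
            class = "psf_stack")
}

#' Write / read tracks as CSV (track_id, t, x, y, z)
#'
#' @param tracks List of tracks (see
#'   \code{\link{simulate_brownian_tracks}}).
#' @param path CSV path.
#' @return \code{write_tracks}: the path, invisibly.
#'   \code{read_tracks}: the list of tracks.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr)
    data.frame(track_id = tr$id, t = tr$times,
               x = tr$positions[, 1], y = tr$positions[, 2],
               z = tr$positions[, 3]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("track_id", "t", "x", "y", "z") %in% names(df)))
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$t), ]
    list(id = d$track_id[1], times = d$t,
         positions = cbind(x = d$x, y = d$y, z = d$z))
  })
}

#' Run configuration: bundle of settings for a reproducible run
#'
#' Serializable container tying together the optical configuration, the
#' noise model, optimizer settings, a seed, and I/O paths. Round-trips
#' losslessly through YAML/JSON (\code{load_run_config(save_run_config(x))}
#' reproduces the configuration).
#'
#' @param optical An \code{\link{optical_config}}.
#' @param noise A \code{\link{noise_model}}.
#' @param design An \code{\link{optimize_settings}} or
#'   \code{\link{multizone_diameters}} design, or \code{NULL}.
#' @param seed Integer seed.
#' @param paths Named list of file paths.
#' @param log_level One of "quiet", "info", "debug".
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(optical = optical_config(), noise = noise_model(),
                       design = NULL, seed = 1, paths = list(),
                       log_level = "info") {
  structure(list(optical = optical, noise = noise, design = design,
                 seed = as.integer(seed), paths = paths,
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param x A \code{run_config}.
#' @param path YAML (\code{.yaml}/\code{.yml}) or JSON path.
#' @export
save_run_config <- function(x, path) {
  stopifnot(inherits(x, "run_config"))
  lst <- list(optical = unclass(x$optical), noise = unclass(x$noise),
              design = if (!is.null(x$design))
                c(unclass(x$design), list(.class = class(x$design)[1])),
              seed = x$seed, paths = x$paths, log_level = x$log_level)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  design <- NULL
  if (!is.null(lst$design)) {
    cls <- lst$design$.class
    args <- lst$design[setdiff(names(lst$design), ".class")]
    design <- switch(cls,
      optimize_settings = {
        args$z_range <- as.numeric(args$z_range)
        do.call(optimize_settings, args[intersect(names(args),
                 names(formals(optimize_settings)))])
      },
      multizone_design = do.call(multizone_diameters,
        args[intersect(names(args), names(formals(multizone_diameters)))]),
      stop("unknown design class in config: ", cls))
  }
  run_config(optical = config_from_list(lst$optical),
             noise = do.call(noise_model, lst$noise[c("photons", "background")]),
             design = design, seed = lst$seed %||% 1,
             paths = as.list(lst$paths), log_level = lst$log_level %||% "info")
}
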