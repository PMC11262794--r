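#' Image stacks and well layouts
#'
#' An `image_stack` holds an ordered sequence of grayscale frames recorded at
#' a fixed inter-frame interval (nominally 6 s). Frames are integer matrices
#' in row-major image orientation: `frame[y + 1, x + 1]` is the intensity of
#' the pixel whose top-left corner sits at `(x, y)` in 0-based pixel
#' coordinates. Intensities are 8-bit gray-scale units (0-255) by default.
#'
#' A `well_layout` lists the rectangular regions of interest, one per well.
#' Rectangles use 0-based, half-open pixel coordinates: a well covers the
#' pixel columns `[x0, x1)` and rows `[y0, y1)`. This convention is used
#' everywhere in the package.
#'
#' @param frames list of numeric matrices, all the same dimensions.
#' @param frame_interval_s seconds between consecutive frames.
#' @param circadian_label optional label for the acquisition window (e.g.
#'   `"CT1"`). Metadata only; no clock model is applied.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s = 6, circadian_label = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("`frames` must be a list of at least 2 matrices", call. = FALSE)
  }
  dims <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop("all frames must be matrices with identical dimensions",
           call. = FALSE)
    }
    if (any(f < 0)) stop("frame intensities must be non-negative",
                         call. = FALSE)
  }
  check_positive(frame_interval_s, "frame_interval_s")
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         circadian_label = circadian_label),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g s interval%s\n",
              length(x$frames), d[1L], d[2L], x$frame_interval_s,
              if (is.null(x$circadian_label)) ""
              else paste0(" [", x$circadian_label, "]")))
  invisible(x)
}

#' @param wells data.frame with columns `well_id`, `x0`, `y0`, `x1`, `y1`
#'   (0-based, half-open pixel rectangles).
#' @rdname image_stack
#' @export
well_layout <- function(wells) {
  need <- c("well_id", "x0", "y0", "x1", "y1")
  if (!is.data.frame(wells) || !all(need %in% names(wells))) {
    stop("`wells` needs columns well_id, x0, y0, x1, y1", call. = FALSE)
  }
  if (nrow(wells) == 0L) stop("layout has no wells", call. = FALSE)
  if (anyDuplicated(wells$well_id)) {
    stop("well_ids must be unique", call. = FALSE)
  }
  if (any(wells$x1 <= wells$x0) || any(wells$y1 <= wells$y0)) {
    stop("well rectangles must have positive extent", call. = FALSE)
  }
  wells <- wells[, need]
  wells$well_id <- as.character(wells$well_id)
  class(wells) <- c("well_layout", "data.frame")
  wells
}

check_wells_in_frame <- function(layout, frame_dim) {
  # frame_dim = c(n_rows, n_cols) = c(height, width)
  if (any(layout$x0 < 0) || any(layout$y0 < 0) ||
      any(layout$x1 > frame_dim[2L]) || any(layout$y1 > frame_dim[1L])) {
    stop("well rectangle extends outside the frame", call. = FALSE)
  }
  invisible(layout)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are stored as 8-bit grayscale multi-page TIFF. `read_stack`
#' restores integer intensities in 0-255 gray-scale units.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @param bits_per_sample TIFF bit depth (8 or 16).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path, bits_per_sample = 8L) {
  stopifnot(inherits(stack, "image_stack"))
  maxval <- 2^bits_per_sample - 1
  pages <- lapply(stack$frames, function(f) pmin(pmax(f, 0), maxval) / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' @param frame_interval_s seconds between frames (not stored in the TIFF;
#'   supply it or read it from the layout file).
#' @rdname write_stack
#' @export
read_stack <- function(path, frame_interval_s = 6, bits_per_sample = 8L) {
  if (!file.exists(path)) {
    stop(sprintf("stack file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  maxval <- 2^bits_per_sample - 1
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate RGB-saved grayscale
    round(p * maxval)
  })
  image_stack(frames, frame_interval_s = frame_interval_s)
}

#' Read and write well layouts
#'
#' The layout file is JSON or YAML (chosen by extension) holding the well
#' rectangles together with the frame interval and, for synthetic data, the
#' generator seed, so a recording is interpretable from its layout alone.
#'
#' @param layout a [well_layout()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param frame_interval_s seconds between frames.
#' @param seed optional generator seed to record.
#' @export
write_layout <- function(layout, path, frame_interval_s = 6, seed = NULL) {
  stopifnot(inherits(layout, "well_layout"))
  obj <- list(
    frame_interval_s = frame_interval_s,
    seed = seed,
    wells = lapply(seq_len(nrow(layout)), function(i) {
      as.list(layout[i, c("well_id", "x0", "y0", "x1", "y1")])
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_layout
#' @return `read_layout` returns a [well_layout()] with attributes
#'   `frame_interval_s` and `seed`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("layout file not found: %s", path), call. = FALSE)
  }
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  wells <- do.call(rbind, lapply(obj$wells, function(w) {
    data.frame(well_id = as.character(w$well_id),
               x0 = as.numeric(w$x0), y0 = as.numeric(w$y0),
               x1 = as.numeric(w$x1), y1 = as.numeric(w$y1))
  }))
  out <- well_layout(wells)
  attr(out, "frame_interval_s") <- obj$frame_interval_s %||% 6
  attr(out, "seed") <- obj$seed
  out
}
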