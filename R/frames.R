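#' Region-of-interest box
#'
#' An axis-aligned rectangle locating the tissue region under assessment.
#' Coordinates are 0-based pixel offsets of the top-left corner, half-open:
#' the box covers columns `x .. x + w - 1` and rows `y .. y + h - 1`.
#'
#' @param x,y Top-left corner, 0-based pixel coordinates.
#' @param w,h Width and height in pixels; both must be positive.
#' @return An object of class `roi_box`.
#' @examples
#' roi_box(10, 5, 64, 48)
#' @export
roi_box <- function(x, y, w, h) {
  stopifnot(is_count(x), is_count(y), is_count(w, min = 1L), is_count(h, min = 1L))
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box x=%d y=%d w=%d h=%d>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

frame_dims <- function(frame) {
  d <- dim(frame)
  stopifnot(length(d) == 3L, d[3] == 3L)
  c(height = d[1], width = d[2])
}

box_inside <- function(box, frame) {
  d <- frame_dims(frame)
  box$x >= 0 && box$y >= 0 &&
    box$x + box$w <= d[["width"]] && box$y + box$h <= d[["height"]]
}

# Clamp a box so it lies fully inside the frame (box size preserved).
clamp_box <- function(box, frame) {
  d <- frame_dims(frame)
  x <- min(max(box$x, 0L), d[["width"]] - box$w)
  y <- min(max(box$y, 0L), d[["height"]] - box$h)
  roi_box(x, y, box$w, box$h)
}

#' Crop a frame to a region of interest
#'
#' @param frame An 8-bit RGB frame: integer array `height x width x 3`,
#'   values in 0..255, channels in logical R, G, B order.
#' @param box A [roi_box()]; must lie fully within the frame.
#' @return The `h x w x 3` sub-array.
#' @export
crop_frame <- function(frame, box) {
  if (!box_inside(box, frame)) {
    stop("ROI box extends outside the frame bounds", call. = FALSE)
  }
  frame[box$y + seq_len(box$h), box$x + seq_len(box$w), , drop = FALSE]
}

# Grayscale projection (ITU-R BT.601 luma), double matrix in 0..255.
as_gray <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Read a frame from a PNG file
#'
#' Normalizes grayscale and RGBA images to a logical RGB triple and
#' quantizes to 8-bit integers, the representation every downstream module
#' expects (the green band is always channel 2).
#'
#' @param path Path to a PNG file.
#' @return An integer array `height x width x 3`, values 0..255.
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    stop("unsupported PNG channel layout: ", dim(img)[3], call. = FALSE)
  }
  clip8(img * 255)
}

#' Write a frame to a PNG file
#'
#' @param frame Integer RGB array as produced by [read_frame_png()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(array(frame / 255, dim = dim(frame)), path)
  invisible(path)
}

# Normalize the pipeline's frame inputs to a pull-based source: a function
# returning the next frame, or NULL when exhausted. Accepts a directory of
# PNG frames (sorted by filename), a list of frames, or a function.
frame_source <- function(input) {
  if (is.function(input)) {
    return(input)
  }
  if (is.character(input) && length(input) == 1L) {
    if (!dir.exists(input)) {
      stop("frame directory not found: ", input, call. = FALSE)
    }
    paths <- sort(list.files(input, pattern = "\\.png$", full.names = TRUE))
    if (length(paths) == 0L) {
      stop("no PNG frames found in ", input, call. = FALSE)
    }
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(paths)) NULL else read_frame_png(paths[i])
    })
  }
  if (is.list(input)) {
    if (length(input) == 0L) stop("empty frame list", call. = FALSE)
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(input)) NULL else input[[i]]
    })
  }
  stop("unsupported frame input; give a directory, list of frames, or function",
       call. = FALSE)
}
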