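#' Tracker configuration
#'
#' Constants of the adaptive-correlation (MOSSE) tracker. Defaults follow
#' the canonical published recipe for this filter family: log + cosine
#' window preprocessing, a Gaussian target response of sigma 2 px, eight
#' random small affine perturbations at initialization, exponential
#' forgetting at rate 0.125, and a peak-to-sidelobe-ratio (PSR) threshold
#' of 8 for the pause/resume logic.
#'
#' @param learning_rate Exponential forgetting rate in (0, 1].
#' @param psr_pause Pause the tracker when PSR drops below this.
#' @param psr_resume Resume once PSR at the paused window reaches this.
#' @param sigma Standard deviation (px) of the Gaussian target peak.
#' @param n_perturb Number of random affine perturbations at init.
#' @param min_size Minimum ROI width/height in pixels.
#' @param eps Regularizer added to the filter denominator.
#' @param exclude Side length of the square around the peak excluded from
#'   the PSR sidelobe (default 11).
#' @param seed Seed for the init perturbations.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(learning_rate = 0.125, psr_pause = 8,
                           psr_resume = 8, sigma = 2, n_perturb = 8L,
                           min_size = 16L, eps = 1e-5, exclude = 11L,
                           seed = 0L) {
  stopifnot(is_number(learning_rate), learning_rate > 0, learning_rate <= 1,
            is_number(psr_pause), is_number(psr_resume),
            is_number(sigma), sigma > 0,
            is_count(n_perturb), is_count(min_size, min = 1L),
            is_number(eps), eps >= 0, is_count(exclude, min = 1L),
            is_count(seed))
  structure(list(learning_rate = learning_rate, psr_pause = psr_pause,
                 psr_resume = psr_resume, sigma = sigma,
                 n_perturb = as.integer(n_perturb),
                 min_size = as.integer(min_size), eps = eps,
                 exclude = as.integer(exclude), seed = as.integer(seed)),
            class = "tracker_config")
}

# Log transform, zero-mean/unit-norm, cosine (Hann) window. Standard MOSSE
# preprocessing; the window suppresses circular-correlation edge effects.
preprocess_window <- function(win) {
  x <- log(win + 1)
  x <- (x - mean(x)) / (sd(x) + 1e-5)
  x * hann2d(nrow(win), ncol(win))
}

hann2d <- function(h, w) {
  hy <- if (h == 1L) 1 else 0.5 * (1 - cos(2 * pi * (0:(h - 1)) / (h - 1)))
  hx <- if (w == 1L) 1 else 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1)))
  outer(hy, hx)
}

gaussian_target <- function(h, w, sigma) {
  cy <- floor(h / 2) + 1
  cx <- floor(w / 2) + 1
  ry <- matrix(seq_len(h), h, w)
  rx <- matrix(seq_len(w), h, w, byrow = TRUE)
  exp(-((ry - cy)^2 + (rx - cx)^2) / (2 * sigma^2))
}

# Sample `win` under a small affine map about its center (rotation +
# isotropic scale), bilinear interpolation, edge-clamped.
affine_perturb <- function(win, angle, scale) {
  h <- nrow(win); w <- ncol(win)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- matrix(seq_len(h), h, w) - cy
  rx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # Inverse map: destination -> source coordinates.
  sy <- (sin(-angle) * rx + cos(-angle) * ry) / scale + cy
  sx <- (cos(-angle) * rx - sin(-angle) * ry) / scale + cx
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- sy - y0; fx <- sx - x0
  idx <- function(r, c) win[cbind(as.vector(r), as.vector(c))]
  out <- (1 - fy) * (1 - fx) * idx(y0, x0) + (1 - fy) * fx * idx(y0, x1) +
    fy * (1 - fx) * idx(y1, x0) + fy * fx * idx(y1, x1)
  matrix(out, h, w)
}

#' Peak-to-sidelobe ratio of a correlation response
#'
#' `(peak - mean(sidelobe)) / sd(sidelobe)`, where the sidelobe is every
#' response pixel outside an `exclude x exclude` square centred on the
#' peak. Ties in the peak value are broken by the first maximum in
#' row-major scan order. A sidelobe with zero variance yields `Inf` (a
#' perfectly clean peak); this sentinel is documented rather than an
#' error because it arises for idealized responses.
#'
#' @param response Numeric matrix, the correlation response map.
#' @param exclude Side of the excluded square around the peak.
#' @return Scalar PSR (possibly `Inf`).
#' @export
psr <- function(response, exclude = 11L) {
  stopifnot(is.matrix(response), length(response) > 0)
  pk <- peak_location(response)
  half <- exclude %/% 2L
  rows <- max(1L, pk[1] - half):min(nrow(response), pk[1] + half)
  cols <- max(1L, pk[2] - half):min(ncol(response), pk[2] + half)
  mask <- matrix(TRUE, nrow(response), ncol(response))
  mask[rows, cols] <- FALSE
  side <- response[mask]
  if (length(side) < 2L) return(Inf)
  s <- sd(side)
  if (s == 0) return(Inf)
  (response[pk[1], pk[2]] - mean(side)) / s
}

# First maximum in row-major scan order, as c(row, col).
peak_location <- function(response) {
  hits <- which(response == max(response), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(unname(hits[1, 1]), unname(hits[1, 2]))
}

#' Initialize the MOSSE tracker
#'
#' Trains the correlation filter on the grayscale, log-preprocessed,
#' cosine-windowed ROI against a centred Gaussian target response,
#' aggregating over `n_perturb` random small affine perturbations of the
#' patch. The filter numerator/denominator live in the frequency domain of
#' the ROI window.
#'
#' @param frame RGB frame array.
#' @param roi A [roi_box()] fully inside the frame and at least
#'   `min_size` in both dimensions.
#' @param config A [tracker_config()].
#' @return A `tracker_state` with `status = "TRACKING"`.
#' @export
init_tracker <- function(frame, roi, config = tracker_config()) {
  stopifnot(inherits(roi, "roi_box"), inherits(config, "tracker_config"))
  if (roi$w < config$min_size || roi$h < config$min_size) {
    stop("ROI smaller than the minimum size of ", config$min_size, " px",
         call. = FALSE)
  }
  if (!box_inside(roi, frame)) {
    stop("ROI box extends outside the frame bounds", call. = FALSE)
  }
  win <- as_gray(crop_frame(frame, roi))
  G <- fft(gaussian_target(roi$h, roi$w, config$sigma))
  A <- matrix(0 + 0i, roi$h, roi$w)
  B <- matrix(0 + 0i, roi$h, roi$w)
  with_seed(config$seed, {
    for (j in seq_len(config$n_perturb + 1L)) {
      p <- if (j == 1L) {
        win
      } else {
        affine_perturb(win, angle = runif(1, -0.1, 0.1),
                       scale = 1 + runif(1, -0.05, 0.05))
      }
      Fp <- fft(preprocess_window(p))
      A <- A + G * Conj(Fp)
      B <- B + Fp * Conj(Fp)
    }
  })
  d <- frame_dims(frame)
  structure(list(A = A, B = B, config = config, last_box = roi,
                 status = "TRACKING",
                 frame_height = d[["height"]], frame_width = d[["width"]]),
            class = "tracker_state")
}

#' Advance the tracker by one frame
#'
#' Correlates the filter with the grayscale window at the last box,
#' re-centres the box on the response peak and computes the PSR. When the
#' PSR drops below the pause threshold the tracker pauses: no box is
#' reported, the filter and last box are left untouched, and the same
#' window is re-examined on subsequent frames until the PSR recovers to
#' the resume threshold. On tracking frames the filter is updated with
#' exponential forgetting at the configured learning rate.
#'
#' @param state A `tracker_state` from [init_tracker()].
#' @param frame RGB frame with the same dimensions as the init frame.
#' @return List with `state` (updated), `box` (a [roi_box()], or `NULL`
#'   while paused), `psr` and `status` (`"TRACKING"` or `"PAUSED"`).
#' @export
update_tracker <- function(state, frame) {
  stopifnot(inherits(state, "tracker_state"))
  d <- frame_dims(frame)
  if (d[["height"]] != state$frame_height || d[["width"]] != state$frame_width) {
    stop("frame size differs from the initialization frame", call. = FALSE)
  }
  cfg <- state$config
  box <- state$last_box
  win <- as_gray(crop_frame(frame, box))
  Fw <- fft(preprocess_window(win))
  H <- state$A / (state$B + cfg$eps)
  resp <- Re(fft(Fw * H, inverse = TRUE)) / length(Fw)
  p <- psr(resp, cfg$exclude)
  threshold <- if (state$status == "TRACKING") cfg$psr_pause else cfg$psr_resume
  if (p < threshold) {
    state$status <- "PAUSED"
    return(list(state = state, box = NULL, psr = p, status = "PAUSED"))
  }
  state$status <- "TRACKING"
  cy <- floor(box$h / 2) + 1
  cx <- floor(box$w / 2) + 1
  # A flat response (e.g. a zero-variance window) carries no localization
  # information; keep the box rather than drift to the row-major corner.
  pk <- if (max(resp) == min(resp)) c(cy, cx) else peak_location(resp)
  dy <- pk[1] - cy
  dx <- pk[2] - cx
  nx <- min(max(box$x + dx, 0L), state$frame_width - box$w)
  ny <- min(max(box$y + dy, 0L), state$frame_height - box$h)
  new_box <- roi_box(nx, ny, box$w, box$h)
  # Update the filter from the re-centred window.
  win2 <- as_gray(crop_frame(frame, new_box))
  F2 <- fft(preprocess_window(win2))
  G <- fft(gaussian_target(box$h, box$w, cfg$sigma))
  eta <- cfg$learning_rate
  state$A <- eta * (G * Conj(F2)) + (1 - eta) * state$A
  state$B <- eta * (F2 * Conj(F2)) + (1 - eta) * state$B
  state$last_box <- new_box
  list(state = state, box = new_box, psr = p, status = "TRACKING")
}

box_center <- function(box) {
  c(x = box$x + (box$w - 1) / 2, y = box$y + (box$h - 1) / 2)
}
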