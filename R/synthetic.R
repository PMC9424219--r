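#' Parameters of a synthetic fluorescence scene
#'
#' Describes one synthetic ROI patch as seen in ICG fluorescence
#' laparoscopy: tissue-coloured background in the red/blue channels, and a
#' green channel whose brightness encodes ICG perfusion. The leftmost
#' `perfused_fraction` of the patch width is drawn at `green_mu_high`, the
#' remainder at `green_mu_low`; `perfused_fraction = 1` with a bright mean
#' models uniformly adequate perfusion, while a dim mean or a fraction
#' below 1 models the two inadequate presentations (low green, non-uniform
#' diffusion).
#'
#' @param roi_width,roi_height Patch size in pixels.
#' @param green_mu_high,green_mu_low Green-channel means (0..255) for the
#'   perfused and unperfused column bands.
#' @param green_sigma Green-channel standard deviation (intensity levels).
#' @param perfused_fraction Fraction in 0..1 of the width drawn bright.
#' @param red_mu,blue_mu Background tissue means for the red/blue channels.
#' @param noise_sd Red/blue channel standard deviation.
#' @param seed Integer seed; all pixel draws flow from it.
#' @return An object of class `scene_params`.
#' @examples
#' generate_roi_patch(scene_params(seed = 7))$label
#' @export
scene_params <- function(roi_width = 80, roi_height = 60,
                         green_mu_high = 200, green_mu_low = 15,
                         green_sigma = 15, perfused_fraction = 1,
                         red_mu = 90, blue_mu = 70, noise_sd = 10,
                         seed = 0L) {
  stopifnot(is_count(roi_width), is_count(roi_height),
            is_number(green_mu_high), green_mu_high >= 0, green_mu_high <= 255,
            is_number(green_mu_low), green_mu_low >= 0, green_mu_low <= 255,
            is_number(green_sigma), green_sigma >= 0,
            is_number(perfused_fraction),
            perfused_fraction >= 0, perfused_fraction <= 1,
            is_number(red_mu), red_mu >= 0, red_mu <= 255,
            is_number(blue_mu), blue_mu >= 0, blue_mu <= 255,
            is_number(noise_sd), noise_sd >= 0,
            is_count(seed))
  structure(list(roi_width = as.integer(roi_width),
                 roi_height = as.integer(roi_height),
                 green_mu_high = green_mu_high, green_mu_low = green_mu_low,
                 green_sigma = green_sigma,
                 perfused_fraction = perfused_fraction,
                 red_mu = red_mu, blue_mu = blue_mu, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# Green mean threshold above which a uniformly perfused patch counts as
# adequate. The label is a function of the generating parameters only.
.ADEQUATE_MU <- 150

scene_label <- function(params) {
  as.integer(params$perfused_fraction >= 1 &&
               params$green_mu_high >= .ADEQUATE_MU)
}

#' Generate one labelled synthetic ROI patch
#'
#' The green channel is drawn per pixel from a clipped
#' Normal(mu, `green_sigma`) where mu is `green_mu_high` over the leftmost
#' `perfused_fraction` of the columns and `green_mu_low` elsewhere; red and
#' blue channels are clipped Gaussian tissue background. The perfusion
#' label depends only on the generating parameters (adequate iff the patch
#' is uniformly perfused at a bright green mean), never on extracted
#' features.
#'
#' @param params A [scene_params()] object.
#' @return A `labeled_sample`: list with `patch` (integer `h x w x 3`
#'   array, 0..255), `label` (1 adequate / 0 inadequate) and `params`.
#' @export
generate_roi_patch <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  w <- params$roi_width
  h <- params$roi_height
  if (w < 1L || h < 1L) stop("zero-area ROI", call. = FALSE)
  with_seed(params$seed, {
    n_bright <- round(params$perfused_fraction * w)
    mu_cols <- c(rep(params$green_mu_high, n_bright),
                 rep(params$green_mu_low, w - n_bright))
    green <- matrix(rnorm(h * w, mean = rep(mu_cols, each = h),
                          sd = params$green_sigma), h, w)
    red <- matrix(rnorm(h * w, params$red_mu, params$noise_sd), h, w)
    blue <- matrix(rnorm(h * w, params$blue_mu, params$noise_sd), h, w)
    patch <- array(c(clip8(red), clip8(green), clip8(blue)),
                   dim = c(h, w, 3L))
    structure(list(patch = patch, label = scene_label(params),
                   params = params),
              class = "labeled_sample")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws `round(n * class_balance)` adequate samples; the remaining
#' inadequate samples are split between the "low green" and "non-uniform
#' diffusion" presentations according to `inadequate_mix`. Per-sample scene
#' parameters are jittered within fixed ranges from a single seeded stream,
#' and the sample order is shuffled.
#'
#' @param n Number of samples.
#' @param class_balance Fraction of adequate samples (default 0.5).
#' @param base_params Baseline [scene_params()]; patch size and background
#'   means are taken from it.
#' @param seed Integer seed governing all draws.
#' @param inadequate_mix Fraction of inadequate samples of the low-green
#'   kind (default 0.5); the rest are non-uniform.
#' @return List of `labeled_sample` objects, length `n`.
#' @export
generate_dataset <- function(n, class_balance = 0.5,
                             base_params = scene_params(), seed = 1L,
                             inadequate_mix = 0.5) {
  stopifnot(is_count(n), is_number(class_balance),
            class_balance >= 0, class_balance <= 1,
            inherits(base_params, "scene_params"), is_count(seed),
            is_number(inadequate_mix),
            inadequate_mix >= 0, inadequate_mix <= 1)
  if (n == 0L) return(list())
  n_adequate <- round(n * class_balance)
  n_inadequate <- n - n_adequate
  n_low <- ceiling(n_inadequate * inadequate_mix)
  n_nonuni <- n_inadequate - n_low
  kinds <- c(rep("adequate", n_adequate), rep("low_green", n_low),
             rep("non_uniform", n_nonuni))
  with_seed(seed, {
    kinds <- sample(kinds)
    sample_seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      kind <- kinds[i]
      p <- base_params
      p$green_sigma <- runif(1, 5, 20)
      p$noise_sd <- runif(1, 5, 15)
      p$red_mu <- base_params$red_mu + runif(1, -10, 10)
      p$blue_mu <- base_params$blue_mu + runif(1, -10, 10)
      if (kind == "adequate") {
        p$perfused_fraction <- 1
        p$green_mu_high <- runif(1, 170, 235)
      } else if (kind == "low_green") {
        p$perfused_fraction <- 1
        p$green_mu_high <- runif(1, 0, 20)
      } else {
        p$perfused_fraction <- runif(1, 0.3, 0.7)
        p$green_mu_high <- runif(1, 170, 235)
        p$green_mu_low <- runif(1, 0, 20)
      }
      p$seed <- sample_seeds[i]
      s <- generate_roi_patch(p)
      s$kind <- kind
      s
    })
  })
}

#' Generate a synthetic tracking sequence
#'
#' A textured fluorescent patch (bright green blob over tissue background)
#' translates at a constant velocity across a noisy background frame.
#' During an optional occlusion interval the patch is hidden (replaced by
#' background) and its position is frozen, so that motion between
#' consecutive visible frames never exceeds the per-frame velocity.
#'
#' @param params [scene_params()] describing the target patch; its
#'   `roi_width`/`roi_height` set the target size.
#' @param n_frames Number of frames.
#' @param velocity Length-2 numeric `c(vx, vy)` in px/frame (or a scalar,
#'   taken as horizontal). Magnitude must not exceed `max_displacement`.
#' @param occlusion `NULL`, or an inclusive 1-based frame-index range
#'   `c(first, last)` during which the target is hidden.
#' @param seed Integer seed.
#' @param frame_width,frame_height Full frame size in pixels.
#' @param start Length-2 integer `c(x0, y0)`, 0-based top-left start
#'   position of the target.
#' @param max_displacement Upper bound on per-frame target motion (px).
#' @return A `tracking_sequence`: list with `frames` (list of RGB arrays)
#'   and `truth` (data.frame `frame, x, y, w, h, visible`; box columns are
#'   `NA` on occluded frames).
#' @export
generate_tracking_sequence <- function(params, n_frames, velocity,
                                       occlusion = NULL, seed = 0L,
                                       frame_width = 240, frame_height = 180,
                                       start = c(20, 20),
                                       max_displacement = 5) {
  stopifnot(inherits(params, "scene_params"), is_count(n_frames, min = 1L),
            is_count(seed), length(start) == 2L)
  if (length(velocity) == 1L) velocity <- c(velocity, 0)
  stopifnot(length(velocity) == 2L, all(is.finite(velocity)))
  if (sqrt(sum(velocity^2)) > max_displacement) {
    stop("per-frame velocity exceeds the maximum displacement of ",
         max_displacement, " px", call. = FALSE)
  }
  w <- params$roi_width
  h <- params$roi_height
  occluded <- rep(FALSE, n_frames)
  if (!is.null(occlusion)) {
    stopifnot(length(occlusion) == 2L, occlusion[1] <= occlusion[2],
              occlusion[1] >= 1, occlusion[2] <= n_frames)
    occluded[occlusion[1]:occlusion[2]] <- TRUE
  }
  # Precompute positions: frozen while occluded.
  pos <- matrix(NA_real_, n_frames, 2)
  cur <- as.numeric(start)
  for (i in seq_len(n_frames)) {
    pos[i, ] <- cur
    if (!occluded[i]) cur <- cur + velocity
  }
  xs <- round(pos[, 1]); ys <- round(pos[, 2])
  if (any(xs < 0 | ys < 0 | xs + w > frame_width | ys + h > frame_height)) {
    stop("target motion leaves the frame bounds", call. = FALSE)
  }
  with_seed(seed, {
    # Fixed target texture: green blob with radial falloff so the tracker
    # has structure to lock onto, drawn once.
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    fall <- 0.5 + 0.5 * exp(-(((rr - (h + 1) / 2)^2 + (cc - (w + 1) / 2)^2) /
                                (2 * (min(h, w) / 3)^2)))
    target <- array(0L, dim = c(h, w, 3L))
    target[, , 1] <- clip8(params$red_mu +
                             rnorm(h * w, 0, params$noise_sd))
    target[, , 2] <- clip8(params$green_mu_low +
                             (params$green_mu_high - params$green_mu_low) *
                             fall + rnorm(h * w, 0, params$green_sigma))
    target[, , 3] <- clip8(params$blue_mu +
                             rnorm(h * w, 0, params$noise_sd))
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      bg <- array(0L, dim = c(frame_height, frame_width, 3L))
      bg[, , 1] <- clip8(rnorm(frame_height * frame_width, params$red_mu,
                               params$noise_sd))
      bg[, , 2] <- clip8(rnorm(frame_height * frame_width, 25,
                               params$noise_sd))
      bg[, , 3] <- clip8(rnorm(frame_height * frame_width, params$blue_mu,
                               params$noise_sd))
      if (!occluded[i]) {
        bg[ys[i] + seq_len(h), xs[i] + seq_len(w), ] <- target
      }
      frames[[i]] <- bg
    }
    truth <- data.frame(frame = seq_len(n_frames),
                        x = ifelse(occluded, NA_integer_, xs),
                        y = ifelse(occluded, NA_integer_, ys),
                        w = w, h = h, visible = !occluded)
    structure(list(frames = frames, truth = truth),
              class = "tracking_sequence")
  })
}

#' Write a labelled dataset to disk
#'
#' Writes one PNG per patch plus a `manifest.csv` with filename, label,
#' presentation kind and the generating parameters.
#'
#' @param samples List of `labeled_sample` objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fn <- sprintf("patch_%04d.png", i)
    write_frame_png(s$patch, file.path(dir, fn))
    p <- s$params
    data.frame(filename = fn, label = s$label,
               kind = if (is.null(s$kind)) NA_character_ else s$kind,
               roi_width = p$roi_width, roi_height = p$roi_height,
               green_mu_high = p$green_mu_high, green_mu_low = p$green_mu_low,
               green_sigma = p$green_sigma,
               perfused_fraction = p$perfused_fraction,
               red_mu = p$red_mu, blue_mu = p$blue_mu,
               noise_sd = p$noise_sd, seed = p$seed)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a tracking sequence to disk
#'
#' Numbered PNG frames plus `truth.csv` with the per-frame ground-truth
#' boxes (`NA` rows while the target is occluded).
#'
#' @param sequence A `tracking_sequence`.
#' @param dir Output directory (created if needed).
#' @return Path to the truth CSV, invisibly.
#' @export
write_tracking_sequence <- function(sequence, dir) {
  stopifnot(inherits(sequence, "tracking_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sequence$frames)) {
    write_frame_png(sequence$frames[[i]],
                    file.path(dir, sprintf("frame_%05d.png", i)))
  }
  path <- file.path(dir, "truth.csv")
  write.csv(sequence$truth, path, row.names = FALSE)
  invisible(path)
}
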