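#' Pipeline configuration
#'
#' Wires the three pipeline blocks together: the initial ROI for the
#' tracker, the trained classifier, the histogram specification for
#' feature extraction, and the tracker constants.
#'
#' @param roi A [roi_box()]: the operator-selected region on frame 1.
#' @param model A fitted `perfusion_model`, or a path to one saved with
#'   [save_model()].
#' @param spec A [histogram_spec()].
#' @param tracker A [tracker_config()].
#' @param n_slices Number of feature slices (default 20).
#' @param output_dir Optional directory for the predictions CSV and
#'   annotated PNG frames.
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(roi, model, spec = histogram_spec(),
                            tracker = tracker_config(), n_slices = 20L,
                            output_dir = NULL, seed = 0L) {
  stopifnot(inherits(roi, "roi_box"), inherits(spec, "histogram_spec"),
            inherits(tracker, "tracker_config"), is_count(seed))
  if (is.character(model)) {
    if (!file.exists(model)) {
      stop("model file not found: ", model, call. = FALSE)
    }
    model <- load_model(model)
  }
  stopifnot(inherits(model, "perfusion_model"))
  structure(list(roi = roi, model = model, spec = spec, tracker = tracker,
                 n_slices = as.integer(n_slices), output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the pipeline on a frame stream
#'
#' Pulls frames from `source` one at a time and applies the full chain:
#' track the ROI, and on tracking frames extract the green-band feature
#' vector and classify perfusion. While the tracker is paused (target
#' lost) the frame is logged with status `PAUSED` and no box, score or
#' label — the assessment is skipped, never guessed. Per-frame latency is
#' measured and logged. If `output_dir` is set, a `predictions.csv` log
#' and annotated PNG frames (green box = adequate, red = inadequate) are
#' written; the log is flushed even if the source stops early.
#'
#' @param source A frame source accepted by the pipeline: a function
#'   returning the next RGB frame or `NULL` when exhausted, a directory
#'   of PNG frames, or a list of frames.
#' @param config A [pipeline_config()].
#' @return Data.frame with one row per consumed frame: `frame_index`,
#'   `x`, `y`, `w`, `h`, `psr`, `status`, `score`, `label`,
#'   `latency_ms`. Box and prediction columns are `NA` on paused frames.
#' @export
run_stream <- function(source, config) {
  stopifnot(inherits(config, "pipeline_config"))
  next_frame <- frame_source(source)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  rows <- list()
  state <- NULL
  i <- 0L
  repeat {
    frame <- next_frame()
    if (is.null(frame)) break
    t0 <- proc.time()[["elapsed"]]
    i <- i + 1L
    if (i == 1L) {
      state <- init_tracker(frame, config$roi, config$tracker)
      box <- config$roi
      p <- Inf
      status <- "TRACKING"
    } else {
      step <- update_tracker(state, frame)
      state <- step$state
      box <- step$box
      p <- step$psr
      status <- step$status
    }
    if (!is.null(box)) {
      feats <- extract_features(crop_frame(frame, box), config$spec,
                                config$n_slices)
      pred <- predict(config$model, feats)
      score <- pred$score
      label <- pred$label
    } else {
      score <- NA_real_
      label <- NA_integer_
    }
    latency <- 1000 * (proc.time()[["elapsed"]] - t0)
    rows[[i]] <- data.frame(
      frame_index = i,
      x = if (is.null(box)) NA_integer_ else box$x,
      y = if (is.null(box)) NA_integer_ else box$y,
      w = if (is.null(box)) NA_integer_ else box$w,
      h = if (is.null(box)) NA_integer_ else box$h,
      psr = p, status = status, score = score, label = label,
      latency_ms = latency)
    if (!is.null(out_dir)) {
      write_frame_png(annotate_frame(frame, box, label),
                      file.path(out_dir, sprintf("annotated_%05d.png", i)))
    }
  }
  if (i == 0L) stop("empty frame source: no frames to process", call. = FALSE)
  log <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(log, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  }
  log
}

#' Run the pipeline on a recorded sequence
#'
#' Offline analysis of a PNG frame directory or an in-memory frame list.
#' Identical code path to [run_stream()], so offline and streaming runs
#' of the same frames produce identical predictions.
#'
#' @param input Directory of PNG frames (sorted by filename) or a list of
#'   RGB frame arrays.
#' @param config A [pipeline_config()].
#' @return See [run_stream()].
#' @export
run_offline <- function(input, config) {
  run_stream(input, config)
}

# Draw a 2-px box on the frame: green for adequate, red for inadequate.
annotate_frame <- function(frame, box, label) {
  if (is.null(box)) return(frame)
  col <- if (isTRUE(label == 1L)) c(0L, 255L, 0L) else c(255L, 0L, 0L)
  rows <- box$y + seq_len(box$h)
  cols <- box$x + seq_len(box$w)
  edge_r <- c(utils::head(rows, 2), utils::tail(rows, 2))
  edge_c <- c(utils::head(cols, 2), utils::tail(cols, 2))
  for (ch in 1:3) {
    frame[edge_r, cols, ch] <- col[ch]
    frame[rows, edge_c, ch] <- col[ch]
  }
  frame
}
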