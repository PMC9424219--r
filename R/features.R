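#' Histogram specification for the green-band area feature
#'
#' The feature of slice i is the thresholded histogram area
#' `A_i = sum_{l=k}^{255} count_i(l) * (b(l+1) - b(l))`, where `count_i(l)`
#' is the number of slice pixels whose 8-bit green value equals `l`, `b`
#' are the bin edges and `k` excludes pixels with low green values. Under
#' the default unit bins (`b(l) = l`) the area is exactly the number of
#' slice pixels with green `>= k`.
#'
#' @param k Minimum included green level, 0..255. Default 25, the value
#'   that gave the best classification performance in clinical evaluation.
#' @param bin_edges Numeric vector of 257 strictly increasing bin edges
#'   `b(0)..b(256)`; default `0:256` (unit widths).
#' @return An object of class `histogram_spec`.
#' @export
histogram_spec <- function(k = 25, bin_edges = 0:256) {
  stopifnot(is_count(k), k >= 0, k <= 255,
            is.numeric(bin_edges), length(bin_edges) == 257L,
            all(diff(bin_edges) > 0))
  structure(list(k = as.integer(k), bin_edges = as.numeric(bin_edges)),
            class = "histogram_spec")
}

#' Split an ROI patch into vertical slices
#'
#' Slice `i` (0-based) covers columns `floor(i*W/n) .. floor((i+1)*W/n)-1`:
#' the slices are disjoint, cover every column at full patch height, are
#' ordered left to right, and their widths differ by at most one pixel.
#'
#' @param patch RGB array (`h x w x 3`) or a single-channel matrix.
#' @param n_slices Number of slices (default 20).
#' @return List of `n_slices` sub-arrays.
#' @export
split_roi <- function(patch, n_slices = 20L) {
  stopifnot(is_count(n_slices, min = 1L))
  w <- if (length(dim(patch)) == 3L) dim(patch)[2] else ncol(patch)
  if (w < n_slices) {
    stop("patch width (", w, ") is smaller than the number of slices (",
         n_slices, ")", call. = FALSE)
  }
  bounds <- floor((0:n_slices) * w / n_slices)
  lapply(seq_len(n_slices), function(i) {
    cols <- (bounds[i] + 1L):bounds[i + 1L]
    if (length(dim(patch)) == 3L) {
      patch[, cols, , drop = FALSE]
    } else {
      patch[, cols, drop = FALSE]
    }
  })
}

#' Green-band histogram of a slice
#'
#' @param slice RGB sub-array (green = channel 2) or a matrix of green
#'   values.
#' @return Integer vector of length 256; element `l + 1` is the number of
#'   pixels with green value exactly `l`.
#' @export
green_histogram <- function(slice) {
  g <- if (length(dim(slice)) == 3L) slice[, , 2] else slice
  stopifnot(all(g >= 0), all(g <= 255), all(g == round(g)))
  tabulate(as.integer(g) + 1L, nbins = 256L)
}

#' Thresholded histogram area
#'
#' Computes `sum_{l=k}^{255} counts[l] * (b(l+1) - b(l))`. With the default
#' unit bins this is the count of pixels with green `>= k`.
#'
#' @param counts Integer vector of 256 level counts, as from
#'   [green_histogram()].
#' @param spec A [histogram_spec()].
#' @return The area (non-negative scalar).
#' @export
histogram_area <- function(counts, spec = histogram_spec()) {
  stopifnot(inherits(spec, "histogram_spec"), length(counts) == 256L,
            all(counts >= 0))
  lv <- spec$k:255
  widths <- spec$bin_edges[lv + 2L] - spec$bin_edges[lv + 1L]
  sum(counts[lv + 1L] * widths)
}

#' Extract the 20-element perfusion feature vector
#'
#' Splits the patch into `n_slices` vertical slices and computes the
#' thresholded green-band histogram area of each, left to right. This is
#' the classifier's input representation.
#'
#' @param patch RGB array (`h x w x 3`), 8-bit values.
#' @param spec A [histogram_spec()].
#' @param n_slices Number of slices (default 20).
#' @param normalize If `TRUE`, divide each area by its slice's pixel count
#'   so features are fractions rather than raw counts. Off by default:
#'   raw areas are the canonical feature.
#' @return Numeric vector of length `n_slices`, all entries `>= 0`.
#' @examples
#' s <- generate_roi_patch(scene_params(seed = 1))
#' extract_features(s$patch)
#' @export
extract_features <- function(patch, spec = histogram_spec(),
                             n_slices = 20L, normalize = FALSE) {
  slices <- split_roi(patch, n_slices)
  vapply(slices, function(sl) {
    a <- histogram_area(green_histogram(sl), spec)
    if (normalize) a / (dim(sl)[1] * dim(sl)[2]) else a
  }, numeric(1))
}

#' Feature matrix of a labelled dataset
#'
#' @param samples List of `labeled_sample` objects (see
#'   [generate_dataset()]).
#' @param spec A [histogram_spec()].
#' @param n_slices Number of slices.
#' @return List with `X` (numeric `n x n_slices` matrix) and `y` (integer
#'   label vector).
#' @export
features_matrix <- function(samples, spec = histogram_spec(),
                            n_slices = 20L) {
  X <- t(vapply(samples, function(s) extract_features(s$patch, spec, n_slices),
                numeric(n_slices)))
  y <- vapply(samples, function(s) as.integer(s$label), integer(1))
  list(X = X, y = y)
}

#' Write a feature matrix as CSV
#'
#' One row per sample: features `f1..f20` then `label`.
#'
#' @param features List with `X` and `y`, as from [features_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- as.data.frame(features$X)
  names(df) <- paste0("f", seq_len(ncol(features$X)))
  df$label <- features$y
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV
#'
#' @param path CSV written by [write_features_csv()].
#' @return List with `X` and `y`.
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path)
  if (!"label" %in% names(df) || ncol(df) < 2L) {
    stop("malformed feature CSV (need f1..fN columns plus 'label'): ", path,
         call. = FALSE)
  }
  fcols <- setdiff(names(df), "label")
  X <- as.matrix(df[fcols])
  bad <- which(!stats::complete.cases(df) | apply(X, 1, function(r) any(r < 0)))
  if (length(bad) > 0L) {
    stop("malformed feature CSV: bad row ", bad[1], " in ", path,
         call. = FALSE)
  }
  list(X = X, y = as.integer(df$label))
}
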