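#' Foreground segmentation of a histological slice
#'
#' Classical promptable segmentation of tissue versus bright background:
#' grayscale conversion (luminance 0.299/0.587/0.114), global threshold by the
#' Otsu criterion (tissue is the dark class), morphological closing with a
#' disc brush, hole filling, and connected-component labeling. The result can
#' then be refined with point prompts ([apply_prompts()]): components
#' containing a positive prompt are kept, components containing a negative
#' prompt are discarded — the same contract as prompting an interactive
#' segmenter with a center-positive point and corner-negative points.
#'
#' @param slice RGB array (h x w x 3) or grayscale matrix in \[0, 1\].
#' @param closing_radius radius of the morphological closing disc, px.
#' @return an object of class `foreground_mask`: list with `mask` (logical
#'   matrix), `labels` (integer component labels), `provenance` (`"auto"`),
#'   `prompts` (`NULL` until prompted).
#' @export
segment_foreground <- function(slice, closing_radius = 3) {
  g <- to_gray(slice)
  if (diff(range(g)) < 1e-6)
    stop("no foreground: image is uniform")
  thr <- EBImage::otsu(g, range = c(0, 1))
  fg <- g < thr  # HE background is bright; tissue is the dark class
  if (!any(fg)) stop("no foreground below the Otsu threshold")
  if (closing_radius > 0) {
    kern <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    fg <- EBImage::closing(fg * 1, kern) > 0.5
  }
  fg <- EBImage::fillHull(fg * 1) > 0.5
  labels <- EBImage::bwlabel(fg * 1)
  structure(list(mask = matrix(as.logical(fg), nrow(g), ncol(g)),
                 labels = matrix(as.integer(labels), nrow(g), ncol(g)),
                 provenance = "auto", prompts = NULL),
            class = "foreground_mask")
}

#' Default point prompts: image center positive, four corners negative
#'
#' @param dim image dimensions `c(h, w)` (extra entries ignored).
#' @return list with `positive` and `negative` n x 2 matrices of `(x, y)`
#'   pixel coordinates.
#' @export
default_prompts <- function(dim) {
  h <- dim[1]; w <- dim[2]
  list(positive = cbind(x = (w + 1) / 2, y = (h + 1) / 2),
       negative = cbind(x = c(1, w, 1, w), y = c(1, 1, h, h)))
}

#' Select mask components with point prompts
#'
#' Keeps exactly the connected components that contain a positive prompt and
#' discards components containing any negative prompt. A component containing
#' both kinds of prompt is discarded with a prompt-conflict warning. A
#' positive prompt falling on background (no containing component) is an
#' error.
#'
#' @param fm a `foreground_mask` from [segment_foreground()] (its `labels`
#'   field is used).
#' @param positives,negatives n x 2 matrices of `(x, y)` pixel coordinates;
#'   at least one positive is required. Defaults: [default_prompts()].
#' @return a `foreground_mask` with provenance `"prompted"`.
#' @export
apply_prompts <- function(fm, positives = NULL, negatives = NULL) {
  stopifnot(inherits(fm, "foreground_mask"))
  if (is.null(positives) || is.null(negatives)) {
    dp <- default_prompts(dim(fm$mask))
    if (is.null(positives)) positives <- dp$positive
    if (is.null(negatives)) negatives <- dp$negative
  }
  positives <- rbind(positives); negatives <- rbind(negatives)
  if (nrow(positives) < 1) stop("at least one positive prompt is required")
  lab_at <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0) return(integer(0))
    r <- pmin(pmax(round(pts[, 2]), 1), nrow(fm$labels))
    c_ <- pmin(pmax(round(pts[, 1]), 1), ncol(fm$labels))
    fm$labels[cbind(r, c_)]
  }
  pos_lab <- lab_at(positives)
  if (any(pos_lab == 0L))
    stop("prompt unresolved: positive prompt lies on background")
  neg_lab <- setdiff(lab_at(negatives), 0L)
  conflict <- intersect(pos_lab, neg_lab)
  if (length(conflict))
    warning("prompt conflict: component(s) ", paste(conflict, collapse = ", "),
            " contain both positive and negative prompts; discarded")
  keep <- setdiff(unique(pos_lab), neg_lab)
  if (!length(keep))
    stop("prompt unresolved: all positively prompted components were discarded")
  mask <- matrix(fm$labels %in% keep, nrow(fm$labels), ncol(fm$labels))
  structure(list(mask = mask,
                 labels = ifelse(mask, fm$labels, 0L),
                 provenance = "prompted",
                 prompts = list(positive = positives, negative = negatives)),
            class = "foreground_mask")
}

#' Segment a slice with the default prompt set
#'
#' Convenience wrapper: [segment_foreground()] followed by [apply_prompts()]
#' with the center-positive / corner-negative defaults. If the positive
#' prompt cannot be resolved (e.g. a crack or jitter moved the tissue off the
#' image center) and `fallback = TRUE`, the prompt is re-placed at the
#' centroid of the largest component — the automated analogue of manually
#' supplying an additional prompt when the default is unsatisfactory.
#'
#' @inheritParams segment_foreground
#' @param positives,negatives optional prompt matrices; see [apply_prompts()].
#' @param fallback re-prompt the largest component when the positive prompt
#'   falls on background.
#' @return a prompted `foreground_mask`.
#' @export
segment_slice <- function(slice, closing_radius = 3,
                          positives = NULL, negatives = NULL,
                          fallback = TRUE) {
  fm <- segment_foreground(slice, closing_radius)
  tryCatch(
    apply_prompts(fm, positives = positives, negatives = negatives),
    error = function(e) {
      if (!fallback || !grepl("prompt unresolved", conditionMessage(e)))
        stop(e)
      sizes <- tabulate(fm$labels[fm$labels > 0L])
      lab <- which.max(sizes)
      idx <- which(fm$labels == lab, arr.ind = TRUE)
      pos <- idx[which.min((idx[, 1] - mean(idx[, 1]))^2 +
                           (idx[, 2] - mean(idx[, 2]))^2), , drop = FALSE]
      apply_prompts(fm, positives = cbind(x = pos[, 2], y = pos[, 1]),
                    negatives = negatives)
    })
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("foreground_mask: %d x %d, %d fg px (%.1f%%), provenance %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$provenance))
  invisible(x)
}

# Accept a foreground_mask or a plain logical/numeric matrix everywhere a
# mask is consumed downstream.
as_mask <- function(m) {
  if (inherits(m, "foreground_mask")) return(m$mask)
  if (is.matrix(m)) return(m > 0.5)
  stop("not a mask: expected foreground_mask or matrix")
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b masks (`foreground_mask` or logical matrices).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
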