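#' Masked mean squared error between two rasters
#'
#' Mean of squared grayscale differences over the mask pixels only,
#' intensities in \[0, 1\]. RGB inputs are converted to grayscale first.
#'
#' @param a,b rasters of identical shape.
#' @param mask mask (`foreground_mask` or logical matrix) selecting the
#'   pixels entering the mean; must be nonempty.
#' @return nonnegative scalar.
#' @export
masked_mse <- function(a, b, mask) {
  ga <- to_gray(a); gb <- to_gray(b); m <- as_mask(mask)
  stopifnot(identical(dim(ga), dim(gb)), identical(dim(ga), dim(m)))
  if (!any(m)) stop("empty mask")
  mean((ga[m] - gb[m])^2)
}

#' Masked structural similarity (SSIM) between two rasters
#'
#' Standard SSIM with stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`,
#' `L = 1`. The default `"global"` mode treats the whole mask as a single
#' window: means, variances and covariance are computed over the mask pixels
#' (sample normalization, n - 1) and one SSIM value is returned — appropriate
#' for the irregular tissue masks this package works with. `"windowed"` mode
#' is the sliding 7x7 uniform-window variant averaged over the mask eroded by
#' the window radius.
#'
#' @param a,b rasters of identical shape, intensities in \[0, 1\].
#' @param mask mask with at least 2 pixels.
#' @param mode `"global"` (default) or `"windowed"`.
#' @return scalar in \[-1, 1\].
#' @export
masked_ssim <- function(a, b, mask, mode = c("global", "windowed")) {
  mode <- match.arg(mode)
  ga <- to_gray(a); gb <- to_gray(b); m <- as_mask(mask)
  stopifnot(identical(dim(ga), dim(gb)), identical(dim(ga), dim(m)))
  C1 <- 0.01^2; C2 <- 0.03^2
  if (mode == "global") {
    if (sum(m) < 2) stop("mask needs at least 2 pixels")
    x <- ga[m]; y <- gb[m]
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(x); vy <- stats::var(y)
    cxy <- stats::cov(x, y)
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  # windowed: 7x7 uniform window, valid on the mask eroded by the radius
  w <- matrix(1 / 49, 7, 7)
  valid <- EBImage::erode(m * 1, EBImage::makeBrush(7, "box")) > 0.5
  if (!any(valid)) stop("mask too thin for the 7x7 windowed mode")
  f <- function(z) EBImage::filter2(z, w, boundary = "replicate")
  mux <- f(ga); muy <- f(gb)
  sxx <- f(ga * ga) - mux^2; syy <- f(gb * gb) - muy^2
  sxy <- f(ga * gb) - mux * muy
  ssim_map <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
  mean(ssim_map[valid])
}

# Neighbor index sets for the moving-average comparator.
coherence_neighbors <- function(i, n, window, mode) {
  half <- window %/% 2
  idx <- if (mode == "symmetric") setdiff(seq(i - half, i + half), i)
         else seq(i - window, i - 1)
  idx[idx >= 1 & idx <= n]
}

#' Stack coherence: MSE and SSIM against a moving average of adjacent slices
#'
#' For each slice the comparator is the pixel-wise mean of the `window`
#' adjacent slices. The default `"symmetric"` reading excludes the slice
#' itself and takes the two neighbors on each side (`{i-2, i-1, i+1, i+2}`
#' for `window = 4`), truncated at the stack ends; the `"causal"` reading
#' takes the `window` preceding slices. Slices with fewer than 2 available
#' neighbors are not evaluable. Metrics are computed on grayscale over the
#' intersection of the slice's mask with the union of the comparator masks.
#'
#' @param stack a [section_stack()] (or a `strategy_run`, whose registered
#'   stack is used).
#' @param masks per-slice masks aligned to the (possibly registered) slices.
#' @param window number of adjacent slices in the moving average.
#' @param window_mode `"symmetric"` (default) or `"causal"`.
#' @param ssim_mode passed to [masked_ssim()].
#' @return data.frame with `slice`, `n_neighbors`, `mse`, `ssim` for
#'   evaluable slices; attributes `mse` and `ssim` hold the aggregates
#'   (means over evaluable slices).
#' @export
stack_coherence <- function(stack, masks, window = 4,
                            window_mode = c("symmetric", "causal"),
                            ssim_mode = c("global", "windowed")) {
  window_mode <- match.arg(window_mode)
  ssim_mode <- match.arg(ssim_mode)
  if (inherits(stack, "strategy_run")) stack <- stack$stack
  stopifnot(inherits(stack, "section_stack"))
  n <- length(stack)
  if (n <= window) stop("stack length must exceed the window")
  gray <- lapply(stack$slices, to_gray)
  m <- lapply(masks, as_mask)
  rows <- list()
  for (i in seq_len(n)) {
    nb <- coherence_neighbors(i, n, window, window_mode)
    if (length(nb) < 2) next
    comp <- Reduce(`+`, gray[nb]) / length(nb)
    comp_mask <- Reduce(`|`, m[nb])
    eval_mask <- m[[i]] & comp_mask
    if (sum(eval_mask) < 2) next
    rows[[length(rows) + 1L]] <- data.frame(
      slice = i, n_neighbors = length(nb),
      mse = masked_mse(gray[[i]], comp, eval_mask),
      ssim = masked_ssim(gray[[i]], comp, eval_mask, mode = ssim_mode))
  }
  out <- do.call(rbind, rows)
  attr(out, "mse") <- mean(out$mse)
  attr(out, "ssim") <- mean(out$ssim)
  attr(out, "n_evaluable") <- nrow(out)
  out
}

#' Run the four-strategy stack-coherence comparison
#'
#' Segments the stack, registers it under each requested strategy, re-segments
#' the registered slices (background omission follows registration, as each
#' strategy label defines), and evaluates [stack_coherence()] on each result.
#'
#' @param stack a [section_stack()].
#' @param strategies subset of [strategy_labels()].
#' @param window,window_mode,ssim_mode passed to [stack_coherence()].
#' @param closing_radius passed to the segmenter.
#' @param ... passed to [estimate_rigid()].
#' @return object of class `strategy_comparison`: list with `results` (named
#'   list of per-strategy entries, each holding `run`, `per_slice`, `mse`,
#'   `ssim`, `n_evaluable`) and `table` (tidy data.frame: strategy, slice,
#'   mse, ssim).
#' @export
compare_strategies <- function(stack, strategies = strategy_labels(),
                               window = 4,
                               window_mode = c("symmetric", "causal"),
                               ssim_mode = c("global", "windowed"),
                               closing_radius = 3, ...) {
  window_mode <- match.arg(window_mode)
  ssim_mode <- match.arg(ssim_mode)
  strategies <- match.arg(strategies, strategy_labels(), several.ok = TRUE)
  masks0 <- lapply(stack$slices, segment_slice, closing_radius = closing_radius)
  results <- list()
  tabs <- list()
  for (s in strategies) {
    run <- run_strategy(stack, masks = masks0, strategy = s, ...)
    # a grossly misregistered slice can leave the frame entirely; it then has
    # no segmentable foreground and is excluded from the evaluation
    reg_masks <- if (s == "unregistered") masks0
                 else lapply(run$stack$slices, function(sl)
                   tryCatch(segment_slice(sl, closing_radius = closing_radius),
                            error = function(e)
                              matrix(FALSE, dim(sl)[1], dim(sl)[2])))
    per <- stack_coherence(run$stack, reg_masks, window = window,
                           window_mode = window_mode, ssim_mode = ssim_mode)
    results[[s]] <- list(strategy = s, run = run, per_slice = per,
                         mse = attr(per, "mse"), ssim = attr(per, "ssim"),
                         n_evaluable = attr(per, "n_evaluable"))
    tabs[[s]] <- data.frame(strategy = s, per[c("slice", "mse", "ssim")])
  }
  structure(list(results = results, table = do.call(rbind, tabs)),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("strategy_comparison (aggregate over evaluable slices):\n")
  for (r in x$results)
    cat(sprintf("  %-12s mse %.5g  ssim %.4f  (n = %d)\n",
                r$strategy, r$mse, r$ssim, r$n_evaluable))
  invisible(x)
}

#' @export
summary.strategy_comparison <- function(object, ...) {
  do.call(rbind, lapply(object$results, function(r)
    data.frame(strategy = r$strategy, mse = r$mse, ssim = r$ssim,
               n_evaluable = r$n_evaluable)))
}

#' @export
plot.strategy_comparison <- function(x, ...) {
  tab <- x$table
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::boxplot(log10(mse) ~ strategy, data = tab, las = 2,
                    ylab = "log10 MSE", xlab = "", main = "per-slice MSE", ...)
  graphics::boxplot(ssim ~ strategy, data = tab, las = 2,
                    ylab = "SSIM", xlab = "", main = "per-slice SSIM", ...)
  invisible(x)
}
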