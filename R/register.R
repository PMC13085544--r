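#' Rigid registration strategy labels
#'
#' The four strategies compared by the pipeline: `unregistered` (no
#' alignment), `r_original` (transforms estimated on the raw RGB slices),
#' `r_segmented` (estimated on the RGB slices with the background blanked by
#' the foreground mask), `r_binary` (estimated on the binary masks). In every
#' case the estimated transforms are applied to the original RGB slices.
#'
#' @export
strategy_labels <- function() c("unregistered", "r_original", "r_segmented", "r_binary")

# Median intensity of the 1-px image border; used as the background/fill
# estimate so registration needs no externally supplied background level.
border_level <- function(g) {
  stats::median(c(g[1, ], g[nrow(g), ], g[, 1], g[, ncol(g)]))
}

# Intensity centroid and principal-axis angle of a content-weight image.
content_moments <- function(w) {
  s <- sum(w)
  if (s <= 0) return(NULL)
  h <- nrow(w); wd <- ncol(w)
  xs <- rep(seq_len(wd), each = h); ys <- rep(seq_len(h), times = wd)
  cx <- sum(xs * w) / s; cy <- sum(ys * w) / s
  mu20 <- sum((xs - cx)^2 * w) / s
  mu02 <- sum((ys - cy)^2 * w) / s
  mu11 <- sum((xs - cx) * (ys - cy) * w) / s
  list(cx = cx, cy = cy, angle = 0.5 * atan2(2 * mu11, mu20 - mu02))
}

#' Estimate the rigid 2D transform aligning two rasters
#'
#' Estimates the [rigid2d()] transform that maps `moving` onto `fixed` by
#' minimizing the mean-squared pixel difference over (angle, tx, ty), over a
#' 3-level image pyramid with Nelder-Mead local optimization per level.
#'
#' The default initialization (`init = "moments"`) is by image moments: the
#' translation from the content-centroid difference and the rotation from
#' the principal-axis angle difference (an axis is defined mod pi; the
#' smaller-magnitude resolution is used), with +/-90 and 180 degree restarts
#' competing at the coarsest level — the restart with the lowest initial
#' metric wins the tie-break. `init = "sweep"` replaces the moments angle by
#' an exhaustive coarse angle sweep (`sweep_step_deg` steps over
#' `+/-max_angle_deg`) with, for each candidate angle, the translation
#' induced by mapping the rotated content centroid of `moving` onto that of
#' `fixed`; it is slower but robust when the content is heavily corrupted or
#' nearly rotationally symmetric. Content weights for the moments are
#' |intensity - border median|, so bright-background HE images and binary
#' masks are handled identically.
#'
#' @param fixed,moving rasters of the same shape (RGB arrays are converted to
#'   grayscale). `moving` must have nonzero variance.
#' @param n_levels pyramid levels (downsampling by 2 per level).
#' @param max_iter Nelder-Mead iteration cap per level.
#' @param tol convergence tolerance (relative, on the MSE objective).
#' @param init `"moments"` (default) or `"sweep"`.
#' @param sweep_step_deg angle step of the coarse sweep, degrees.
#' @param max_angle_deg restrict the sweep to |angle| below this bound (the
#'   full circle by default); use when the physical misalignment is known to
#'   be bounded.
#' @return a `rigid2d` mapping `moving` onto `fixed`, rotation center at the
#'   image center. Attribute `converged` is `FALSE` (with a warning) if the
#'   optimizer hit the iteration cap at the finest level.
#' @export
estimate_rigid <- function(fixed, moving, n_levels = 3, max_iter = 200,
                           tol = 1e-6, init = c("moments", "sweep"),
                           sweep_step_deg = 2.5, max_angle_deg = 180) {
  init <- match.arg(init)
  gf <- to_gray(fixed); gm <- to_gray(moving)
  stopifnot(identical(dim(gf), dim(gm)))
  if (stats::var(as.vector(gm)) < 1e-12)
    stop("degenerate moving image: zero variance")
  fill_m <- border_level(gm)

  pyr_f <- list(gf); pyr_m <- list(gm)
  for (k in seq_len(n_levels - 1)) {
    if (min(dim(pyr_f[[k]])) < 32) break
    pyr_f[[k + 1]] <- downsample2(pyr_f[[k]])
    pyr_m[[k + 1]] <- downsample2(pyr_m[[k]])
  }
  n_levels <- length(pyr_f)

  # MSE objective with the coordinate grid cached per pyramid level;
  # the inverse rigid lookup is inlined for speed.
  obj_at <- function(level) {
    f <- pyr_f[[level]]; m <- pyr_m[[level]]
    h <- nrow(f); w <- ncol(f)
    ctr <- image_center(f)
    gx <- rep(seq_len(w), each = h) - ctr[1]
    gy <- rep(seq_len(h), times = w) - ctr[2]
    fv <- as.vector(f)
    function(par) {
      ca <- cos(par[1]); sa <- sin(par[1])
      dx <- gx - par[2]; dy <- gy - par[3]
      mv <- bilinear_sample(m, ca * dx + sa * dy + ctr[1],
                            -sa * dx + ca * dy + ctr[2], fill = fill_m)
      mean((mv - fv)^2)
    }
  }
  nm_ctl <- function(maxit)
    list(maxit = maxit, reltol = tol, parscale = c(0.05, 1, 1))

  # candidate construction at the coarsest level
  lev <- n_levels
  ctr_lev <- image_center(pyr_f[[lev]])
  wf <- abs(pyr_f[[lev]] - border_level(pyr_f[[lev]]))
  wm <- abs(pyr_m[[lev]] - fill_m)
  mf <- content_moments(wf); mm <- content_moments(wm)
  if (init == "moments") {
    d_ang <- if (is.null(mf) || is.null(mm)) 0 else {
      d <- mf$angle - mm$angle
      atan2(sin(2 * d), cos(2 * d)) / 2  # axis mod pi, smaller magnitude
    }
    angles <- d_ang + c(0, pi / 2, -pi / 2, pi)
    min_sep <- Inf  # refine every restart; the tie-break is the metric
  } else {
    angles <- seq(-max_angle_deg, max_angle_deg - 1e-9,
                  by = sweep_step_deg) * pi / 180
    min_sep <- 4 * sweep_step_deg * pi / 180
  }
  f_obj <- obj_at(lev)
  cand <- t(vapply(angles, function(th) {
    tr <- if (is.null(mf) || is.null(mm)) c(0, 0) else {
      R <- rigid2d_matrix(rigid2d(th))
      c(mf$cx, mf$cy) - ctr_lev - R %*% (c(mm$cx, mm$cy) - ctr_lev)
    }
    par <- c(th, tr[1], tr[2])
    c(par, f_obj(par))
  }, numeric(4)))
  # refine the best well-separated candidates (at most 4)
  ord <- order(cand[, 4])
  picks <- integer(0)
  for (i in ord) {
    if (length(picks) == 4) break
    if (!length(picks) ||
        all(abs(atan2(sin(cand[i, 1] - cand[picks, 1]),
                      cos(cand[i, 1] - cand[picks, 1]))) > min_sep) ||
        init == "moments")
      picks <- c(picks, i)
  }
  fits <- lapply(picks, function(i)
    stats::optim(cand[i, 1:3], f_obj, method = "Nelder-Mead",
                 control = nm_ctl(max_iter)))
  best <- fits[[which.min(vapply(fits, function(f) f$value, 0))]]
  par <- best$par

  # refine through finer levels (translation doubles per level)
  converged <- TRUE
  for (level in rev(seq_len(n_levels - 1))) {
    par <- c(par[1], 2 * par[2], 2 * par[3])
    fit <- stats::optim(par, obj_at(level), method = "Nelder-Mead",
                        control = nm_ctl(ceiling(max_iter / 2)))
    par <- fit$par
    if (level == 1) converged <- fit$convergence == 0L
  }
  if (!converged)
    warning("rigid registration hit the iteration cap; returning best-so-far")
  out <- rigid2d(par[1], par[2], par[3], image_center(gf))
  attr(out, "converged") <- converged
  out
}

#' Chain pairwise transforms to a common reference slice
#'
#' Given pairwise transforms `T_i` mapping slice `i+1` onto slice `i`, returns
#' the absolute transform of every slice into the frame of the reference
#' slice (which gets the identity). Chaining runs in both directions from the
#' reference, which limits drift accumulation.
#'
#' @param pairwise list of `n - 1` [rigid2d()] transforms; element `i` maps
#'   slice `i + 1` onto slice `i`.
#' @param reference_index index of the reference slice (default: middle).
#' @return list of `n` absolute `rigid2d` transforms.
#' @export
chain_to_reference <- function(pairwise,
                               reference_index = (length(pairwise) %/% 2) + 1L) {
  n <- length(pairwise) + 1L
  stopifnot(reference_index >= 1, reference_index <= n)
  ctr <- pairwise[[1]]$center
  abs_t <- vector("list", n)
  abs_t[[reference_index]] <- rigid2d(0, 0, 0, ctr)
  if (reference_index < n) {
    for (j in seq(reference_index + 1L, n))
      abs_t[[j]] <- rigid2d_compose(abs_t[[j - 1L]], pairwise[[j - 1L]])
  }
  if (reference_index > 1) {
    for (j in seq(reference_index - 1L, 1L))
      abs_t[[j]] <- rigid2d_compose(abs_t[[j + 1L]],
                                    rigid2d_invert(pairwise[[j]]))
  }
  abs_t
}

#' Resample a slice under a rigid transform
#'
#' Bilinear resampling: the output image is the input moved by `t`
#' (out-of-frame pixels take `fill`). Applied to original RGB slices after
#' transform estimation, whatever image the transform was estimated on.
#'
#' @param slice RGB array or grayscale matrix in \[0, 1\].
#' @param t a [rigid2d()].
#' @param fill fill value(s); default: per-channel median of the image border
#'   (the background level).
#' @return raster of the same shape.
#' @export
resample_slice <- function(slice, t, fill = NULL) {
  if (is.null(fill)) {
    fill <- if (is.matrix(slice)) border_level(slice)
            else vapply(seq_len(dim(slice)[3]),
                        function(ch) border_level(slice[, , ch]), 0)
  }
  warp_image(slice, t, fill = fill)
}

#' Register a stack under one strategy
#'
#' Estimates pairwise rigid transforms between adjacent slices on the
#' strategy's registration image (raw grayscale for `r_original`, grayscale
#' with background blanked to the border level for `r_segmented`, the binary
#' mask for `r_binary`), chains them to the middle reference slice, and
#' applies the absolute transforms to the original RGB slices.
#' `unregistered` is a passthrough with identity transforms.
#'
#' @param stack a [section_stack()].
#' @param masks list of per-slice masks ([segment_slice()] output or logical
#'   matrices); required for `r_segmented` and `r_binary`.
#' @param strategy one of [strategy_labels()].
#' @param ... passed to [estimate_rigid()].
#' @return list of class `strategy_run`: `stack` (registered
#'   [section_stack()]), `transforms` (absolute per-slice [rigid2d()]),
#'   `pairwise`, `strategy`, `reference_index`.
#' @export
run_strategy <- function(stack, masks = NULL,
                         strategy = strategy_labels(), ...) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(stack, "section_stack"))
  n <- length(stack)
  ctr <- image_center(stack$slices[[1]])
  ref <- (n %/% 2) + if (n %% 2 == 0) 0L else 1L  # middle slice

  if (strategy == "unregistered") {
    ident <- lapply(seq_len(n), function(i) rigid2d(0, 0, 0, ctr))
    return(structure(list(stack = stack, transforms = ident,
                          pairwise = NULL, strategy = strategy,
                          reference_index = ref),
                     class = "strategy_run"))
  }
  if (strategy %in% c("r_segmented", "r_binary")) {
    if (is.null(masks) || length(masks) != n)
      stop("strategy '", strategy, "' requires one mask per slice")
  }
  reg_img <- switch(strategy,
    r_original = lapply(stack$slices, to_gray),
    r_segmented = lapply(seq_len(n), function(i) {
      g <- to_gray(stack$slices[[i]])
      m <- as_mask(masks[[i]])
      g[!m] <- border_level(g)
      g
    }),
    r_binary = lapply(seq_len(n), function(i) as_mask(masks[[i]]) * 1))

  pairwise <- vector("list", n - 1L)
  for (i in seq_len(n - 1L))
    pairwise[[i]] <- estimate_rigid(reg_img[[i]], reg_img[[i + 1L]], ...)
  abs_t <- chain_to_reference(pairwise, ref)
  reg_slices <- lapply(seq_len(n), function(i)
    if (rigid2d_is_identity(abs_t[[i]])) stack$slices[[i]]
    else resample_slice(stack$slices[[i]], abs_t[[i]]))
  out_stack <- section_stack(reg_slices, stack$pixel_size_um, stack$z_um,
                             stack$species)
  structure(list(stack = out_stack, transforms = abs_t, pairwise = pairwise,
                 strategy = strategy, reference_index = ref),
            class = "strategy_run")
}

#' @export
print.strategy_run <- function(x, ...) {
  cat(sprintf("strategy_run: %s, %d slices, reference slice %d\n",
              x$strategy, length(x$transforms), x$reference_index))
  invisible(x)
}

#' Ground-truth error of recovered absolute transforms
#'
#' Compares the absolute transforms of a [run_strategy()] result against the
#' generator's applied per-slice perturbations. The truth for slice `j` in
#' the reference frame is `P_ref o P_j^{-1}` where `P_j` maps the unperturbed
#' slice onto stored slice `j`.
#'
#' @param run a `strategy_run`.
#' @param truth the `truth` element of [generate_stack()].
#' @return data.frame with per-slice `angle_err_deg` and `trans_err_px`.
#' @export
transform_errors <- function(run, truth) {
  ref <- run$reference_index
  p_ref <- truth$transforms[[ref]]
  do.call(rbind, lapply(seq_along(run$transforms), function(j) {
    expected <- rigid2d_compose(p_ref, rigid2d_invert(truth$transforms[[j]]))
    e <- rigid2d_error(run$transforms[[j]], expected)
    data.frame(slice = j, angle_err_deg = e[["angle_deg"]],
               trans_err_px = e[["trans_px"]])
  }))
}
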