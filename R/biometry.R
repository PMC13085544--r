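#' Species-specific histological shrinkage factors
#'
#' Shrinkage is the ratio post-processing / in-vivo dimension, so dividing a
#' measured value by the factor estimates the in-vivo dimension. Lateral
#' metrics (lesion diameter) use the axial-length factors; vertical metrics
#' (retinal thickness) use the central-retinal-thickness factors.
#'
#' @return data.frame with columns `species`, `axial`, `thickness`.
#' @export
shrinkage_factors <- function() {
  data.frame(species = c("mouse", "rat", "rabbit"),
             axial = c(0.923, 0.816, 0.858),
             thickness = c(0.925, 0.727, 0.826))
}

#' Shrinkage-correct a measured dimension
#'
#' @param x measured (post-processing) value(s), um.
#' @param species `"mouse"`, `"rat"` or `"rabbit"`.
#' @param metric `"axial"` (lateral, e.g. lesion diameter) or `"thickness"`
#'   (vertical, e.g. retinal thickness).
#' @return estimated in-vivo value(s): `x / factor`.
#' @export
shrinkage_correct <- function(x, species, metric = c("axial", "thickness")) {
  metric <- match.arg(metric)
  sf <- shrinkage_factors()
  row <- sf[sf$species == species, ]
  if (nrow(row) != 1) stop("unknown species: ", species)
  x / row[[metric]]
}

#' Radial thickness profile of an annular retina mask
#'
#' Operationalizes evenly spaced cuts through the retina: the band center is
#' taken as the centroid of the hole-filled mask, and at each sampled angle
#' the thickness is the chord length through the band along the radial ray
#' (the local normal of a circular band), measured by sub-pixel sampling of
#' the mask.
#'
#' @param retina_mask binary mask of the retinal band (annulus, possibly with
#'   a thinned sector).
#' @param pixel_size_um um per pixel.
#' @param n_angles number of sampled angles over the full circle.
#' @param r_step_px radial sampling step, px.
#' @return data.frame with `angle` (radians, in `[0, 2*pi)`), `thickness_um`
#'   (chord through the band) and `r_mid_px` (band mid radius along the ray);
#'   attributes `center_px` (the trace center) and `pixel_size_um`.
#' @export
thickness_profile <- function(retina_mask, pixel_size_um,
                              n_angles = 360, r_step_px = 0.25) {
  m <- as_mask(retina_mask)
  if (!any(m)) stop("empty retina mask")
  filled <- EBImage::fillHull(m * 1) > 0.5
  h <- nrow(m); w <- ncol(m)
  cx <- sum(rep(seq_len(w), each = h) * filled) / sum(filled)
  cy <- sum(rep(seq_len(h), times = w) * filled) / sum(filled)
  r_max <- min(cx - 1, w - cx, cy - 1, h - cy)
  rs <- seq(r_step_px, r_max, by = r_step_px)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  mnum <- m * 1
  thick <- numeric(n_angles); rmid <- rep(NA_real_, n_angles)
  for (k in seq_len(n_angles)) {
    xs <- cx + rs * cos(angles[k])
    ys <- cy + rs * sin(angles[k])
    v <- bilinear_sample(mnum, xs, ys, fill = 0) >= 0.5
    thick[k] <- sum(v) * r_step_px * pixel_size_um
    if (any(v)) rmid[k] <- (rs[which(v)[1]] + rs[rev(which(v))[1]]) / 2
  }
  out <- data.frame(angle = angles, thickness_um = thick, r_mid_px = rmid)
  attr(out, "center_px") <- c(cx, cy)
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

# circular runs of TRUE in a logical vector (indices, wraparound-merged)
circular_runs <- function(v) {
  n <- length(v)
  if (!any(v)) return(list())
  if (all(v)) return(list(seq_len(n)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(which(r$values), function(i) seq(starts[i], ends[i]))
  if (length(runs) > 1 && v[1] && v[n]) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

#' Detect the coagulation-lesion arc in a thickness profile
#'
#' The lesion is the maximal contiguous arc (wraparound-aware) where the
#' thickness falls below `threshold_frac` times a robust baseline — the
#' median of the upper half of the profile values. When two candidate arcs
#' tie in length the one with lower mean thickness wins. No arc below
#' threshold is a "no lesion" result, not an error.
#'
#' @param profile a [thickness_profile()] result.
#' @param threshold_frac lesion threshold as a fraction of baseline.
#' @param baseline optional baseline thickness override, um.
#' @return list with `found`, and when found: `arc` `(angle_lo, angle_hi)`
#'   (radians; `angle_hi` may exceed `2*pi` for wrapped arcs), `extent_rad`,
#'   `arc_length_um`, `edges` (2 x 2 matrix of um image coordinates),
#'   `n_candidates`, `baseline_um`, `mean_lesion_thickness_um`.
#' @export
detect_lesion <- function(profile, threshold_frac = 0.75, baseline = NULL) {
  th <- profile$thickness_um
  if (is.null(baseline)) {
    upper <- sort(th, decreasing = TRUE)[seq_len(max(1L, length(th) %/% 2L))]
    baseline <- stats::median(upper)
  }
  below <- th < threshold_frac * baseline
  runs <- circular_runs(below)
  if (!length(runs))
    return(list(found = FALSE, n_candidates = 0L, baseline_um = baseline))
  lens <- vapply(runs, length, 0L)
  cand <- which(lens == max(lens))
  if (length(cand) > 1) {
    mth <- vapply(cand, function(i) mean(th[runs[[i]]]), 0)
    cand <- cand[which.min(mth)]
  }
  run <- runs[[cand[1]]]
  n <- length(th)
  step <- 2 * pi / n
  a_lo <- profile$angle[run[1]] - step / 2
  extent <- length(run) * step
  a_hi <- a_lo + extent
  ctr <- attr(profile, "center_px")
  px <- attr(profile, "pixel_size_um")
  # edge radius: robust mid-radius of the thinned band over the run (the
  # boundary rays themselves straddle full and thinned band)
  r_run <- profile$r_mid_px[run]
  r_ed <- stats::median(r_run, na.rm = TRUE)
  edges <- rbind(c(ctr[1] + r_ed * cos(a_lo), ctr[2] + r_ed * sin(a_lo)),
                 c(ctr[1] + r_ed * cos(a_hi), ctr[2] + r_ed * sin(a_hi))) * px
  colnames(edges) <- c("x_um", "y_um")
  list(found = TRUE, arc = c(a_lo, a_hi), extent_rad = extent,
       arc_length_um = extent * mean(r_run, na.rm = TRUE) * px,
       edges = edges, n_candidates = length(runs), baseline_um = baseline,
       mean_lesion_thickness_um = mean(th[run]))
}

#' Shrinkage-corrected straight-line lesion diameter
#'
#' The lesion lies on a curved surface but is small, so its size is
#' approximated by the straight-line (Euclidean) distance between the two
#' edge points, then corrected with the species axial shrinkage factor.
#'
#' @param edges 2 x 2 matrix of edge coordinates in um (e.g. from
#'   [detect_lesion()]).
#' @param species `"mouse"`, `"rat"` or `"rabbit"`.
#' @return corrected diameter, um.
#' @export
lesion_diameter <- function(edges, species) {
  stopifnot(is.matrix(edges), nrow(edges) == 2)
  chord <- sqrt(sum((edges[2, ] - edges[1, ])^2))
  shrinkage_correct(chord, species, "axial")
}

#' Six-point scar and baseline thickness sampling
#'
#' Samples the retinal thickness at six points evenly distributed along the
#' detected scar (arc fractions 1/12, 3/12, ..., 11/12 of the lesion extent)
#' and at six points in the `baseline_window_um` band adjoining the lesion
#' edges — three per side when both flanks offer the full window, otherwise
#' all six on the available flank. Thickness values are corrected with the
#' species thickness shrinkage factor; the thickness ratio is the ratio of
#' the scar and baseline means (the correction cancels in the ratio).
#'
#' @param profile a [thickness_profile()] result.
#' @param lesion a [detect_lesion()] result with `found = TRUE`.
#' @param species `"mouse"`, `"rat"` or `"rabbit"`.
#' @param baseline_window_um baseline band width adjoining the scar edge, um.
#' @return object of class `biometry_record`: lesion diameter (corrected,
#'   um), six corrected scar and baseline thickness samples (um), their
#'   means, the thickness ratio, species.
#' @export
sample_thickness <- function(profile, lesion, species,
                             baseline_window_um = 600) {
  if (!isTRUE(lesion$found)) stop("no lesion detected")
  px <- attr(profile, "pixel_size_um")
  th_fun <- {
    a <- profile$angle; t_ <- profile$thickness_um
    stats::approxfun(c(a - 2 * pi, a, a + 2 * pi), rep(t_, 3))
  }
  wrap <- function(x) ((x + pi) %% (2 * pi)) - pi
  a_lo <- lesion$arc[1]; a_hi <- lesion$arc[2]
  extent <- lesion$extent_rad
  scar_ang <- a_lo + (2 * seq_len(6) - 1) / 12 * extent
  scar_raw <- th_fun(wrap(scar_ang))

  r_mid <- mean(profile$r_mid_px, na.rm = TRUE) * px
  w <- baseline_window_um / r_mid  # angular width of the baseline band
  avail <- 2 * pi - extent
  if (avail < w)
    stop("insufficient baseline band: less than ", baseline_window_um,
         " um of retina outside the lesion")
  off3 <- (2 * seq_len(3) - 1) / 6 * w
  off6 <- (2 * seq_len(6) - 1) / 12 * w
  base_ang <- if (avail >= 2 * w) c(a_lo - off3, a_hi + off3)
              else a_hi + off6
  base_raw <- th_fun(wrap(base_ang))

  scar <- shrinkage_correct(scar_raw, species, "thickness")
  base <- shrinkage_correct(base_raw, species, "thickness")
  structure(list(
    species = species,
    lesion_diameter_um = lesion_diameter(lesion$edges, species),
    lesion_chord_raw_um = sqrt(sum((lesion$edges[2, ] - lesion$edges[1, ])^2)),
    scar_thickness_um = scar, baseline_thickness_um = base,
    scar_mean_um = mean(scar), baseline_mean_um = mean(base),
    thickness_ratio = mean(scar) / mean(base),
    baseline_sides = if (avail >= 2 * w) "both" else "one"),
    class = "biometry_record")
}

#' @export
print.biometry_record <- function(x, ...) {
  cat(sprintf("biometry_record (%s):\n", x$species))
  cat(sprintf("  lesion diameter   %.1f um (shrinkage-corrected)\n",
              x$lesion_diameter_um))
  cat(sprintf("  scar thickness    %.1f um (mean of 6)\n", x$scar_mean_um))
  cat(sprintf("  baseline thickness %.1f um (mean of 6, %s side(s))\n",
              x$baseline_mean_um, x$baseline_sides))
  cat(sprintf("  thickness ratio   %.3f\n", x$thickness_ratio))
  invisible(x)
}

#' @export
as.data.frame.biometry_record <- function(x, ...) {
  data.frame(species = x$species,
             lesion_diameter_um = x$lesion_diameter_um,
             scar_mean_um = x$scar_mean_um,
             baseline_mean_um = x$baseline_mean_um,
             thickness_ratio = x$thickness_ratio)
}

#' Full biometry of one retina mask (or the widest lesion in a set)
#'
#' Runs [thickness_profile()], [detect_lesion()] and [sample_thickness()] on
#' a retina mask. Given a list of masks (serial sections), each is measured
#' and the record with the largest lesion diameter is returned — the
#' automatic analogue of selecting the section showing the widest lesion.
#'
#' @param retina_mask binary retina mask, or a list of such masks.
#' @param species `"mouse"`, `"rat"` or `"rabbit"`.
#' @param pixel_size_um um per pixel.
#' @param threshold_frac,baseline_window_um tuning; see [detect_lesion()]
#'   and [sample_thickness()].
#' @param ... passed to [thickness_profile()].
#' @return a `biometry_record` (with `slice` set when a list was given), or
#'   `NULL` if no lesion is found.
#' @export
measure_biometry <- function(retina_mask, species, pixel_size_um,
                             threshold_frac = 0.75, baseline_window_um = 600,
                             ...) {
  if (is.list(retina_mask) && !is.matrix(retina_mask)) {
    recs <- lapply(seq_along(retina_mask), function(i) {
      r <- measure_biometry(retina_mask[[i]], species, pixel_size_um,
                            threshold_frac, baseline_window_um, ...)
      if (!is.null(r)) r$slice <- i
      r
    })
    recs <- Filter(Negate(is.null), recs)
    if (!length(recs)) return(NULL)
    return(recs[[which.max(vapply(recs, function(r) r$lesion_diameter_um, 0))]])
  }
  prof <- thickness_profile(retina_mask, pixel_size_um, ...)
  les <- detect_lesion(prof, threshold_frac = threshold_frac)
  if (!isTRUE(les$found)) return(NULL)
  sample_thickness(prof, les, species, baseline_window_um)
}
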