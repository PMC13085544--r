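#' Parameters of the synthetic serial-section phantom
#'
#' The phantom is a stylized HE-stained sagittal eye section: a bright
#' background, a pale lightly-stained interior, a purple retinal band and a
#' pink scleral band forming a closed annulus, and a coagulation-lesion sector
#' in which the retina is thinned to `lesion_thinning_ratio` times its nominal
#' thickness (thinning from the inner side, as in a scar replacing the inner
#' layers). Each slice can additionally carry per-slice rigid jitter,
#' background-colored crack wedges and dark debris blobs, emulating the
#' positional changes and tissue damage introduced by histological processing.
#'
#' All physical lengths are in micrometers; the raster is `image_size` square
#' pixels at `pixel_size` um/px. Section (z) thickness follows the species:
#' 3 um for mouse and rat, 6 um for rabbit.
#'
#' @param image_size side of the square raster in pixels.
#' @param pixel_size um per pixel.
#' @param n_slices number of serial sections.
#' @param band_center_radius radius of the retinal band centerline, um.
#' @param retina_thickness nominal retinal thickness, um.
#' @param sclera_thickness scleral band thickness, um.
#' @param lesion_angular_extent angular width of the lesion sector, radians
#'   (must be < 2*pi).
#' @param lesion_thinning_ratio target scar/baseline thickness ratio, in (0,1).
#' @param lesion_center_angle direction of the lesion sector center, radians.
#' @param jitter_rotation_sd SD of per-slice rotation jitter, degrees
#'   (draws clamped at 2.5 SD).
#' @param jitter_translation_sd SD of per-slice translation jitter per axis,
#'   um (draws clamped at 2.5 SD).
#' @param crack_probability per-slice probability of a background-colored
#'   crack wedge, in \[0, 1\].
#' @param debris_density number of dark debris blobs per slice.
#' @param background_level background intensity, 8-bit (0-255).
#' @param species one of `"mouse"`, `"rat"`, `"rabbit"`; sets z thickness.
#' @param seed master seed; per-slice streams are derived from it so changing
#'   `n_slices` does not reshuffle earlier slices.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 192L,
                           pixel_size = 10,
                           n_slices = 40L,
                           band_center_radius = 460,
                           retina_thickness = 200,
                           sclera_thickness = 120,
                           lesion_angular_extent = pi / 3,
                           lesion_thinning_ratio = 0.41,
                           lesion_center_angle = pi / 2,
                           jitter_rotation_sd = 4,
                           jitter_translation_sd = 60,
                           crack_probability = 0.1,
                           debris_density = 5,
                           background_level = 245,
                           species = c("mouse", "rat", "rabbit"),
                           seed = 1L) {
  species <- match.arg(species)
  p <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
            n_slices = as.integer(n_slices),
            band_center_radius = band_center_radius,
            retina_thickness = retina_thickness,
            sclera_thickness = sclera_thickness,
            lesion_angular_extent = lesion_angular_extent,
            lesion_thinning_ratio = lesion_thinning_ratio,
            lesion_center_angle = lesion_center_angle,
            jitter_rotation_sd = jitter_rotation_sd,
            jitter_translation_sd = jitter_translation_sd,
            crack_probability = crack_probability,
            debris_density = debris_density,
            background_level = background_level,
            species = species, seed = as.integer(seed))
  if (p$retina_thickness <= 0) stop("retina_thickness must be > 0")
  if (p$lesion_thinning_ratio <= 0 || p$lesion_thinning_ratio >= 1)
    stop("lesion_thinning_ratio must be in (0, 1)")
  if (p$lesion_angular_extent >= 2 * pi)
    stop("lesion_angular_extent must be < 2*pi")
  if (p$jitter_rotation_sd < 0 || p$jitter_translation_sd < 0)
    stop("jitter SDs must be >= 0")
  if (p$crack_probability < 0 || p$crack_probability > 1)
    stop("crack_probability must be in [0, 1]")
  outer_px <- (p$band_center_radius + p$retina_thickness / 2 +
               p$sclera_thickness + 100) / p$pixel_size  # +100 um nerve stub
  margin_px <- 2.5 * p$jitter_translation_sd / p$pixel_size
  if (outer_px + margin_px >= p$image_size / 2)
    stop("band (plus jitter margin) does not fit inside the image frame")
  class(p) <- "phantom_params"
  p
}

species_z_um <- function(species) {
  switch(species, mouse = 3, rat = 3, rabbit = 6,
         stop("unknown species: ", species))
}

# HE-like palette (0-1 RGB). Tissue grays are kept in a band well separated
# from the bright background so a global bimodal threshold lands between
# tissue and background rather than inside the tissue classes.
.phantom_cols <- list(
  interior = c(215, 195, 210) / 255,
  retina   = c(160, 120, 175) / 255,
  sclera   = c(230, 160, 170) / 255,
  debris   = c(175, 135, 155) / 255  # detached stained-tissue fragments
)

# Deterministic per-slice seed derived from the master seed; arithmetic so
# streams are independent of n_slices.
slice_seed <- function(seed, i) (abs(seed) * 10007L + i * 97L) %% 2147483629L

# Band centerline radius for slice i: weak spherical taper about the stack
# midplane, z offsets from the species section thickness.
band_radius_at <- function(params, slice_index) {
  z <- species_z_um(params$species)
  d <- (slice_index - (params$n_slices + 1) / 2) * z
  f <- 1 - (d / params$band_center_radius)^2
  params$band_center_radius * sqrt(max(f, 0.25))
}

# Draw the per-slice corruption state (jitter, crack, debris) from the slice's
# own stream. Jitter draws are Normal, clamped at 2.5 SD.
draw_slice_state <- function(params, slice_index) {
  set.seed(slice_seed(params$seed, slice_index))
  rot_sd <- params$jitter_rotation_sd
  tr_sd <- params$jitter_translation_sd
  clamp <- function(x, b) pmin(pmax(x, -b), b)
  angle_deg <- if (rot_sd > 0) clamp(stats::rnorm(1, 0, rot_sd), 2.5 * rot_sd) else 0
  t_um <- if (tr_sd > 0) clamp(stats::rnorm(2, 0, tr_sd), 2.5 * tr_sd) else c(0, 0)
  # a damage event is a background-colored crack wedge plus an overlap fold:
  # an arc of the band where doubled-over tissue stains much darker. The
  # fold changes intensities only, not the silhouette, so binarized masks
  # are immune to it while raw-intensity registration sees a strong feature.
  crack <- NULL
  fold <- NULL
  if (stats::runif(1) < params$crack_probability) {
    crack <- list(angle = stats::runif(1, 0, 2 * pi),
                  width = stats::runif(1, 5, 20) * pi / 180)
    fold <- list(angle = stats::runif(1, 0, 2 * pi),
                 width = stats::runif(1, 20, 60) * pi / 180)
  }
  # debris: mostly small stained specks anywhere in the frame; every fifth
  # blob is a large detached tissue fragment that settles in the open
  # background away from the section (as floated-off shreds do)
  debris <- NULL
  n_deb <- round(params$debris_density)
  if (n_deb > 0) {
    n_frag <- n_deb %/% 5L
    n_small <- n_deb - n_frag
    debris <- data.frame(
      x = stats::runif(n_small, 1, params$image_size),
      y = stats::runif(n_small, 1, params$image_size),
      r = stats::runif(n_small, 1.5, 4))
    if (n_frag > 0) {
      outer_px <- (params$band_center_radius + params$retina_thickness / 2 +
                   params$sclera_thickness + 100) / params$pixel_size
      ecx <- (params$image_size + 1) / 2 + t_um[1] / params$pixel_size
      ecy <- (params$image_size + 1) / 2 + t_um[2] / params$pixel_size
      for (k in seq_len(n_frag)) {
        r <- stats::runif(1, 8, 15)
        for (try in 1:50) {
          x <- stats::runif(1, 1, params$image_size)
          y <- stats::runif(1, 1, params$image_size)
          if (sqrt((x - ecx)^2 + (y - ecy)^2) > outer_px + r + 4) break
        }
        debris <- rbind(debris, data.frame(x = x, y = y, r = r))
      }
    }
  }
  list(angle = angle_deg * pi / 180, t_px = t_um / params$pixel_size,
       crack = crack, fold = fold, debris = debris)
}

# Pure geometric renderer. The rigid perturbation is applied analytically:
# the band is drawn about the displaced center and the lesion direction is
# rotated, so the stored transform is exact (no resampling of the phantom).
render_slice <- function(params, slice_index, state) {
  n <- params$image_size
  c0 <- image_center(c(n, n))
  cx <- c0[1] + state$t_px[1]
  cy <- c0[2] + state$t_px[2]
  px <- params$pixel_size
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # x = column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # y = row index
  dx <- (xs - cx) * px
  dy <- (ys - cy) * px
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  rb <- band_radius_at(params, slice_index)
  Tret <- params$retina_thickness
  rin <- rb - Tret / 2
  rout <- rb + Tret / 2
  rsc <- rout + params$sclera_thickness
  alpha <- params$lesion_center_angle + state$angle
  dphi <- atan2(sin(phi - alpha), cos(phi - alpha))
  in_sector <- abs(dphi) <= params$lesion_angular_extent / 2
  rin_eff <- ifelse(in_sector, rout - params$lesion_thinning_ratio * Tret, rin)

  # optic-nerve stub: a 20-degree, 100-um scleral protrusion opposite the
  # lesion. It breaks the rotational symmetry of the silhouette (eye sections
  # are not circular), so rotation is identifiable even from the binary mask,
  # without touching the retinal band that biometry measures.
  nerve_ang <- params$lesion_center_angle + pi + state$angle
  dpn <- atan2(sin(phi - nerve_ang), cos(phi - nerve_ang))
  nerve <- abs(dpn) <= (10 * pi / 180) & r > rsc & r <= rsc + 100

  fg <- r <= rsc | nerve
  retina <- r >= rin_eff & r <= rout
  sclera <- (r > rout & r <= rsc) | nerve
  interior <- r < rin_eff
  lesion <- retina & in_sector

  bg <- params$background_level / 255
  rgb <- array(bg, c(n, n, 3))
  # mild multiplicative texture locked to the tissue frame (rotates/translates
  # with the band) so noise-free stacks stay slice-identical
  tex <- 1 + 0.06 * sin(8 * (phi - state$angle)) * cos(2 * pi * r / 120)
  for (ch in 1:3) {
    m <- rgb[, , ch]
    m[interior] <- .phantom_cols$interior[ch]
    m[retina] <- (.phantom_cols$retina[ch] * tex)[retina]
    m[sclera] <- (.phantom_cols$sclera[ch] * tex)[sclera]
    rgb[, , ch] <- m
  }
  # overlap fold: doubled tissue darkens an arc of the band (stored frame);
  # intensities only, the masks are untouched
  if (!is.null(state$fold)) {
    dpf <- atan2(sin(phi - state$fold$angle), cos(phi - state$fold$angle))
    fold_px <- abs(dpf) <= state$fold$width / 2 & r >= rin_eff & r <= rsc
    for (ch in 1:3) {
      m <- rgb[, , ch]; m[fold_px] <- 0.55 * m[fold_px]; rgb[, , ch] <- m
    }
  }
  # crack: background-colored wedge through the whole section, in the stored
  # (post-jitter) frame — processing damage does not rotate with the tissue
  if (!is.null(state$crack)) {
    dpc <- atan2(sin(phi - state$crack$angle), cos(phi - state$crack$angle))
    wedge <- abs(dpc) <= state$crack$width / 2
    for (ch in 1:3) { m <- rgb[, , ch]; m[wedge] <- bg; rgb[, , ch] <- m }
    fg <- fg & !wedge
    retina <- retina & !wedge
    lesion <- lesion & !wedge
  }
  if (!is.null(state$debris)) {
    for (k in seq_len(nrow(state$debris))) {
      blob <- (xs - state$debris$x[k])^2 + (ys - state$debris$y[k])^2 <=
        state$debris$r[k]^2
      for (ch in 1:3) {
        m <- rgb[, , ch]; m[blob] <- .phantom_cols$debris[ch]; rgb[, , ch] <- m
      }
    }
  }
  rgb <- quantize8(rgb)
  transform <- rigid2d(state$angle, state$t_px[1], state$t_px[2], center = c0)
  # lesion arc endpoints at the mid-radius of the thinned band, um image
  # coordinates (the radius a chord measured across the scar runs along)
  edge_ang <- alpha + c(-0.5, 0.5) * params$lesion_angular_extent
  r_edge <- rout - params$lesion_thinning_ratio * Tret / 2
  endpoints <- cbind(x_um = cx * px + r_edge * cos(edge_ang),
                     y_um = cy * px + r_edge * sin(edge_ang))
  list(rgb = rgb,
       masks = list(foreground = fg | retina | sclera | interior,
                    retina = retina, lesion = lesion),
       transform = transform, lesion_endpoints = endpoints,
       crack = state$crack)
}

#' Generate one synthetic slice
#'
#' Renders slice `slice_index` of the phantom, including that slice's own
#' seeded rigid jitter, crack and debris state. The rigid perturbation is
#' applied analytically (the band is drawn displaced and rotated), so the
#' returned transform — which maps the unperturbed slice onto the stored one,
#' about the image center — is exact.
#'
#' @param params a [phantom_params()] object.
#' @param slice_index slice number, 1-based, `<= n_slices`.
#' @return list with `rgb` (h x w x 3 array in \[0,1\], 8-bit quantized),
#'   `masks` (logical `foreground`, `retina`, `lesion`), `transform`
#'   (a [rigid2d()]), and `lesion_endpoints` (2 x 2, um).
#' @export
generate_slice <- function(params, slice_index) {
  stopifnot(inherits(params, "phantom_params"),
            slice_index >= 1, slice_index <= params$n_slices)
  render_slice(params, slice_index, draw_slice_state(params, slice_index))
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' @param params a [phantom_params()] object.
#' @return list with `stack` (a `section_stack`: slices, calibration, species)
#'   and `truth` (per-slice applied [rigid2d()] transforms, per-slice masks,
#'   lesion arc endpoints, the true thinning ratio, crack placements).
#' @export
generate_stack <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  slices <- vector("list", params$n_slices)
  transforms <- vector("list", params$n_slices)
  masks <- vector("list", params$n_slices)
  endpoints <- vector("list", params$n_slices)
  cracks <- vector("list", params$n_slices)
  for (i in seq_len(params$n_slices)) {
    s <- generate_slice(params, i)
    slices[[i]] <- s$rgb
    transforms[[i]] <- s$transform
    masks[[i]] <- s$masks
    endpoints[[i]] <- s$lesion_endpoints
    cracks[i] <- list(s$crack)  # keep NULL placeholders for crack-free slices
  }
  stack <- section_stack(slices, pixel_size_um = params$pixel_size,
                         z_um = species_z_um(params$species),
                         species = params$species)
  truth <- list(transforms = transforms, masks = masks,
                lesion_endpoints = endpoints,
                thinning_ratio = params$lesion_thinning_ratio,
                cracks = cracks, params = params)
  list(stack = stack, truth = truth)
}

#' Ordered serial-section stack with physical calibration
#'
#' @param slices list of h x w x 3 arrays (or matrices) in \[0, 1\].
#' @param pixel_size_um lateral calibration, um per pixel.
#' @param z_um section thickness, um.
#' @param species species tag (free text; presets use mouse/rat/rabbit).
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(slices, pixel_size_um, z_um, species = "mouse") {
  stopifnot(is.list(slices), length(slices) >= 1,
            pixel_size_um > 0, z_um > 0)
  d1 <- dim(slices[[1]])
  for (s in slices) stopifnot(identical(dim(s)[1:2], d1[1:2]))
  structure(list(slices = slices, pixel_size_um = pixel_size_um,
                 z_um = z_um, species = species),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("section_stack: %d slices of %d x %d px, %.3g um/px, z %.3g um (%s)\n",
              length(x$slices), d[1], d[2], x$pixel_size_um, x$z_um, x$species))
  invisible(x)
}

#' @export
length.section_stack <- function(x) length(x$slices)

#' Simulate a per-animal cohort from group summaries
#'
#' Draws `n` animal endpoint values per group from Normal(mean, sd), seeded,
#' returning a tidy long table. Used to emulate the sampling structure behind
#' summary tables reported as mean +/- SD with group sizes.
#'
#' @param spec data.frame with columns `species`, `treatment`, `endpoint`,
#'   `mean`, `sd`, `n` (one row per group).
#' @param seed integer seed.
#' @return data.frame with columns `species`, `treatment`, `endpoint`,
#'   `animal_id`, `value`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  need <- c("species", "treatment", "endpoint", "mean", "sd", "n")
  stopifnot(is.data.frame(spec), all(need %in% names(spec)))
  if (any(spec$sd < 0)) stop("sd must be >= 0")
  if (any(spec$n < 2)) stop("each group needs n >= 2")
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    v <- stats::rnorm(spec$n[i], spec$mean[i], spec$sd[i])
    data.frame(species = spec$species[i], treatment = spec$treatment[i],
               endpoint = spec$endpoint[i],
               animal_id = seq_len(spec$n[i]), value = v)
  }))
  rownames(out) <- NULL
  out
}
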