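#' Assemble registered slices into a calibrated 3D volume
#'
#' Stacks the slices of a (registered) [section_stack()] in index order into a
#' `(z, y, x, channel)` intensity array with physical voxel calibration: the
#' lateral voxel size from the stack's pixel size and the axial size from the
#' section thickness (3 um mouse/rat presets, 6 um rabbit).
#'
#' @param stack a [section_stack()] or a [run_strategy()] result.
#' @param masks optional per-slice masks; when given, background voxels
#'   (outside the mask) are set to `fill`.
#' @param fill background fill intensity in \[0, 1\] (used with `masks`).
#' @return object of class `volume_model`: list with `data` (4D array),
#'   `voxel_um` `(z, y, x)`, `species`, `strategy`.
#' @export
assemble_volume <- function(stack, masks = NULL, fill = 1) {
  strategy <- NA_character_
  if (inherits(stack, "strategy_run")) {
    strategy <- stack$strategy
    stack <- stack$stack
  }
  stopifnot(inherits(stack, "section_stack"))
  n <- length(stack)
  d <- dim(stack$slices[[1]])
  nch <- if (length(d) == 3L) d[3] else 1L
  vol <- array(0, c(n, d[1], d[2], nch))
  for (i in seq_len(n)) {
    s <- stack$slices[[i]]
    if (is.matrix(s)) s <- array(s, c(d[1], d[2], 1L))
    if (!is.null(masks)) {
      m <- as_mask(masks[[i]])
      for (ch in seq_len(nch)) {
        p <- s[, , ch]; p[!m] <- fill; s[, , ch] <- p
      }
    }
    vol[i, , , ] <- s
  }
  structure(list(data = vol,
                 voxel_um = c(z = stack$z_um, y = stack$pixel_size_um,
                              x = stack$pixel_size_um),
                 species = stack$species, strategy = strategy),
            class = "volume_model")
}

#' @export
print.volume_model <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_model: %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um, depth %.4g um (%s)\n",
              d[1], d[2], d[3], x$voxel_um[1], x$voxel_um[2], x$voxel_um[3],
              d[1] * x$voxel_um[1], x$species))
  invisible(x)
}

#' Extract an orthogonal sectional view from a volume
#'
#' `axial` returns slice plane `index` (a registered slice); `sagittal` fixes
#' the x (column) coordinate and returns a `(z, y)` image; `coronal` fixes
#' the y (row) coordinate and returns a `(z, x)` image. The attribute
#' `aspect` gives the anisotropic display stretch `z voxel / xy voxel` for
#' the non-axial planes.
#'
#' @param volume a [assemble_volume()] result.
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param index plane index, within bounds.
#' @return raster (matrix for single-channel, h x w x c array otherwise) with
#'   an `aspect` attribute.
#' @export
orthogonal_section <- function(volume, plane = c("axial", "sagittal", "coronal"),
                               index) {
  plane <- match.arg(plane)
  stopifnot(inherits(volume, "volume_model"))
  d <- dim(volume$data)
  bound <- switch(plane, axial = d[1], coronal = d[2], sagittal = d[3])
  if (index < 1 || index > bound)
    stop("index out of bounds for plane '", plane, "'")
  out <- switch(plane,
    axial = volume$data[index, , , , drop = FALSE],
    coronal = volume$data[, index, , , drop = FALSE],
    sagittal = volume$data[, , index, , drop = FALSE])
  out <- array(out, dim(out)[dim(out) > 1 | seq_along(dim(out)) == 4])
  dn <- dim(out)
  if (length(dn) == 3L && dn[3] == 1L) out <- out[, , 1]
  attr(out, "aspect") <- if (plane == "axial") 1
                         else unname(volume$voxel_um["z"] / volume$voxel_um["x"])
  out
}

#' Write a volume as a multi-page 8-bit TIFF
#'
#' One page per z slice, no compression. The physical calibration is written
#' to a JSON sidecar (`<path>.json`) because baseline TIFF tags cannot carry
#' the anisotropic z spacing. Volumes written from 8-bit-quantized slices
#' re-import bit-exactly with [read_volume_tiff()].
#'
#' @param volume a [assemble_volume()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "volume_model"))
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[1]), function(i) {
    s <- array(volume$data[i, , , ], d[2:4])
    if (d[4] == 1L) s[, , 1] else s
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(voxel_um = as.list(volume$voxel_um),
                            species = volume$species,
                            strategy = volume$strategy),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' @param path TIFF file written by [write_volume_tiff()].
#' @param pixel_size_um,z_um,species calibration to attach (TIFF resolution
#'   tags are not trusted for round trips).
#' @return a `volume_model`.
#' @export
read_volume_tiff <- function(path, pixel_size_um, z_um, species = "mouse") {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  nch <- if (length(d) == 3L) d[3] else 1L
  vol <- array(0, c(length(pages), d[1], d[2], nch))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (is.matrix(p)) p <- array(p, c(d[1], d[2], 1L))
    vol[i, , , ] <- p
  }
  structure(list(data = vol,
                 voxel_um = c(z = z_um, y = pixel_size_um, x = pixel_size_um),
                 species = species, strategy = NA_character_),
            class = "volume_model")
}
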