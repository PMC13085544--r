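# Disk formats: numbered 8-bit PNG slices (slice_0000.png ...), 0/255 mask
# PNGs, transforms and ground truth as JSON, cohorts as CSV.

#' Write a section stack as numbered PNG slices
#'
#' Writes `slice_0000.png`, `slice_0001.png`, ... plus a `stack.json` sidecar
#' carrying the physical calibration (um/px, section thickness, species).
#'
#' @param stack a [section_stack()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "section_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$slices))
    png::writePNG(stack$slices[[i]],
                  file.path(dir, sprintf("slice_%04d.png", i - 1L)))
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, z_um = stack$z_um,
         species = stack$species, n_slices = length(stack$slices)),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a section stack written by [write_stack()]
#'
#' @param dir directory holding `slice_*.png` and `stack.json`.
#' @return a [section_stack()].
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"))
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no slice_*.png files in ", dir)
  slices <- lapply(files, png::readPNG)
  section_stack(slices, pixel_size_um = meta$pixel_size_um,
                z_um = meta$z_um, species = meta$species)
}

#' Write a binary mask as a 0/255 PNG
#' @param mask a `foreground_mask` or logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a logical matrix
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (!is.matrix(m)) m <- to_gray(m)
  m > 0.5
}

#' Serialize per-slice rigid transforms to JSON
#'
#' One record per slice: `{slice, angle_deg, tx_px, ty_px, center_px,
#' strategy}`; rotation center is stored explicitly so the convention is
#' unambiguous.
#'
#' @param transforms list of [rigid2d()].
#' @param path output JSON path.
#' @param strategy strategy label stored with each record.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path, strategy = NA_character_) {
  recs <- lapply(seq_along(transforms), function(i) {
    t <- transforms[[i]]
    list(slice = i, angle_deg = t$angle * 180 / pi,
         tx_px = t$tx, ty_px = t$ty, center_px = t$center,
         strategy = strategy)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transforms written by [write_transforms()]
#' @param path JSON path.
#' @return list of [rigid2d()].
#' @export
read_transforms <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r)
    rigid2d(r$angle_deg * pi / 180, r$tx_px, r$ty_px,
            center = unlist(r$center_px)))
}
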