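## Binary raster masks (nucleus / foci) and the two masking methods
## applied to orte tables: (a) a nucleus mask discarding events outside
## the nucleus, (b) a focus mask keeping only events inside damage-focus
## regions.  Pixel membership is half-open: an event at (x, y) belongs to
## pixel (floor(x/p), floor(y/p)), so boundary points fall in exactly one
## pixel.

#' Construct a binary mask
#'
#' @param inside logical or 0/1 matrix; rows index y (downward), columns
#'   index x
#' @param pixel_size_nm pixel edge length in nm
#' @param origin_x_nm,origin_y_nm nm coordinate of the top-left corner of
#'   pixel (1, 1)
#' @param kind `"nucleus"` or `"foci"`
#' @return a `binary_mask` object
#' @export
binary_mask <- function(inside, pixel_size_nm,
                        origin_x_nm = 0, origin_y_nm = 0,
                        kind = c("nucleus", "foci")) {
  kind <- match.arg(kind)
  check_num(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  if (!is.matrix(inside)) stopf("inside must be a matrix")
  m <- matrix(as.logical(inside != 0), nrow = nrow(inside))
  structure(list(inside = m, pixel_size_nm = as.numeric(pixel_size_nm),
                 origin_x_nm = as.numeric(origin_x_nm),
                 origin_y_nm = as.numeric(origin_y_nm),
                 kind = kind),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary mask (%s): %d x %d px @ %g nm, %d inside (%.1f%%)\n",
              x$kind, nrow(x$inside), ncol(x$inside), x$pixel_size_nm,
              sum(x$inside), 100 * mean(x$inside)))
  invisible(x)
}

#' Mask area in um^2
#'
#' Number of inside pixels times the pixel area, converted from nm^2.
#'
#' @param mask a [binary_mask()]
#' @return area in um^2
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$inside) * mask$pixel_size_nm^2 / 1e6
}

#' Membership of points in a mask
#'
#' @param mask a [binary_mask()]
#' @param x,y coordinates in nm
#' @return logical vector; points off the mask grid are outside
#' @export
mask_contains <- function(mask, x, y) {
  px <- floor((x - mask$origin_x_nm) / mask$pixel_size_nm) + 1L
  py <- floor((y - mask$origin_y_nm) / mask$pixel_size_nm) + 1L
  ok <- px >= 1L & px <= ncol(mask$inside) &
        py >= 1L & py <= nrow(mask$inside)
  res <- logical(length(x))
  res[ok] <- mask$inside[cbind(py[ok], px[ok])]
  res
}

#' Apply a binary mask to an orte matrix
#'
#' Keeps exactly the events whose (x, y) falls inside the mask; row order
#' is preserved.  Events falling off the mask grid count as outside.
#'
#' @param orte an [orte_matrix()]
#' @param mask a [binary_mask()]
#' @param verbose log the number of excluded events
#' @return the filtered [orte_matrix()]
#' @export
apply_mask <- function(orte, mask, verbose = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  keep <- mask_contains(mask, orte$x_nm, orte$y_nm)
  if (verbose)
    message(sprintf("apply_mask(%s): kept %d / %d events",
                    mask$kind, sum(keep), length(keep)))
  out <- orte[keep, , drop = FALSE]
  attr(out, "channel") <- attr(orte, "channel")
  attr(out, "source") <- attr(orte, "source")
  class(out) <- class(orte)
  out
}

#' Write a mask as TIFF (0/255) with a JSON sidecar
#'
#' @param mask a [binary_mask()]
#' @param path TIFF path; the sidecar is written at `<path>.json`
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  write_tiff(matrix(ifelse(mask$inside, 255L, 0L),
                    nrow = nrow(mask$inside)), path, bits = 8L)
  jsonlite::write_json(list(pixel_size_nm = mask$pixel_size_nm,
                            origin_x_nm = mask$origin_x_nm,
                            origin_y_nm = mask$origin_y_nm,
                            kind = mask$kind),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`)
#' @return a [binary_mask()]
#' @export
read_mask <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stopf("mask sidecar not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- read_tiff(path)
  binary_mask(pages[[1L]] != 0, meta$pixel_size_nm,
              meta$origin_x_nm, meta$origin_y_nm, kind = meta$kind)
}
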