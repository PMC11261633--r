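#' Rectangular region of interest
#'
#' A rotated rectangle in physical (um) coordinates of the projection plane,
#' used for AIS intensity profiles: the long axis is the profile axis. The
#' convention for profile orientation is that the positive long-axis
#' direction points towards the calyx (proximal), so that distal positions
#' come out negative.
#'
#' @param center length-2 numeric, `(x, y)` centre in um
#' @param length long-axis extent in um (> 0); e.g. 37 for larvae, 47 for
#'   adults
#' @param width short-axis extent in um (> 0), approximately the peduncle
#'   width
#' @param angle rotation of the long axis in degrees counter-clockwise from
#'   the image x-axis
#' @param plane projection plane (only `"xy"` is supported)
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(center, length, width, angle = 0, plane = "xy") {
  center <- as.numeric(center)
  if (base::length(center) != 2L || any(!is.finite(center)))
    stop("center must be two finite numbers (x, y) in um")
  if (!is.finite(length) || length <= 0) stop("length must be > 0")
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  if (!identical(plane, "xy")) stop("only the xy projection plane is supported")
  structure(list(center = c(x = center[1L], y = center[2L]),
                 length = as.numeric(length), width = as.numeric(width),
                 angle = as.numeric(angle), plane = plane),
            class = "rect_roi")
}

#' Polygonal region of interest
#'
#' A simple polygon in physical (um) coordinates, applied as a prism across
#' all z-slices (the compartment ROIs of the calyx and the dorsal/alpha
#' lobe are drawn once on the stack, not per slice).
#'
#' @param vertices numeric matrix with columns `(x, y)` in um, at least 3
#'   rows, describing a non-degenerate simple polygon.
#' @return An object of class `poly_roi`.
#' @export
poly_roi <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 (x, y) matrix")
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  if (abs(polygon_area(vertices)) < 1e-12)
    stop("degenerate polygon (zero area)")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices), class = "poly_roi")
}

polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  i2 <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Read / write an ROI file
#'
#' ROIs are stored one per file as a small JSON object with an explicit
#' units field, avoiding binary ROI dialects.
#'
#' @param path file path
#' @return For `read_roi`, a [rect_roi()] or [poly_roi()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("ROI parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(obj$type)) stop("ROI parse error in ", path, ": missing 'type'")
  if (!identical(obj$units, "um"))
    stop("ROI parse error in ", path, ": units must be 'um'")
  switch(obj$type,
    rect = rect_roi(obj$center, obj$length, obj$width,
                    if (is.null(obj$angle)) 0 else obj$angle),
    polygon = poly_roi(matrix(unlist(obj$vertices), ncol = 2L, byrow = FALSE)),
    stop("ROI parse error in ", path, ": unknown type '", obj$type, "'"))
}

#' @rdname read_roi
#' @param roi a [rect_roi()] or [poly_roi()]
#' @export
write_roi <- function(roi, path) {
  obj <- if (inherits(roi, "rect_roi")) {
    list(type = "rect", units = "um", center = unname(roi$center),
         length = roi$length, width = roi$width, angle = roi$angle)
  } else if (inherits(roi, "poly_roi")) {
    list(type = "polygon", units = "um",
         vertices = unname(roi$vertices))
  } else stop("roi must be a rect_roi or poly_roi")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# Logical [y, x] mask of pixel centres inside the ROI, for a grid with
# pixel size (y, x) in um. Pixel (iy, ix) has centre ((ix-0.5)*dx, (iy-0.5)*dy).
roi_mask <- function(roi, ny, nx, pixel_size) {
  dy <- pixel_size[1L]; dx <- pixel_size[2L]
  cx <- (seq_len(nx) - 0.5) * dx
  cy <- (seq_len(ny) - 0.5) * dy
  pts <- cbind(rep(cx, each = ny), rep(cy, times = nx))
  verts <- if (inherits(roi, "poly_roi")) roi$vertices else rect_vertices(roi)
  inside <- mgcv::in.out(rbind(verts, verts[1L, ]), pts)
  matrix(inside, ny, nx)
}

rect_vertices <- function(roi) {
  a <- roi$angle * pi / 180
  u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
  hl <- roi$length / 2; hw <- roi$width / 2
  c0 <- roi$center
  rbind(c0 + u * hl + v * hw, c0 - u * hl + v * hw,
        c0 - u * hl - v * hw, c0 + u * hl - v * hw)
}
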