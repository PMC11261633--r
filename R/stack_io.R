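#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered channel-major (all z-slices of channel 0, then channel
#' 1, ...). Samples are stored as 32-bit IEEE floats, so intensities --
#' including `NA`/NaN introduced by thresholding -- round-trip bit-exactly.
#' The voxel size, shape, and channel names are recorded as a JSON object in
#' the TIFF ImageDescription tag.
#'
#' @param stack an [image_stack()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  meta <- list(format = "aismito-stack", version = 1L,
               voxel_size_um = unname(stack$voxel_size),
               shape_zyx = c(d[3L], d[1L], d[2L]),
               n_channels = d[4L],
               channel_names = stack$channel_names)
  pages <- vector("list", d[3L] * d[4L])
  k <- 1L
  for (ci in seq_len(d[4L])) for (zi in seq_len(d[3L])) {
    pages[[k]] <- stack$voxels[, , zi, ci]
    k <- k + 1L
  }
  write_float_tiff(pages, path,
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Stacks written by [write_stack()] are reassembled from the JSON metadata
#' in the ImageDescription tag. Plain TIFFs from other tools are promoted to
#' a single-channel stack (a 2D image becomes a 1-channel, 1-slice stack),
#' in which case the voxel size must be supplied via `voxel_size` because it
#' cannot be recovered from the file.
#'
#' @param path TIFF file path
#' @param voxel_size optional `(z, y, x)` voxel size in um, overriding or
#'   supplying file metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1L]], "description")
  meta <- NULL
  if (!is.null(desc))
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop("format error: multi-sample TIFF pages are not supported: ", path)
      dim(p) <- dim(p)[1:2]
    }
    pages[[i]] <- p
  }
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("format error: ragged TIFF (pages differ in size): ", path)
  ny <- dims[1L, 1L]; nx <- dims[2L, 1L]

  if (!is.null(meta) && identical(meta$format, "aismito-stack")) {
    nz <- meta$shape_zyx[1L]; nc <- meta$n_channels
    if (length(pages) != nz * nc)
      stop("format error: page count does not match metadata: ", path)
    vs <- if (is.null(voxel_size)) meta$voxel_size_um else voxel_size
    a <- array(NA_real_, c(ny, nx, nz, nc))
    k <- 1L
    for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
      a[, , zi, ci] <- pages[[k]]
      k <- k + 1L
    }
    a[is.nan(a)] <- NA_real_  # thresholded voxels come back as NaN
    return(image_stack(a, vs, meta$channel_names))
  }
  # foreign TIFF: promote pages to z-slices of a single channel
  if (is.null(voxel_size))
    stop("no voxel size metadata in ", path,
         "; supply voxel_size explicitly (e.g. from the analysis config)")
  a <- array(NA_real_, c(ny, nx, length(pages), 1L))
  for (zi in seq_along(pages)) a[, , zi, 1L] <- pages[[zi]]
  image_stack(a, voxel_size)
}

#' Write a measurement table as CSV
#'
#' Columns keep the order of the input data frame; missing values are
#' written as empty fields; row names are dropped. The written form is
#' deterministic so that pipeline reruns are byte-comparable.
#'
#' @param rows a data frame
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("rows must be a data.frame")
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
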