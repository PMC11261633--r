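#' Multi-channel 3D image stack
#'
#' The container consumed by every analysis stage: a channel x z x y x x
#' voxel grid with a physical voxel size. Internally voxels are stored as a
#' 4D array indexed `[y, x, z, channel]` (matching how TIFF pages are read),
#' with intensities in arbitrary real units. Missing values (`NA`) are only
#' ever introduced by thresholding.
#'
#' @param voxels numeric array. A 2D `[y, x]` matrix or 3D `[y, x, z]` array
#'   is promoted to a single-channel stack; otherwise a 4D `[y, x, z, channel]`
#'   array.
#' @param voxel_size numeric length-3, physical voxel size in micrometres in
#'   `(z, y, x)` order. All components must be positive.
#' @param channel_names optional character vector, one name per channel.
#'   Defaults to `"ch0"`, `"ch1"`, ... (channel 0 is conventionally the
#'   mitochondrial marker, channel 1 the AIS/structural marker).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, channel_names = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 2D, 3D, or 4D numeric array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (z, y, x) in um")
  names(voxel_size) <- c("z", "y", "x")
  nc <- dim(voxels)[4L]
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nc) - 1L)
  if (length(channel_names) != nc)
    stop("channel_names must have one entry per channel")
  structure(
    list(voxels = voxels, voxel_size = voxel_size,
         channel_names = as.character(channel_names)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d x %d x %d (z,y,x) voxels at (%.3g, %.3g, %.3g) um\n",
    d[4L], paste(x$channel_names, collapse = ", "),
    d[3L], d[1L], d[2L], x$voxel_size["z"], x$voxel_size["y"],
    x$voxel_size["x"]))
  invisible(x)
}

#' Number of channels / z-slices in a stack
#' @param stack an `image_stack`
#' @return integer count
#' @export
n_channels <- function(stack) dim(stack$voxels)[4L]

#' @rdname n_channels
#' @export
n_slices <- function(stack) dim(stack$voxels)[3L]

#' Extract one channel as a 3D array
#'
#' @param stack an `image_stack`
#' @param channel 0-based channel index (channel 0 = first channel), or a
#'   channel name.
#' @return 3D numeric array `[y, x, z]` carrying a `voxel_size` attribute.
#' @export
stack_channel <- function(stack, channel = 0L) {
  i <- resolve_channel(stack, channel)
  a <- stack$voxels[, , , i, drop = FALSE]
  dim(a) <- dim(a)[1:3]
  attr(a, "voxel_size") <- stack$voxel_size
  a
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop("unknown channel name: ", channel)
    return(i)
  }
  i <- as.integer(channel) + 1L
  if (i < 1L || i > n_channels(stack))
    stop("channel index out of range: ", channel)
  i
}
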