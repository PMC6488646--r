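#' Read a multi-page TIFF voxel stack
#'
#' Reads a z-major multi-page TIFF into a (z, y, x) intensity array. Requires
#' the `tiff` package.
#'
#' @param path Path to the TIFF file.
#' @param voxel_size Voxel pitch (x, y, z), micrometres. Default
#'   `c(0.645, 0.645, 1)`.
#' @return A 3D array (z, y, x) with a `voxel_size` attribute.
#' @export
read_voxel_stack <- function(path, voxel_size = c(0.645, 0.645, 1)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required to read TIFF stacks", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(length(pages), dim(pages[[1L]])[1L],
                            dim(pages[[1L]])[2L]))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]   # drop extra channels
    stack[i, , ] <- pg
  }
  attr(stack, "voxel_size") <- voxel_size
  stack
}

#' Write a voxel stack as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` (TIFF float convention); the scale
#' factor is returned invisibly so round trips can be undone.
#'
#' @param stack 3D array (z, y, x).
#' @param path Output path.
#' @return Invisibly, the scale factor the intensities were divided by.
#' @export
write_voxel_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required to write TIFF stacks", call. = FALSE)
  }
  stopifnot(length(dim(stack)) == 3L)
  scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1L]),
                  function(i) pmax(stack[i, , ] / scale, 0))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}
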