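#' Construct an image stack
#'
#' The raw input to tracking: a 3-D array of grey intensities indexed
#' (row, col, slice), with slice 1 the top of the soil column when
#' `slice_axis_down` is `TRUE`.  Voxels must be isotropic; a single edge
#' length in micrometres carries all physical scaling.
#'
#' @param voxels 3-D numeric array (row, col, slice), finite, non-negative.
#' @param voxel_size_um voxel edge length in micrometres (> 0).
#' @param slice_axis_down `TRUE` if increasing slice index means deeper.
#' @return an `image_stack`.
#' @export
#' @examples
#' s <- image_stack(array(0L, c(4, 4, 2)), voxel_size_um = 100)
#' dim(s$voxels)
image_stack <- function(voxels, voxel_size_um, slice_axis_down = TRUE) {
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop("voxels must be a 3-D array with all dimensions >= 1")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("intensities must be finite and non-negative")
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("voxel_size_um must be a positive scalar (anisotropic voxels are not supported)")
  }
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 slice_axis_down = isTRUE(slice_axis_down)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d pixels, %d slices, %.4g um/voxel\n",
              d[1L], d[2L], d[3L], x$voxel_size_um))
  invisible(x)
}

#' Read an image stack from disk
#'
#' Accepts either a directory of equally-sized single-slice images (TIFF or
#' PNG; slice order is lexicographic filename order) or a single multipage
#' TIFF.  16-bit data are kept as stored, without rescaling.
#'
#' @param path directory of slices or a multipage TIFF file.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param slice_axis_down orientation flag stored on the result.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, voxel_size_um, slice_axis_down = TRUE) {
  if (!file.exists(path)) stop("no such path: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (!length(files)) stop("no TIFF/PNG slices found in ", path)
    slices <- unlist(lapply(files, read_slice_file), recursive = FALSE)
  } else {
    slices <- read_tiff_pages(path)
  }
  if (!length(slices)) stop("zero slices in ", path)
  nr <- nrow(slices[[1L]]); nc <- ncol(slices[[1L]])
  ok <- vapply(slices, function(m) nrow(m) == nr && ncol(m) == nc, logical(1))
  if (!all(ok)) stop("inconsistent slice dimensions")
  vox <- array(0L, c(nr, nc, length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]
  image_stack(vox, voxel_size_um, slice_axis_down)
}

read_slice_file <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    a <- png::readPNG(f, info = TRUE)
    info <- attr(a, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(a)) == 3L) a <- a[, , 1L]  # greyscale stored with channels
    # readPNG normalises to [0, 1]; restore the stored integer scale
    list(matrix(as.integer(round(a * (2^depth - 1))), nrow(a), ncol(a)))
  } else {
    read_tiff_pages(f)
  }
}

#' Write an image stack
#'
#' Writes a multipage greyscale TIFF (8-bit if all intensities fit, else
#' 16-bit).  If `path` is an existing directory, one TIFF per slice is
#' written instead (`slice_0001.tif`, ...), in slice order.
#'
#' @param stack an `image_stack`.
#' @param path output file or existing directory.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  bits <- if (max(stack$voxels) > 255) 16L else 8L
  slices <- lapply(seq_len(d[3L]), function(i) {
    matrix(as.integer(round(stack$voxels[, , i])), d[1L], d[2L])
  })
  if (dir.exists(path)) {
    for (i in seq_along(slices)) {
      write_tiff_pages(slices[i], file.path(path, sprintf("slice_%04d.tif", i)),
                       bits = bits)
    }
  } else {
    write_tiff_pages(slices, path, bits = bits)
  }
  invisible(path)
}
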