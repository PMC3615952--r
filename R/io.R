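# On-disk artifacts: segmentation directories, ascii PLY meshes, trait and
# marker CSVs.  All formats are plain text or baseline TIFF so results can
# be inspected with standard tools.

#' Write a segmentation to a directory
#'
#' Writes `mask.tif` (multipage, 0/255), `direction_label.tif` (0 = soil,
#' 1 = found going down, 2 = found going up), `markers.csv` (one row per
#' consumed marker: slice_index, n_pixels, direction, pass_id), and
#' `meta.json` (counters, voxel size, seed, tracker parameters).
#'
#' @param seg a `root_segmentation`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(seg$mask)
  mk_pages <- function(arr, scale) {
    lapply(seq_len(d[3L]), function(i) {
      matrix(as.integer(arr[, , i]) * scale, d[1L], d[2L])
    })
  }
  write_tiff_pages(mk_pages(seg$mask, 255L), file.path(path, "mask.tif"))
  write_tiff_pages(mk_pages(seg$direction_label, 1L),
                   file.path(path, "direction_label.tif"))
  log <- seg$marker_log
  consumed <- log[log$status == "consumed",
                  c("slice_index", "n_pixels", "direction", "pass_id"),
                  drop = FALSE]
  utils::write.csv(consumed, file.path(path, "markers.csv"),
                   row.names = FALSE)
  meta <- list(dims = d, pass_count = seg$pass_count,
               slices_visited = seg$slices_visited,
               first_pass_visits = seg$first_pass_visits,
               voxel_size_um = seg$voxel_size_um,
               seed = as.numeric(seg$seed),
               cfg = if (!is.null(seg$cfg)) unclass(seg$cfg))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a segmentation directory
#'
#' @param path directory written by [write_segmentation()].
#' @return a `root_segmentation` (marker status column restored as
#'   "consumed" for every logged marker).
#' @export
read_segmentation <- function(path) {
  mfile <- file.path(path, "mask.tif")
  if (!file.exists(mfile)) stop("no segmentation at ", path)
  pages <- read_tiff_pages(mfile)
  d <- c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages))
  mask <- array(FALSE, d)
  for (i in seq_len(d[3L])) mask[, , i] <- pages[[i]] > 0L
  lab <- array(0L, d)
  lfile <- file.path(path, "direction_label.tif")
  if (file.exists(lfile)) {
    lp <- read_tiff_pages(lfile)
    for (i in seq_len(d[3L])) lab[, , i] <- lp[[i]]
  } else {
    lab[mask] <- DIR_DOWN
  }
  log <- utils::read.csv(file.path(path, "markers.csv"),
                         colClasses = c("integer", "integer", "character",
                                        "integer"))
  log$status <- rep("consumed", nrow(log))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(
    mask = mask, direction_label = lab, marker_log = log,
    pass_count = meta$pass_count %||% NA_integer_,
    slices_visited = meta$slices_visited %||% NA_integer_,
    first_pass_visits = meta$first_pass_visits %||% NA_integer_,
    voxel_size_um = meta$voxel_size_um %||% NA_real_,
    seed = meta$seed %||% c(NA_real_, NA_real_),
    cfg = meta$cfg), class = "root_segmentation")
}

#' Write a triangle mesh as ascii PLY
#'
#' @param vertices n x 3 numeric matrix.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(vertices, triangles, path) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  nv <- nrow(vertices)
  if (nrow(triangles) && (min(triangles) < 1L || max(triangles) > nv)) {
    stop("triangle index out of range")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(triangles)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  if (nv) {
    writeLines(sprintf("%.8g %.8g %.8g",
                       vertices[, 1L], vertices[, 2L], vertices[, 3L]), con)
  }
  if (nrow(triangles)) {
    writeLines(sprintf("3 %d %d %d", triangles[, 1L] - 1L,
                       triangles[, 2L] - 1L, triangles[, 3L] - 1L), con)
  }
  invisible(path)
}

#' Write a trait table
#'
#' @param traits one or more rows from [measure_traits()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
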