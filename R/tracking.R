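# Slice-to-slice tracking with backward-looking marker detection.
#
# A downward pass carries root objects from slice n to n + 1 by re-running
# the level set on the next slice, initialised with each object's footprint
# and appearance model.  Before advancing it re-examines slice n - 1 from
# the objects on slice n; connected components seen there that do not
# overlap anything already labelled are upward-growing (plagiotropic) root
# candidates and become markers.  Markers spawn upward passes (which look
# downward symmetrically), alternating until no pending markers remain.

DIR_DOWN <- 1L
DIR_UP <- 2L

dir_code <- function(direction) if (direction == "up") DIR_UP else DIR_DOWN
dir_step <- function(direction) if (direction == "up") -1L else 1L
opposite <- function(direction) if (direction == "up") "down" else "up"

# Mutable tracking state shared by the passes.
new_track_state <- function(dims) {
  st <- new.env(parent = emptyenv())
  st$mask <- array(FALSE, dims)
  st$dirlab <- array(0L, dims)
  st$dims <- dims
  st$markers <- list()
  st$pass_count <- 0L
  st$visits <- 0L
  st$first_pass_visits <- 0L
  st$next_id <- 2L
  st
}

slice_mask_px <- function(st, n) {
  nrnc <- st$dims[1L] * st$dims[2L]
  w <- which(st$mask[, , n])
  nr <- st$dims[1L]
  px_set(((w - 1L) %% nr) + 1L, ((w - 1L) %/% nr) + 1L)
}

label_pixels <- function(st, n, px, code) {
  if (!px_n(px)) return(invisible())
  nr <- st$dims[1L]
  lin <- (n - 1L) * nr * st$dims[2L] + px_linear(px, nr)
  fresh <- lin[st$dirlab[lin] == 0L]
  st$mask[fresh] <- TRUE
  st$dirlab[fresh] <- code
  invisible()
}

#' Advance root objects to the adjacent slice
#'
#' Runs one level-set evolution per object on the target slice (initialised
#' with the object's footprint and model), decomposes the result into
#' connected components, and turns each component of at least
#' `cfg$min_area` unlabelled pixels into a child object.  When evolutions
#' from two parents claim overlapping components, the component goes to the
#' parent whose appearance model matches it best; children conditionally
#' adapt their parent's model via [update_model()].
#'
#' @param objects list of `root_object`s on a common slice.
#' @param stack `image_stack`.
#' @param cfg [tracker_config()].
#' @param direction `"down"` or `"up"`: which neighbouring slice to enter.
#' @param labelled (row, col) matrix of already-labelled pixels on the
#'   target slice (excluded from children), or `NULL`.
#' @return list of child `root_object`s on the target slice (possibly empty
#'   — target loss).
#' @export
advance <- function(objects, stack, cfg, direction = "down",
                    labelled = NULL) {
  if (!length(objects)) return(list())
  n <- objects[[1L]]$slice_index
  target <- n + dir_step(direction)
  dims <- dim(stack$voxels)
  if (target < 1L || target > dims[3L]) stop("target slice does not exist")
  img <- stack$voxels[, , target]
  nr <- dims[1L]

  cands <- list()
  for (oi in seq_along(objects)) {
    ob <- objects[[oi]]
    px <- evolve_levelset(img, ob$pixels, ob$model, cfg,
                          exclude_pixels = labelled)
    px <- px_setdiff(px, labelled, nr)
    if (px_n(px) < cfg$min_area) next
    comps <- connected_components(px, cfg$connectivity_2d)
    for (ci in seq_along(comps)) {
      comp <- comps[[ci]]
      if (px_n(comp) < cfg$min_area) next
      obs <- appearance_model(img[px_linear(comp, nr)], ob$model$breaks)
      cands[[length(cands) + 1L]] <- list(
        parent = oi, comp = comp, obs = obs,
        sim = similarity(ob$model, obs))
    }
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, numeric(1), "sim"),
               vapply(cands, `[[`, numeric(1), "parent"))
  taken <- px_empty()
  children <- list()
  for (k in ord) {
    cd <- cands[[k]]
    if (px_intersect_n(cd$comp, taken, nr) > 0L) next  # merged trackers: best model wins
    taken <- rbind(taken, cd$comp)
    parent <- objects[[cd$parent]]
    children[[length(children) + 1L]] <- new_root_object(
      slice_index = target, pixels = cd$comp,
      model = update_model(parent$model, cd$obs, cfg$beta),
      parent_id = parent$id, id = NA_integer_, direction = direction)
  }
  children
}

#' Look back for plagiotropic roots
#'
#' Re-examines the slice just left behind, initialised with the objects on
#' the current slice.  Components recovered there that share fewer than
#' `cfg$overlap_threshold` pixels with the already-labelled mask were not
#' seen when that slice was first visited — they enter the image sequence
#' from the other direction and are recorded as markers for a future pass
#' the opposite way.
#'
#' @param objects list of `root_object`s on the current slice.
#' @param stack `image_stack`.
#' @param labelled_px (row, col) matrix of labelled pixels on the look-back
#'   slice.
#' @param cfg [tracker_config()].
#' @param pass_direction direction of the running pass; the look-back goes
#'   the opposite way and markers inherit that opposite direction.
#' @param source_pass integer id of the running pass.
#' @return list of marker records (slice_index, pixels, direction,
#'   source_pass, status = "pending").
#' @export
look_back <- function(objects, stack, labelled_px, cfg,
                      pass_direction = "down", source_pass = 1L) {
  if (!length(objects)) return(list())
  back_dir <- opposite(pass_direction)
  n <- objects[[1L]]$slice_index
  back <- n + dir_step(back_dir)
  dims <- dim(stack$voxels)
  stopifnot(back >= 1L, back <= dims[3L])
  img <- stack$voxels[, , back]
  nr <- dims[1L]
  markers <- list()
  taken <- px_empty()
  add_marker <- function(fresh) {
    if (px_n(fresh) < cfg$min_area) return(invisible())
    if (!has_2x2_block(fresh)) return(invisible())  # thin noise, not a root
    if (px_intersect_n(fresh, taken, nr) > 0L) return(invisible())
    taken <<- rbind(taken, fresh)
    markers[[length(markers) + 1L]] <<- list(
      slice_index = back, pixels = fresh, direction = back_dir,
      source_pass = source_pass, status = "pending")
    invisible()
  }
  for (ob in objects) {
    px <- evolve_levelset(img, ob$pixels, ob$model, cfg,
                          exclude_pixels = labelled_px)
    if (!px_n(px)) next
    for (comp in connected_components(px, cfg$connectivity_2d)) {
      if (px_n(comp) < cfg$min_area) next
      if (px_intersect_n(comp, labelled_px, nr) < cfg$overlap_threshold) {
        # entirely unseen from the other direction: a plagiotropic root
        add_marker(px_setdiff(comp, labelled_px, nr))
      } else {
        # partially seen: a slowly diverging (or noise-bridged) lateral can
        # share one component with the already-labelled root.  Its fresh
        # remainder is a marker when it is a compact blob (contains a 2x2
        # solid block) rather than a thin boundary-jitter arc.
        fresh <- px_setdiff(comp, labelled_px, nr)
        if (!px_n(fresh)) next
        for (fc in connected_components(fresh, cfg$connectivity_2d)) {
          if (px_n(fc) >= cfg$min_area && has_2x2_block(fc)) add_marker(fc)
        }
      }
    }
  }
  markers
}

# TRUE when the pixel set contains a full 2x2 solid block: distinguishes a
# genuine root cross-section from 1-pixel-thin segmentation jitter.
has_2x2_block <- function(px) {
  if (px_n(px) < 4L) return(FALSE)
  r0 <- min(px[, 1L]); c0 <- min(px[, 2L])
  nr <- max(px[, 1L]) - r0 + 1L
  m <- matrix(FALSE, nr, max(px[, 2L]) - c0 + 1L)
  m[(px[, 2L] - c0) * nr + (px[, 1L] - r0 + 1L)] <- TRUE
  if (nrow(m) < 2L || ncol(m) < 2L) return(FALSE)
  any(m[-1L, -1L] & m[-nrow(m), -1L] & m[-1L, -ncol(m)] &
      m[-nrow(m), -ncol(m)])
}

# One tracking pass.  Counts one slice visit per advance and one per
# look-back (a "segmentation attempt" on that slice), labels new voxels
# with the pass direction, and appends any markers to the state.
run_pass_state <- function(st, stack, cfg, start_objects, direction) {
  st$pass_count <- st$pass_count + 1L
  pass_id <- st$pass_count
  code <- dir_code(direction)
  dims <- st$dims
  objects <- start_objects
  for (ob in objects) label_pixels(st, ob$slice_index, ob$pixels, code)
  objects_by_slice <- list()
  n_markers <- 0L
  repeat {
    if (!length(objects)) break
    n <- objects[[1L]]$slice_index
    objects_by_slice[[as.character(n)]] <- objects
    back <- n + dir_step(opposite(direction))
    if (!cfg$forward_only && back >= 1L && back <= dims[3L]) {
      st$visits <- st$visits + 1L
      mk <- look_back(objects, stack, slice_mask_px(st, back), cfg,
                      pass_direction = direction, source_pass = pass_id)
      if (length(mk)) {
        st$markers <- c(st$markers, mk)
        n_markers <- n_markers + length(mk)
      }
    }
    target <- n + dir_step(direction)
    if (target < 1L || target > dims[3L]) break
    st$visits <- st$visits + 1L
    children <- advance(objects, stack, cfg, direction,
                        labelled = slice_mask_px(st, target))
    if (!length(children)) break
    for (i in seq_along(children)) {
      children[[i]]$id <- st$next_id
      st$next_id <- st$next_id + 1L
      label_pixels(st, target, children[[i]]$pixels, code)
    }
    objects <- children
  }
  list(objects_by_slice = objects_by_slice, new_markers = n_markers,
       slices_visited = length(objects_by_slice))
}

#' Extract a root system from an image stack
#'
#' The full segmentation procedure: one seeded downward pass over the whole
#' stack with backward looks for plagiotropic roots, then alternating
#' marker-spawned passes (deepest marker first) until no pending markers
#' remain.  With `cfg$forward_only = TRUE` the backward looks are skipped,
#' reproducing the classic top-to-bottom tracker.
#'
#' @param stack an `image_stack`.
#' @param seed (row, col) click on slice 1, inside the root.
#' @param cfg [tracker_config()].
#' @return a `root_segmentation`: logical `mask` and integer
#'   `direction_label` arrays congruent with the stack (1 = found going
#'   down, 2 = found going up), the marker log, `pass_count`, and slice
#'   visit counters.
#' @export
#' @seealso [measure_traits()] to quantify the result.
extract_root_system <- function(stack, seed, cfg = tracker_config()) {
  dims <- dim(stack$voxels)
  breaks <- model_breaks(stack$voxels, cfg$bins)
  st <- new_track_state(dims)
  st$visits <- 1L  # the seeded segmentation of slice 1
  obj0 <- init_from_click(stack, seed, cfg, breaks = breaks)
  run_pass_state(st, stack, cfg, list(obj0), "down")
  st$first_pass_visits <- st$visits

  consumed_pass <- integer(0)
  repeat {
    pending <- which(vapply(st$markers, function(m) m$status == "pending",
                            logical(1)))
    if (!length(pending)) break
    # deepest in the soil column first, then creation order
    depth <- vapply(st$markers[pending], function(m) m$slice_index, integer(1))
    mi <- pending[order(-depth, pending)][1L]
    mk <- st$markers[[mi]]
    nr <- dims[1L]
    remainder <- px_setdiff(mk$pixels, slice_mask_px(st, mk$slice_index), nr)
    if (px_n(remainder) < cfg$min_area) {
      st$markers[[mi]]$status <- "discarded"  # claimed by an earlier pass
      next
    }
    img <- stack$voxels[, , mk$slice_index]
    model <- appearance_model(img[px_linear(remainder, nr)], breaks)
    st$visits <- st$visits + 1L
    px <- evolve_levelset(img, remainder, model, cfg,
                          exclude_pixels = slice_mask_px(st, mk$slice_index))
    px <- px_setdiff(px, slice_mask_px(st, mk$slice_index), nr)
    st$markers[[mi]]$status <- "consumed"
    st$markers[[mi]]$pass_id <- st$pass_count + 1L
    starts <- list()
    if (px_n(px) >= cfg$min_area) {
      for (comp in connected_components(px, cfg$connectivity_2d)) {
        if (px_n(comp) < cfg$min_area) next
        starts[[length(starts) + 1L]] <- new_root_object(
          slice_index = mk$slice_index, pixels = comp,
          model = appearance_model(img[px_linear(comp, nr)], breaks),
          parent_id = NA_integer_, id = st$next_id, direction = mk$direction)
        st$next_id <- st$next_id + 1L
      }
    }
    if (length(starts)) {
      run_pass_state(st, stack, cfg, starts, mk$direction)
    } else {
      st$pass_count <- st$pass_count + 1L  # consumed marker, empty pass
    }
  }

  marker_log <- if (length(st$markers)) {
    data.frame(
      slice_index = vapply(st$markers, `[[`, integer(1), "slice_index"),
      n_pixels = vapply(st$markers, function(m) px_n(m$pixels), integer(1)),
      direction = vapply(st$markers, `[[`, character(1), "direction"),
      pass_id = vapply(st$markers, function(m) m$pass_id %||% NA_integer_,
                       integer(1)),
      status = vapply(st$markers, `[[`, character(1), "status")
    )
  } else {
    data.frame(slice_index = integer(0), n_pixels = integer(0),
               direction = character(0), pass_id = integer(0),
               status = character(0))
  }
  structure(list(
    mask = st$mask, direction_label = st$dirlab, marker_log = marker_log,
    pass_count = st$pass_count, slices_visited = st$visits,
    first_pass_visits = st$first_pass_visits,
    voxel_size_um = stack$voxel_size_um, seed = seed, cfg = cfg
  ), class = "root_segmentation")
}

#' @export
print.root_segmentation <- function(x, ...) {
  cat(sprintf(paste0(
    "root_segmentation: %d voxels labelled (%d down, %d up), ",
    "%d pass(es), %d slice visits (%d on the first pass), %d marker(s)\n"),
    sum(x$mask), sum(x$direction_label == DIR_DOWN),
    sum(x$direction_label == DIR_UP), x$pass_count, x$slices_visited,
    x$first_pass_visits, nrow(x$marker_log)))
  invisible(x)
}
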