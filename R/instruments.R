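# Forceps: rigid manipulation of a prism or a detached specimen by a
# movable target point, each grabbed vertex keeping its offset from the
# point. Grabbed vertices are kinematic (infinite mass): springs act on
# the surroundings, not on the held tissue.

#' Grab tissue with the forceps
#'
#' Creates a rigid manipulation handle over a prism element (`element_id`)
#' or a detached specimen (`specimen_id`). Offsets of every grabbed vertex
#' from the target point are stored at grab time; while the handle is
#' active the grabbed vertices are kinematically driven and excluded from
#' force integration.
#'
#' @param lattice a `skin_lattice`
#' @param element_id alive prism element id (mutually exclusive with
#'   `specimen_id`)
#' @param specimen_id specimen id returned by [excise()]
#' @param target_point 3-vector, mm
#' @return a `grab_handle`
#' @export
grab <- function(lattice, element_id = NULL, specimen_id = NULL,
                 target_point) {
  lat <- lattice
  if (is.null(element_id) == is.null(specimen_id))
    argument_error("grab exactly one of element_id or specimen_id")
  if (!is.null(element_id)) {
    if (element_id < 1 || element_id > length(lat$e_alive) ||
        !lat$e_alive[element_id])
      argument_error(paste0("unknown or dead element id: ", element_id))
    verts <- as.integer(lat$e_verts[element_id, ])
  } else {
    if (specimen_id < 1 || specimen_id > length(lat$specimens))
      argument_error(paste0("unknown specimen id: ", specimen_id))
    verts <- lat$specimens[[specimen_id]]$vertices
    verts <- verts[lat$alive[verts]]
  }
  h <- list(id = length(lat$grabs) + 1L, vertices = verts,
            target_point = as.numeric(target_point),
            offsets = sweep(lat$pos[verts, , drop = FALSE], 2,
                            as.numeric(target_point)),
            active = TRUE)
  class(h) <- "grab_handle"
  lat$grabs[[h$id]] <- h
  h
}

#' Move a grab handle to a new target point
#'
#' Pure translation: every grabbed vertex moves to `new_target` plus its
#' stored offset, so pairwise distances within the grabbed set are
#' preserved to machine precision. Surrounding tissue responds through any
#' still-connected springs on the next [relax()].
#'
#' @param handle an active `grab_handle`
#' @param new_target 3-vector, mm
#' @param lattice the `skin_lattice` the handle belongs to
#' @return the updated handle
#' @export
move_handle <- function(handle, new_target, lattice) {
  lat <- lattice
  h <- lat$grabs[[handle$id]]
  if (!isTRUE(h$active)) state_error("grab handle is not active")
  h$target_point <- as.numeric(new_target)
  lat$pos[h$vertices, ] <- sweep(h$offsets, 2, h$target_point, `+`)
  lat$vel[h$vertices, ] <- 0
  lat$grabs[[h$id]] <- h
  h
}

#' Release a grab handle
#' @param handle a `grab_handle`
#' @param lattice the owning `skin_lattice`
#' @return invisibly the deactivated handle
#' @export
release_handle <- function(handle, lattice) {
  h <- lattice$grabs[[handle$id]]
  h$active <- FALSE
  lattice$grabs[[h$id]] <- h
  invisible(h)
}

#' Remove a detached specimen from the scene
#'
#' Tombstones the specimen's vertices, springs and elements (alive = FALSE;
#' ids are never renumbered). Fails if any alive spring still joins the
#' specimen to the remainder.
#'
#' @param lattice a `skin_lattice`
#' @param specimen_id id returned by [excise()]
#' @return removal report with counts of removed vertices/springs/elements
#' @export
remove_excised <- function(lattice, specimen_id) {
  lat <- lattice
  if (specimen_id < 1 || specimen_id > length(lat$specimens))
    argument_error(paste0("unknown specimen id: ", specimen_id))
  sp <- lat$specimens[[specimen_id]]
  vs <- sp$vertices[lat$alive[sp$vertices]]
  idx <- which(lat$s_alive)
  one_in <- xor(lat$s_i[idx] %in% vs, lat$s_j[idx] %in% vs)
  if (any(one_in))
    precondition_error("specimen is still attached to the remainder")
  both_in <- lat$s_i[idx] %in% vs & lat$s_j[idx] %in% vs
  els <- sp$elements[lat$e_alive[sp$elements]]
  lat$alive[vs] <- FALSE
  lat$s_alive[idx[both_in]] <- FALSE
  lat$e_alive[els] <- FALSE
  for (k in seq_along(lat$grabs))     # any forceps still holding it let go
    if (any(lat$grabs[[k]]$vertices %in% vs)) lat$grabs[[k]]$active <- FALSE
  sp$removed <- TRUE
  lat$specimens[[specimen_id]] <- sp
  lat$generation <- lat$generation + 1L
  list(vertices_removed = length(vs), springs_removed = sum(both_in),
       elements_removed = length(els))
}
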