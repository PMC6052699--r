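# Topological surgery on the lattice. Cuts never delete elements: cut
# vertices are duplicated (tombstone-safe, ids stable) and the elements on
# one side of the path are reassigned to the duplicates; the spring set is
# then re-derived from the elements, which severs pairs that crossed the
# cut and creates duplicate-side pairs inheriting the ancestral spring
# properties (including pre-tensioned rest lengths).

path_signature <- function(path) {
  paste0(paste(path$vertices, collapse = ","), "|",
         path$closed, "|", path$through_thickness)
}

duplicate_vertex <- function(lat, v) {
  n <- length(lat$alive) + 1L
  lat$pos <- rbind(lat$pos, lat$pos[v, ])
  lat$vel <- rbind(lat$vel, lat$vel[v, ])
  lat$mass <- c(lat$mass, lat$mass[v])
  lat$plane <- c(lat$plane, lat$plane[v])
  lat$fixed <- c(lat$fixed, lat$fixed[v])
  lat$alive <- c(lat$alive, TRUE)
  lat$dup_of <- c(lat$dup_of, v)
  n
}

# Signed side of each element centroid relative to the path polyline:
# sign of cross(local path direction, centroid - nearest path vertex).
# For closed paths, "inside the polygon" is used instead so the excised
# side is always the one that receives the duplicates.
element_side <- function(lat, path, els) {
  pv <- path$vertices
  pxy <- lat$pos[pv, 1:2, drop = FALSE]
  cen <- t(vapply(els, function(e) element_centroid(lat, e)[1:2],
                  numeric(2)))
  if (path$closed) {
    ins <- pracma::inpolygon(cen[, 1], cen[, 2], pxy[, 1], pxy[, 2],
                             boundary = FALSE)
    return(ifelse(ins, -1, 1))          # -1 = duplicate side (inside)
  }
  vapply(seq_along(els), function(k) {
    d2 <- (pxy[, 1] - cen[k, 1])^2 + (pxy[, 2] - cen[k, 2])^2
    i <- which.min(d2)
    i0 <- max(1L, i - 1L); i1 <- min(length(pv), i + 1L)
    dir <- pxy[i1, ] - pxy[i0, ]
    w <- cen[k, ] - pxy[i, ]
    s <- dir[1] * w[2] - dir[2] * w[1]
    if (abs(s) < 1e-9) 1 else sign(s)   # ties stay with the original
  }, numeric(1))
}

#' Cut vertically along a planned path
#'
#' Splits the skin along a connected SURFACE path. Each interior path
#' vertex (every vertex, for a closed path) and its vertically
#' corresponding INTERFACE vertex are duplicated; top-tier prisms on the
#' duplicate side of the path are reassigned to the copies so no top-tier
#' spring or element spans the cut, physically opening a wound that gapes
#' under pre-tension once relaxed. `through_thickness` paths also split the
#' bottom (fat) tier and BASE plane. Open-path endpoints are never
#' duplicated, so open cuts taper. Re-cutting an already-severed path is a
#' no-op.
#'
#' @param lattice a `skin_lattice`
#' @param path a cut path from an `incision_plan` (`$cut_paths`)
#' @return a cut report: duplicated vertex ids, severed and created spring
#'   ids, and whether the call was a no-op
#' @export
vertical_cut <- function(lattice, path) {
  lat <- lattice
  pv <- path$vertices
  if (!all(lat$alive[pv])) topology_error("cut path references tombstoned vertex")
  pairs <- cbind(pv, c(pv[-1], pv[1]))
  if (!path$closed) pairs <- pairs[-length(pv), , drop = FALSE]
  key <- pair_key(pairs[, 1], pairs[, 2])
  alive_key <- pair_key(lat$s_i[lat$s_alive], lat$s_j[lat$s_alive])
  if (!all(key %in% alive_key))
    topology_error("consecutive cut-path vertices are not HORIZONTAL-adjacent")

  sig <- path_signature(path)
  if (sig %in% lat$cut_log)
    return(list(noop = TRUE, duplicated_vertices = integer(0),
                severed_springs = integer(0), created_springs = integer(0)))

  cutverts <- if (path$closed) pv else pv[-c(1, length(pv))]
  report <- list(noop = FALSE, duplicated_vertices = integer(0))
  if (length(cutverts)) {
    ifc <- vapply(cutverts, function(v) vertical_partner(lat, v, TRUE),
                  integer(1))
    base <- if (path$through_thickness)
      vapply(ifc, function(v) vertical_partner(lat, v, TRUE), integer(1))
    else rep(NA_integer_, length(ifc))

    top_els <- elements_with_vertex(lat, cutverts, "TOP")
    side_top <- element_side(lat, path, top_els)
    bot_els <- integer(0); side_bot <- numeric(0)
    if (path$through_thickness) {
      bot_els <- elements_with_vertex(lat, ifc, "BOTTOM")
      side_bot <- element_side(lat, path, bot_els)
    }

    dup_s <- vapply(cutverts, function(v) duplicate_vertex(lat, v), integer(1))
    dup_i <- vapply(ifc, function(v) duplicate_vertex(lat, v), integer(1))
    dup_b <- rep(NA_integer_, length(cutverts))
    if (path$through_thickness)
      dup_b <- vapply(base, function(v) duplicate_vertex(lat, v), integer(1))

    remap <- function(els, sides, from, to) {
      for (k in which(sides < 0)) {
        ev <- lat$e_verts[els[k], ]
        hit <- match(ev, from)
        repl <- !is.na(hit)
        ev[repl] <- to[hit[repl]]
        lat$e_verts[els[k], ] <- ev
      }
    }
    remap(top_els, side_top, c(cutverts, ifc), c(dup_s, dup_i))
    if (path$through_thickness)
      remap(bot_els, side_bot, c(ifc, base), c(dup_i, dup_b))

    report$duplicated_vertices <- c(dup_s, dup_i,
                                    dup_b[!is.na(dup_b)])
  }
  sync <- sync_springs(lat)
  report$severed_springs <- sync$severed
  report$created_springs <- sync$created
  lat$cut_log <- c(lat$cut_log, sig)
  lat$generation <- lat$generation + 1L
  report
}

#' Undermine a flap region (horizontal cut)
#'
#' Separates the top (skin) tier from the fat beneath a region of top-tier
#' prisms: every INTERFACE vertex all of whose incident alive top-tier
#' prisms lie in the region is duplicated; top-tier prisms keep the
#' original while bottom-tier prisms take the duplicate, freeing the flap's
#' underside. The region boundary stays attached and acts as the flap's
#' pedicle.
#'
#' @param lattice a `skin_lattice`
#' @param region set of alive TOP-tier element ids
#' @return a cut report (duplicated vertices, severed/created springs)
#' @export
undermine <- function(lattice, region) {
  lat <- lattice
  region <- as.integer(region)
  if (length(region) == 0)
    return(list(noop = TRUE, duplicated_vertices = integer(0),
                severed_springs = integer(0), created_springs = integer(0)))
  if (!all(lat$e_alive[region]) ||
      !all(lat$e_tier[region] == TIERS[["TOP"]]))
    gating_error("undermining region must be alive TOP-tier elements")

  # interior INTERFACE vertices: every incident alive TOP prism is in the
  # region (vectorized tally over the element table)
  top_alive <- which(lat$e_alive & lat$e_tier == TIERS[["TOP"]])
  iface_all <- as.vector(lat$e_verts[top_alive, 4:6])
  iface_reg <- as.vector(lat$e_verts[region, 4:6])
  n_all <- table(iface_all)
  n_reg <- table(iface_reg)
  cand <- as.integer(names(n_reg))
  interior <- cand[n_reg == n_all[names(n_reg)]]

  dup <- vapply(interior, function(v) duplicate_vertex(lat, v), integer(1))
  if (length(interior)) {
    bot <- which(lat$e_alive & lat$e_tier == TIERS[["BOTTOM"]])
    bv <- lat$e_verts[bot, , drop = FALSE]
    hit <- match(bv, interior)
    if (any(!is.na(hit))) {
      bv[!is.na(hit)] <- dup[hit[!is.na(hit)]]
      lat$e_verts[bot, ] <- bv
    }
  }
  sync <- sync_springs(lat)
  lat$undermined <- c(lat$undermined, list(region))
  lat$generation <- lat$generation + 1L
  list(noop = FALSE, duplicated_vertices = dup,
       severed_springs = sync$severed, created_springs = sync$created)
}

# igraph over all alive springs; used for component oracles.
spring_graph <- function(lat) {
  idx <- which(lat$s_alive)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(lat$s_i[idx]),
               to = as.character(lat$s_j[idx])),
    directed = FALSE,
    vertices = data.frame(name = as.character(which(lat$alive))))
}

# Full-thickness element set and vertex set of a planned specimen: the
# excision region plus the bottom-tier prisms directly beneath it (sharing
# its INTERFACE vertices after cutting).
specimen_extent <- function(lat, excision_region) {
  top <- excision_region[lat$e_alive[excision_region]]
  ifc <- unique(as.vector(lat$e_verts[top, 4:6]))
  bot <- which(lat$e_alive & lat$e_tier == TIERS[["BOTTOM"]])
  beneath <- bot[vapply(bot, function(e)
    all(lat$e_verts[e, 1:3] %in% ifc), logical(1))]
  els <- c(top, beneath)
  list(elements = els,
       vertices = sort(unique(as.vector(lat$e_verts[els, , drop = FALSE]))))
}

#' Label the excised region as a detachable specimen
#'
#' Verifies by graph search over alive springs that the plan's excision
#' region (with the fat directly beneath it) forms a connected component
#' with no alive spring to the remainder, then labels it as a detachable
#' specimen and unpins its BASE vertices so forceps can lift it. The tissue
#' is not deleted here; removal from the scene is a forceps action
#' ([remove_excised()]).
#'
#' @param lattice a `skin_lattice`
#' @param plan the active `incision_plan`
#' @return the specimen component id (integer)
#' @export
excise <- function(lattice, plan) {
  lat <- lattice
  ext <- specimen_extent(lat, plan$excision_region)
  vs <- ext$vertices
  idx <- which(lat$s_alive)
  one_in <- xor(lat$s_i[idx] %in% vs, lat$s_j[idx] %in% vs)
  if (any(one_in)) {
    att <- idx[one_in]
    precondition_error(
      sprintf("excision region still attached by %d spring(s): %s",
              length(att), paste(utils::head(att, 10), collapse = ", ")),
      attaching_springs = att)
  }
  id <- length(lat$specimens) + 1L
  lat$specimens[[id]] <- list(id = id, elements = ext$elements,
                              vertices = vs, removed = FALSE)
  lat$fixed[vs] <- FALSE                # detached tissue is no longer anchored
  # once the defect exists its designated edges are fixed (rotation and
  # H flap), so free flap edges are pulled towards them during suturing
  lat$fixed[plan$fixed_edge_vertices] <- TRUE
  id
}
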