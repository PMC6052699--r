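STAGES <- c("ASSESS", "MARK", "INCISE", "EXCISE_SPECIMEN", "UNDERMINE",
            "REMOVE_SPECIMEN", "APPOSE", "SUTURE", "COMPLETE")

# igraph over alive SURFACE-plane HORIZONTAL springs, edge weight = current
# length; cached per topology generation.
surface_graph <- function(lat) {
  if (!is.null(lat$sg) && identical(lat$sg_generation, lat$generation))
    return(lat$sg)
  p <- PLANES[["SURFACE"]]
  idx <- which(lat$s_alive & lat$s_cls == SPRING_CLASSES[["HORIZONTAL"]] &
                 lat$plane[lat$s_i] == p & lat$plane[lat$s_j] == p)
  d <- lat$pos[lat$s_i[idx], , drop = FALSE] -
    lat$pos[lat$s_j[idx], , drop = FALSE]
  verts <- sort(unique(c(lat$s_i[idx], lat$s_j[idx])))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(lat$s_i[idx]),
               to = as.character(lat$s_j[idx]),
               weight = sqrt(rowSums(d^2))),
    directed = FALSE, vertices = data.frame(name = as.character(verts)))
  lat$sg <- g
  lat$sg_generation <- lat$generation
  g
}

# Nearest alive SURFACE vertex to each xy point; ties broken by lower id.
nearest_surface_vertex <- function(lat, pts) {
  cand <- which(lat$alive & lat$plane == PLANES[["SURFACE"]])
  xy <- lat$pos[cand, 1:2, drop = FALSE]
  apply(pts, 1, function(p) {
    d2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
    cand[which(d2 == min(d2))[1]]   # candidates are id-sorted
  })
}

# Remove immediate repeats, then excise any loops (keep first occurrence).
dedupe_path <- function(v) {
  v <- v[c(TRUE, diff(v) != 0)]
  while (anyDuplicated(v)) {
    dup <- v[duplicated(v)][1]
    occ <- which(v == dup)
    v <- v[-seq(occ[1] + 1L, occ[2])]
  }
  v
}

# Same for a cyclic sequence: snapping noise produces short spurious
# excursions that revisit a vertex; always drop the shorter arc between
# the two occurrences so the outline itself survives.
dedupe_cycle <- function(v) {
  v <- v[c(TRUE, diff(v) != 0)]
  if (length(v) > 1 && v[1] == v[length(v)]) v <- v[-length(v)]
  guard <- 0L
  while (anyDuplicated(v) && guard < 10000L) {
    guard <- guard + 1L
    dup <- v[duplicated(v)][1]
    occ <- which(v == dup)[1:2]
    mid <- occ[2] - occ[1]
    if (mid <= length(v) - mid) v <- v[-seq(occ[1] + 1L, occ[2])]
    else v <- v[seq(occ[1], occ[2] - 1L)]
    v <- v[c(TRUE, diff(v) != 0)]
    if (length(v) > 1 && v[1] == v[length(v)]) v <- v[-length(v)]
  }
  v
}

# Map a continuous template polyline (n x 2, mm) to a connected SURFACE
# vertex path: nearest-vertex sampling then shortest-path stitching over
# the HORIZONTAL spring graph.
snap_path <- function(lat, pts, closed) {
  snapped <- nearest_surface_vertex(lat, pts)
  snapped <- if (closed) dedupe_cycle(snapped) else dedupe_path(snapped)
  if (closed)
    snapped <- c(snapped, snapped[1])
  g <- surface_graph(lat)
  out <- snapped[1]
  for (k in seq_len(length(snapped) - 1L)) {
    a <- snapped[k]; b <- snapped[k + 1L]
    if (a == b) next
    sp <- igraph::shortest_paths(g, as.character(a), as.character(b),
                                 output = "vpath")$vpath[[1]]
    seg <- as.integer(names(sp))
    if (length(seg) < 2) plan_error("template segment not connected on lattice")
    out <- c(out, seg[-1])
  }
  path <- if (closed) dedupe_cycle(out) else dedupe_path(out)
  # shortcut-smooth open incisions only: a small closed outline could be
  # swallowed whole by repeated shortcuts
  if (!closed) path <- smooth_path(lat, path, FALSE)
  n <- length(path)
  if (closed && n < 3) plan_error("closed path degenerates below 3 vertices")
  if (!closed && n < 2) plan_error("open path degenerates below 2 vertices")
  # connectivity contract: consecutive (and wrap, if closed) pairs adjacent
  pairs <- cbind(path, c(path[-1], path[1]))
  if (!closed) pairs <- pairs[-n, , drop = FALSE]
  key <- pair_key(pairs[, 1], pairs[, 2])
  alive_key <- pair_key(lat$s_i[lat$s_alive], lat$s_j[lat$s_alive])
  if (!all(key %in% alive_key))
    plan_error("snapped path not connected under HORIZONTAL adjacency")
  path
}

# Shortcut smoothing: drop a path vertex whenever its two neighbours are
# directly spring-adjacent and the shortcut is shorter -- removes the
# snapping jitter that would otherwise inflate the polyline length.
smooth_path <- function(lat, path, closed) {
  alive_key <- pair_key(lat$s_i[lat$s_alive], lat$s_j[lat$s_alive])
  seglen <- function(a, b)
    sqrt(sum((lat$pos[a, 1:2] - lat$pos[b, 1:2])^2))
  repeat {
    n <- length(path)
    if (n < (if (closed) 4L else 3L)) break
    changed <- FALSE
    i <- if (closed) 1L else 2L
    while (i <= (if (closed) length(path) else length(path) - 1L)) {
      n <- length(path)
      prev <- if (i == 1L) path[n] else path[i - 1L]
      nxt <- if (i == n) path[1L] else path[i + 1L]
      if (prev != nxt &&
          pair_key(prev, nxt) %in% alive_key &&
          seglen(prev, nxt) <
            seglen(prev, path[i]) + seglen(path[i], nxt) - 1e-9) {
        path <- path[-i]
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed) break
  }
  path
}

check_template_bounds <- function(lat, pts) {
  lo <- lat$spacing                       # >= one ring of margin
  hix <- (lat$cols - 1L) * lat$spacing
  hiy <- (lat$rows - 1L) * lat$spacing
  if (any(pts[, 1] < lo) || any(pts[, 1] > hix) ||
      any(pts[, 2] < lo) || any(pts[, 2] > hiy))
    plan_error("plan geometry exceeds lattice interior bounds")
}

# TOP-tier elements whose centroid falls inside the xy polygon.
elements_inside_polygon <- function(lat, poly_xy) {
  top <- which(lat$e_alive & lat$e_tier == TIERS[["TOP"]])
  cx <- rowMeans(matrix(lat$pos[lat$e_verts[top, 1:3], 1], length(top)))
  cy <- rowMeans(matrix(lat$pos[lat$e_verts[top, 1:3], 2], length(top)))
  inside <- pracma::inpolygon(cx, cy, poly_xy[, 1], poly_xy[, 2],
                              boundary = FALSE)
  top[inside]
}

cut_path <- function(vertices, closed, through_thickness) {
  stopifnot(length(vertices) >= 2)
  list(vertices = as.integer(vertices), closed = isTRUE(closed),
       through_thickness = isTRUE(through_thickness))
}

new_incision_plan <- function(lat, procedure, cut_paths, excision_region,
                              undermining_region, suture_pairs,
                              fixed_edge_vertices, rigid_edge_chain,
                              langer_direction, long_axis, params) {
  path_verts <- unique(unlist(lapply(cut_paths, `[[`, "vertices")))
  exc_verts <- unique(as.vector(lat$e_verts[excision_region, , drop = FALSE]))
  und_verts <- unique(as.vector(lat$e_verts[undermining_region, , drop = FALSE]))
  sut_verts <- unique(as.vector(suture_pairs))
  allowed <- list(
    ASSESS = integer(0),
    MARK = path_verts,
    INCISE = path_verts,
    EXCISE_SPECIMEN = unique(c(exc_verts, path_verts)),
    UNDERMINE = und_verts,
    REMOVE_SPECIMEN = unique(c(exc_verts, path_verts)),
    APPOSE = unique(c(rigid_edge_chain, sut_verts)),
    SUTURE = sut_verts,
    COMPLETE = integer(0))
  all_ref <- unique(c(path_verts, exc_verts, und_verts, sut_verts,
                      fixed_edge_vertices, rigid_edge_chain))
  if (!all(lat$alive[all_ref]))
    plan_error("plan references tombstoned vertices")
  structure(list(procedure = procedure, cut_paths = cut_paths,
                 excision_region = as.integer(excision_region),
                 undermining_region = as.integer(undermining_region),
                 suture_pairs = suture_pairs,
                 fixed_edge_vertices = as.integer(fixed_edge_vertices),
                 rigid_edge_chain = as.integer(rigid_edge_chain),
                 allowed_vertices_by_stage = allowed,
                 langer_direction = langer_direction,
                 long_axis = long_axis, params = params),
            class = "incision_plan")
}

#' @export
print.incision_plan <- function(x, ...) {
  cat(sprintf(
    "<incision_plan> %s | %d cut paths, %d excision / %d undermining elements, %d suture pairs, %d fixed-edge, %d rigid-chain vertices\n",
    x$procedure, length(x$cut_paths), length(x$excision_region),
    length(x$undermining_region), nrow(x$suture_pairs),
    length(x$fixed_edge_vertices), length(x$rigid_edge_chain)))
  invisible(x)
}

# Pair loop vertices on opposite sides of the long axis by matched
# along-axis coordinate, ordered wound-centre outward.
pair_across_axis <- function(lat, loop, center, u, max_dt) {
  v <- c(-u[2], u[1])
  rel <- sweep(lat$pos[loop, 1:2, drop = FALSE], 2, center)
  tt <- rel %*% u
  ww <- rel %*% v
  eps <- 1e-9
  upper <- loop[ww > eps]; tu <- tt[ww > eps]
  lower <- loop[ww < -eps]; tl <- tt[ww < -eps]
  pairs <- NULL
  for (k in seq_along(upper)) {
    j <- which.min(abs(tl - tu[k]))
    if (length(j) && abs(tl[j] - tu[k]) <= max_dt)
      pairs <- rbind(pairs, c(upper[k], lower[j], abs(tu[k])))
  }
  if (is.null(pairs)) plan_error("no opposing suture pairs found")
  pairs <- pairs[!duplicated(pairs[, 2]), , drop = FALSE]
  pairs <- pairs[order(pairs[, 3], pairs[, 1]), , drop = FALSE]
  cbind(free = as.integer(pairs[, 1]), anchor = as.integer(pairs[, 2]))
}

#' Plan an elliptical (fusiform) excision with direct closure
#'
#' Lays a closed fusiform outline of long:short axis ratio `ratio` (surgical
#' convention 3:1), long axis aligned with the Langer-line direction, snapped
#' to a connected SURFACE vertex loop. The excision region is the set of
#' top-tier prisms inside the loop; suture pairs join opposing mid-wound
#' vertices ordered from the wound centre outward. Simple closure pulls both
#' edges together, so no defect edge is fixed and no flap edge rigidified.
#'
#' @param lattice a `skin_lattice`
#' @param center xy centre of the lesion, mm
#' @param lesion_radius short half-axis of the fusiform outline, mm
#' @param ratio long:short axis ratio (default 3)
#' @param langer_direction unit 2-vector of the skin tension lines
#' @return an `incision_plan`
#' @export
plan_ellipse <- function(lattice, center, lesion_radius, ratio = 3,
                         langer_direction = c(1, 0)) {
  if (lesion_radius < lattice$spacing / 2)
    plan_error("lesion_radius below half the lattice spacing")
  u <- langer_direction / sqrt(sum(langer_direction^2))
  v <- c(-u[2], u[1])
  a <- ratio * lesion_radius; b <- lesion_radius
  t <- seq(0, 2 * pi, length.out = 256L)[-256L]
  pts <- cbind(center[1] + a * cos(t) * u[1] + b * sin(t) * v[1],
               center[2] + a * cos(t) * u[2] + b * sin(t) * v[2])
  check_template_bounds(lattice, pts)
  loop <- snap_path(lattice, pts, closed = TRUE)
  poly <- lattice$pos[loop, 1:2, drop = FALSE]
  excision <- elements_inside_polygon(lattice, poly)
  if (length(excision) == 0) plan_error("excision region snapped to nothing")
  pairs <- pair_across_axis(lattice, loop, center, u,
                            max_dt = lattice$spacing / 2)
  # stitch spacing ~2 vertices: interrupted sutures, not a continuous seam
  pairs <- pairs[seq(1, nrow(pairs), by = 2), , drop = FALSE]
  new_incision_plan(lattice, "ELLIPSE",
                    list(cut_path(loop, TRUE, TRUE)),
                    excision, integer(0), pairs, integer(0), integer(0),
                    u, u, list(center = center,
                               lesion_radius = lesion_radius, ratio = ratio))
}

# Snap an axis-aligned straight segment.
snap_segment <- function(lat, p0, p1) {
  n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / (lat$spacing / 2)) + 1L)
  s <- seq(0, 1, length.out = n)
  snap_path(lat, cbind(p0[1] + s * (p1[1] - p0[1]),
                       p0[2] + s * (p1[2] - p0[2])), closed = FALSE)
}

#' Plan a bilateral advancement (H) flap
#'
#' A closed square defect outline (excised full thickness) with four
#' parallel limb incisions extending `limb_length` from the defect corners
#' along the advancement axis, forming the "H". The two rectangular flaps
#' between limb pairs are the undermining region. Suture pairs appose the
#' two advancing leading edges (the former lateral defect edges) across the
#' defect; limb incisions are then closed vertex-to-duplicate. The
#' non-advancing superior and inferior defect edges are the fixed defect
#' edges.
#'
#' @param lattice a `skin_lattice`
#' @param defect_center xy centre of the square defect, mm
#' @param defect_halfwidth half the defect side, mm
#' @param limb_length length of each advancement limb, mm (0 degenerates to
#'   direct closure of the square)
#' @return an `incision_plan`
#' @export
plan_h_flap <- function(lattice, defect_center, defect_halfwidth,
                        limb_length) {
  h <- defect_halfwidth; L <- limb_length
  cx <- defect_center[1]; cy <- defect_center[2]
  if (h < lattice$spacing / 2)
    plan_error("defect_halfwidth below half the lattice spacing")
  corners <- rbind(c(cx - h, cy - h), c(cx + h, cy - h),
                   c(cx + h, cy + h), c(cx - h, cy + h))
  limb_ends <- rbind(c(cx - h - L, cy - h), c(cx + h + L, cy - h),
                     c(cx + h + L, cy + h), c(cx - h - L, cy + h))
  check_template_bounds(lattice, rbind(corners, limb_ends))

  # closed square outline (densified so snapping follows the sides)
  dens <- function(p0, p1) {
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / (lattice$spacing / 2)))
    s <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    cbind(p0[1] + s * (p1[1] - p0[1]), p0[2] + s * (p1[2] - p0[2]))
  }
  sq <- rbind(dens(corners[1, ], corners[2, ]), dens(corners[2, ], corners[3, ]),
              dens(corners[3, ], corners[4, ]), dens(corners[4, ], corners[1, ]))
  outline <- snap_path(lattice, sq, closed = TRUE)
  excision <- elements_inside_polygon(lattice,
                                      lattice$pos[outline, 1:2, drop = FALSE])
  if (length(excision) == 0) plan_error("defect region snapped to nothing")

  paths <- list(cut_path(outline, TRUE, TRUE))
  undermining <- integer(0)
  if (L > 0) {
    for (k in 1:4)
      paths <- c(paths, list(cut_path(
        snap_segment(lattice, corners[k, ], limb_ends[k, ]), FALSE, FALSE)))
    rect <- function(x0, x1, y0, y1)
      elements_inside_polygon(lattice, rbind(c(x0, y0), c(x1, y0),
                                             c(x1, y1), c(x0, y1)))
    undermining <- c(rect(cx - h - L, cx - h, cy - h, cy + h),
                     rect(cx + h, cx + h + L, cy - h, cy + h))
  }

  # leading edges: lattice vertices on the two lateral defect sides
  # (corners excluded: they belong to the fixed superior/inferior edges);
  # tolerance absorbs pre-tension settling of the snapped positions
  px <- lattice$pos[outline, 1]; py <- lattice$pos[outline, 2]
  tol <- lattice$spacing / 3
  lateral <- py > cy - h + tol & py < cy + h - tol
  left <- outline[abs(px - (cx - h)) < tol & lateral]
  right <- outline[abs(px - (cx + h)) < tol & lateral]
  left <- left[order(lattice$pos[left, 2])]
  right <- right[order(lattice$pos[right, 2])]
  ylr <- lattice$pos[left, 2]
  pairs <- NULL
  for (k in seq_along(left)) {
    j <- which.min(abs(lattice$pos[right, 2] - ylr[k]))
    if (abs(lattice$pos[right[j], 2] - ylr[k]) < lattice$spacing / 2)
      pairs <- rbind(pairs, c(left[k], right[j], abs(ylr[k] - cy)))
  }
  if (is.null(pairs)) plan_error("no apposition pairs on defect edges")
  pairs <- pairs[order(pairs[, 3], pairs[, 1]), 1:2, drop = FALSE]
  pairs <- cbind(free = as.integer(pairs[, 1]),
                 anchor = as.integer(pairs[, 2]))
  if (L > 0) {
    # limb closure: original vertex to its cut-time duplicate (free==anchor)
    limb_int <- unlist(lapply(paths[-1], function(p) {
      v <- p$vertices
      if (length(v) > 2) v[-c(1, length(v))] else integer(0)
    }))
    limb_int <- limb_int[seq_along(limb_int) %% 2L == 1L]  # every other stitch
    pairs <- rbind(pairs, cbind(free = limb_int, anchor = limb_int))
  }
  fixed_edges <- setdiff(outline, c(left, right))  # superior/inferior sides
  new_incision_plan(lattice, "H_FLAP", paths, excision, undermining, pairs,
                    fixed_edges, integer(0), c(1, 0), c(1, 0),
                    list(defect_center = defect_center,
                         defect_halfwidth = h, limb_length = L))
}

#' Plan a semicircular rotation flap
#'
#' A closed, approximately triangular defect whose base lies on a circle of
#' radius `arc_radius`, adjoined by an open arc incision sweeping
#' `arc_sweep` degrees from the defect base corner. The crescent between
#' the arc and the defect is the rotating flap (undermining region); its
#' leading free edge (the defect-adjacent cut boundary) is the rigid edge
#' chain used during apposition testing, the far defect edge is fixed, and
#' suture pairs appose the rotated leading edge to the fixed edge before
#' the donor arc is closed vertex-to-duplicate.
#'
#' @param lattice a `skin_lattice`
#' @param defect_center xy centre of the lesion, mm
#' @param defect_radius lesion radius setting the defect size, mm
#' @param arc_radius radius of the rotation arc, mm (> defect_radius)
#' @param arc_sweep arc sweep, degrees (default 180, a semicircle)
#' @return an `incision_plan`
#' @export
plan_rotation <- function(lattice, defect_center, defect_radius, arc_radius,
                          arc_sweep = 180) {
  if (arc_radius <= defect_radius)
    plan_error("arc_radius must exceed defect_radius")
  d <- defect_radius; R <- arc_radius
  O <- c(defect_center[1], defect_center[2] - (R - d))  # circle centre
  phi <- asin(min(1, d / R))
  a1 <- pi / 2 + phi                      # far base corner (left)
  a2 <- pi / 2 - phi                      # arc-start base corner (right)
  B1 <- O + R * c(cos(a1), sin(a1))
  B2 <- O + R * c(cos(a2), sin(a2))
  A <- O + (R - 2 * d) * c(0, 1)          # apex, pointing to the pivot
  sweep_rad <- arc_sweep * pi / 180
  arc_t <- seq(a2, a2 - sweep_rad, length.out = 128L)
  arc_pts <- cbind(O[1] + R * cos(arc_t), O[2] + R * sin(arc_t))
  # defect outline: base along the circle from B1 to B2, then to apex
  base_t <- seq(a1, a2, length.out = 24L)
  tri_pts <- rbind(cbind(O[1] + R * cos(base_t), O[2] + R * sin(base_t)),
                   rbind(B2 * 2 / 3 + A / 3, B2 / 3 + A * 2 / 3, A,
                         A * 2 / 3 + B1 / 3, A / 3 + B1 * 2 / 3))
  check_template_bounds(lattice, rbind(arc_pts, tri_pts))

  outline <- snap_path(lattice, tri_pts, closed = TRUE)
  arc <- snap_path(lattice, arc_pts, closed = FALSE)  # starts at B2
  excision <- elements_inside_polygon(lattice,
                                      lattice$pos[outline, 1:2, drop = FALSE])
  if (length(excision) == 0) plan_error("defect region snapped to nothing")

  # flap crescent: inside the circle, within the swept sector, not defect
  top <- which(lattice$e_alive & lattice$e_tier == TIERS[["TOP"]])
  cx <- rowMeans(matrix(lattice$pos[lattice$e_verts[top, 1:3], 1], length(top)))
  cy <- rowMeans(matrix(lattice$pos[lattice$e_verts[top, 1:3], 2], length(top)))
  rad <- sqrt((cx - O[1])^2 + (cy - O[2])^2)
  ang <- atan2(cy - O[2], cx - O[1])
  # angular membership in (a2 - sweep, a2), unwrapped below a2
  rel <- (a2 - ang) %% (2 * pi)
  in_sector <- rad < R & rel > 0 & rel < sweep_rad
  undermining <- setdiff(top[in_sector], excision)

  # the leading (flap-side) edge is the outline walk from the apex to the
  # arc-start base corner B2; the far (fixed) edge the walk to B1 -- taking
  # the shorter way around the outline keeps each chain contiguous
  ox <- lattice$pos[outline, 1]; oy <- lattice$pos[outline, 2]
  apexv <- outline[which.min((ox - A[1])^2 + (oy - A[2])^2)]
  nearest_on <- function(p) outline[which.min((ox - p[1])^2 + (oy - p[2])^2)]
  subpath <- function(from_v, to_v) {
    n <- length(outline)
    i <- match(from_v, outline); j <- match(to_v, outline)
    fwd <- outline[(seq(i, i + (j - i) %% n) - 1L) %% n + 1L]
    bwd <- outline[(seq(i, i - (i - j) %% n) - 1L) %% n + 1L]
    if (length(fwd) <= length(bwd)) fwd else bwd
  }
  lead_chain <- subpath(apexv, nearest_on(B2))
  far_chain <- subpath(apexv, nearest_on(B1))
  lead <- lead_chain[-1]; farv <- far_chain[-1]       # apex excluded
  n <- min(length(lead), length(farv))
  if (n == 0) plan_error("rotation defect edges snapped to nothing")
  pairs <- cbind(free = lead[seq_len(n)], anchor = farv[seq_len(n)])
  arc_int <- arc[-c(1, length(arc))]
  arc_int <- arc_int[seq_along(arc_int) %% 3L == 1L]  # donor stitches
  pairs <- rbind(pairs, cbind(free = arc_int, anchor = arc_int))

  new_incision_plan(lattice, "ROTATION",
                    list(cut_path(outline, TRUE, TRUE),
                         cut_path(arc, FALSE, FALSE)),
                    excision, undermining, pairs,
                    farv, c(apexv, lead), c(1, 0), NULL,
                    list(defect_center = defect_center,
                         defect_radius = d, arc_radius = R,
                         arc_sweep = arc_sweep, circle_center = O))
}

#' Gate an interaction to the plan's allowed vertices for a stage
#'
#' Cutting, suturing and other tissue-modifying interactions are only
#' possible at the plan's pre-specified vertices; off-plan interactions are
#' disabled and flagged back to the user. Never mutates tissue.
#'
#' @param plan an `incision_plan`
#' @param stage one of the procedure stages
#' @param vertex_id lattice vertex id
#' @return list with `allowed` (logical) and `feedback` (character; empty
#'   when allowed)
#' @export
interaction_gate <- function(plan, stage, vertex_id) {
  if (!stage %in% names(plan$allowed_vertices_by_stage))
    argument_error(paste0("unknown stage: ", stage))
  ok <- vertex_id %in% plan$allowed_vertices_by_stage[[stage]]
  list(allowed = ok,
       feedback = if (ok) "" else
         sprintf("Interaction at vertex %d is not part of the %s plan during %s; follow the marked incision layout.",
                 vertex_id, plan$procedure, stage))
}

#' Angle between the plan's long axis and the Langer-line direction
#'
#' A marking-stage quality metric: incisions aligned with the skin tension
#' lines scar less. Defined for plans with a long axis (elliptical closure
#' and the H-flap advancement axis); otherwise NA.
#'
#' @param plan an `incision_plan`
#' @return acute angle in degrees, in \[0, 90\], or NA
#' @export
langer_alignment <- function(plan) {
  if (is.null(plan$long_axis)) return(NA_real_)
  u <- plan$long_axis / sqrt(sum(plan$long_axis^2))
  l <- plan$langer_direction / sqrt(sum(plan$langer_direction^2))
  acos(min(1, abs(sum(u * l)))) * 180 / pi
}
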