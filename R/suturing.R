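# Suturing: temporary high-stiffness constraint springs with a shrinking
# rest-length schedule, quasi-statically relaxed after each decrement.
# Anchors on fixed defect edges are pinned (ANCHOR_FIXED), so free flap
# edges are pulled towards the defect edge rather than both edges pulling
# towards each other; elliptical closure keeps the symmetric BOTH_PULL
# behaviour. Closed pairs are welded for the stability of later stages.

SUTURE_DEFAULTS <- list(stiffness_factor = 10, schedule_steps = 5L,
                        closure_epsilon = 0.05, closure_tolerance = 0.1,
                        rigid_tolerance = 1e-6)

suture_params <- function(lat) {
  p <- lat$suture_params
  if (is.null(p)) SUTURE_DEFAULTS else utils::modifyList(SUTURE_DEFAULTS, p)
}

# Resolve a plan pair against the current lattice: a pair with
# free == anchor closes an incision line and resolves to (duplicate,
# original) once the cut has created the duplicate.
resolve_pair <- function(lat, pair) {
  free <- pair[[1]]; anchor <- pair[[2]]
  if (free == anchor) {
    dups <- which(lat$dup_of == anchor & lat$alive)
    if (length(dups)) free <- dups[1]
  }
  c(free = free, anchor = anchor)
}

#' Place a suture for one plan pair
#'
#' Creates a temporary high-stiffness spring between the pair's free and
#' anchor vertices. When the anchor lies on the plan's fixed defect edge
#' (rotation and H flap) the mode is ANCHOR_FIXED and the anchor is pinned
#' for the life of the constraint; otherwise both edges pull together
#' (BOTH_PULL, elliptical closure). Sutures must be placed in plan order,
#' wound centre outward: earlier pairs must be CLOSED first.
#'
#' @param lattice a `skin_lattice`
#' @param plan the active `incision_plan`
#' @param pair_index 1-based index into `plan$suture_pairs`
#' @return a `suture_constraint` (also registered on the lattice)
#' @export
place_suture <- function(lattice, plan, pair_index) {
  lat <- lattice
  if (pair_index < 1 || pair_index > nrow(plan$suture_pairs))
    argument_error("pair_index out of range")
  if (pair_index > 1) {
    for (k in seq_len(pair_index - 1L)) {
      s <- if (k <= length(lat$sutures)) lat$sutures[[k]] else NULL
      if (is.null(s) || s$status != "CLOSED")
        ordering_error(sprintf(
          "suture pair %d placed before pair %d closed (close wound-centre outward)",
          pair_index, k))
    }
  }
  rp <- resolve_pair(lat, plan$suture_pairs[pair_index, ])
  if (!all(lat$alive[rp])) topology_error("suture vertex is tombstoned")
  mode <- if (rp[["anchor"]] %in% plan$fixed_edge_vertices)
    "ANCHOR_FIXED" else "BOTH_PULL"
  if (mode == "ANCHOR_FIXED") lat$fixed[rp[["anchor"]]] <- TRUE
  kH <- lat$k_by_class[SPRING_CLASSES[["HORIZONTAL"]]]
  kS <- suture_params(lat)$stiffness_factor * kH
  s <- list(pair_index = pair_index, free = rp[["free"]],
            anchor = rp[["anchor"]], mode = mode,
            stiffness = kS,
            # near-critical for the pair's reduced mass: a pulled stitch
            # settles without ringing
            damping = sqrt(2 * kS * min(lat$mass[rp])),
            rest_current = NA_real_, spring_active = FALSE,
            status = "PLACED")
  class(s) <- "suture_constraint"
  lat$sutures[[pair_index]] <- s
  s
}

suture_gap <- function(lat, s) {
  sqrt(sum((lat$pos[s$free, ] - lat$pos[s$anchor, ])^2))
}

weld_pair <- function(lat, s) {
  lat$pos[s$free, ] <- lat$pos[s$anchor, ]
  lat$vel[s$free, ] <- lat$vel[s$anchor, ]
  lat$welds <- rbind(lat$welds, c(s$free, s$anchor))
  s$spring_active <- FALSE
  s$status <- "CLOSED"
  s
}

#' Tighten a placed suture to closure
#'
#' Steps through a strictly decreasing rest-length schedule (default 5
#' equal decrements from the current gap down to `closure_epsilon`),
#' relaxing the lattice after each decrement and recording the gap. The
#' pair is CLOSED as soon as the endpoint distance falls within
#' `closure_tolerance`; if the elastic schedule alone cannot defeat the
#' surrounding tissue tension, a final knot pins the free vertex at the
#' anchor before welding. Closed pairs are permanently welded.
#'
#' @param lattice a `skin_lattice`
#' @param pair_index index of a placed suture
#' @param config a [sim_config()]
#' @return list with final `status` and the per-stage `gap_trace` (mm)
#' @export
tighten <- function(lattice, pair_index, config = sim_config()) {
  lat <- lattice
  s <- lat$sutures[[pair_index]]
  if (is.null(s) || !s$status %in% c("PLACED", "TIGHTENING"))
    state_error("tighten requires a PLACED or TIGHTENING suture")
  sp <- suture_params(lat)
  eps <- sp$closure_epsilon
  tol <- sp$closure_tolerance
  gap0 <- suture_gap(lat, s)
  trace <- numeric(0)
  if (gap0 <= tol) {
    s <- weld_pair(lat, s)
    lat$sutures[[pair_index]] <- s
    return(list(status = s$status, gap_trace = trace))
  }
  s$status <- "TIGHTENING"
  schedule <- seq(gap0, eps,
                  length.out = sp$schedule_steps + 1L)[-1]
  # intermediate decrements are transient states: give them a reduced step
  # budget; only the final welded state gets the full relaxation budget
  mid_cfg <- config
  mid_cfg$max_steps <- min(config$max_steps, 15000L)
  for (r in schedule) {
    s$rest_current <- r
    s$spring_active <- TRUE
    lat$sutures[[pair_index]] <- s
    rep <- relax(lat, mid_cfg)
    trace <- c(trace, suture_gap(lat, s))
    if (suture_gap(lat, s) <= tol) break
  }
  if (suture_gap(lat, s) > tol) {       # the knot: tie free to anchor
    lat$pos[s$free, ] <- lat$pos[s$anchor, ]
    lat$vel[s$free, ] <- 0
    s$spring_active <- FALSE
    lat$sutures[[pair_index]] <- s
    lat$welds <- rbind(lat$welds, c(s$free, s$anchor))
    relax(lat, config)
    lat$welds <- lat$welds[-nrow(lat$welds), , drop = FALSE]
    trace <- c(trace, suture_gap(lat, s))
  }
  s <- weld_pair(lat, s)
  lat$sutures[[pair_index]] <- s
  relax(lat, config)
  list(status = s$status, gap_trace = trace)
}

#' Rigidify an edge chain (shape matching)
#'
#' Stores the chain's current geometry as a reference shape; while the
#' group is active every dynamics step projects the chain onto the best
#' rigid fit (translation + rotation) of that shape to the current
#' positions, so the chain behaves as a rigid edge regardless of the time
#' step. Used on the rotation flap's leading edge during apposition
#' testing and suture pulling.
#'
#' @param lattice a `skin_lattice`
#' @param chain ordered vertex ids (length >= 2, distinct, alive)
#' @return a `rigid_group` (also registered on the lattice)
#' @export
rigidify_edge <- function(lattice, chain) {
  lat <- lattice
  chain <- as.integer(chain)
  if (length(chain) < 2) argument_error("rigid chain needs >= 2 vertices")
  if (anyDuplicated(chain)) argument_error("rigid chain vertices must be distinct")
  if (!all(lat$alive[chain])) topology_error("rigid chain vertex tombstoned")
  g <- list(id = length(lat$rigid_groups) + 1L, chain = chain,
            reference_shape = lat$pos[chain, , drop = FALSE],
            active = TRUE)
  class(g) <- "rigid_group"
  lat$rigid_groups[[g$id]] <- g
  g
}

#' Deactivate a rigid group
#' @param lattice a `skin_lattice`
#' @param group a `rigid_group` (or its id)
#' @export
release_rigid <- function(lattice, group) {
  id <- if (is.list(group)) group$id else group
  lattice$rigid_groups[[id]]$active <- FALSE
  invisible(lattice$rigid_groups[[id]])
}

chain_distance_matrix <- function(pos) as.matrix(stats::dist(pos))

#' Apposition test: can the mobilized flap reach the defect?
#'
#' Activates rigidity on the plan's rigid edge chain, applies trial
#' reduced-stiffness suture constraints drawing the flap towards the
#' defect, relaxes, and reports the residual gap per apposition pair. All
#' trial constraints and the rigidity are then removed and the prior state
#' restored.
#'
#' @param lattice a `skin_lattice`
#' @param plan the active `incision_plan`
#' @param config a [sim_config()]
#' @return numeric vector of residual gaps (mm), one per apposition pair
#'   (pairs with distinct free/anchor vertices)
#' @export
apposition_test <- function(lattice, plan, config = sim_config()) {
  lat <- lattice
  done <- vapply(plan$cut_paths, function(p) path_signature(p) %in% lat$cut_log,
                 logical(1))
  if (!all(done))
    precondition_error("apposition test requires all plan cuts complete")
  if (length(plan$undermining_region) &&
      !any(vapply(lat$undermined, function(r)
        all(plan$undermining_region %in% r), logical(1))))
    precondition_error("apposition test requires the flap to be undermined")

  snap_pos <- lat$pos; snap_vel <- lat$vel
  snap_sut <- lat$sutures; snap_fixed <- lat$fixed
  grp <- NULL
  if (length(plan$rigid_edge_chain) >= 2)
    grp <- rigidify_edge(lat, plan$rigid_edge_chain)

  app <- which(plan$suture_pairs[, 1] != plan$suture_pairs[, 2])
  kH <- lat$k_by_class[SPRING_CLASSES[["HORIZONTAL"]]]
  n0 <- length(lat$sutures)
  for (k in app) {
    rp <- resolve_pair(lat, plan$suture_pairs[k, ])
    lat$sutures[[length(lat$sutures) + 1L]] <- list(
      pair_index = NA_integer_, free = rp[["free"]], anchor = rp[["anchor"]],
      mode = "TRIAL", stiffness = 0.25 * suture_params(lat)$stiffness_factor * kH,
      damping = sqrt(0.5 * suture_params(lat)$stiffness_factor * kH),
      rest_current = suture_params(lat)$closure_epsilon,
      spring_active = TRUE, status = "TRIAL")
  }
  relax(lat, config)
  gaps <- vapply(app, function(k) {
    rp <- resolve_pair(lat, plan$suture_pairs[k, ])
    sqrt(sum((lat$pos[rp[["free"]], ] - lat$pos[rp[["anchor"]], ])^2))
  }, numeric(1))

  lat$sutures <- snap_sut
  if (!is.null(grp)) release_rigid(lat, grp)
  lat$pos <- snap_pos; lat$vel <- snap_vel; lat$fixed <- snap_fixed
  relax(lat, config)
  stats::setNames(gaps, app)
}
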