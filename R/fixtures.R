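# Canonical fixtures: deterministic lattice configurations, plan
# parameters and golden event scripts for the three procedures. TINY
# fixtures fit the brute-force oracles (6x6 cells); DEFAULT exercises
# realistic geometry (20x20 cells, 100 mm patch).

fixture_params <- function(procedure, size) {
  tiny <- list(rows = 6L, cols = 6L, spacing = 5)
  deft <- list(rows = 20L, cols = 20L, spacing = 5)
  tbl <- list(
    ELLIPSE = list(
      TINY = list(lattice = tiny,
                  plan = list(center = c(15, 15), lesion_radius = 4,
                              ratio = 2.5)),
      DEFAULT = list(lattice = deft,
                     plan = list(center = c(50, 50), lesion_radius = 8,
                                 ratio = 3))),
    H_FLAP = list(
      TINY = list(lattice = tiny,
                  plan = list(defect_center = c(15, 15),
                              defect_halfwidth = 5, limb_length = 5)),
      DEFAULT = list(lattice = deft,
                     plan = list(defect_center = c(50, 50),
                                 defect_halfwidth = 10,
                                 limb_length = 20))),
    ROTATION = list(
      TINY = list(lattice = tiny,
                  plan = list(defect_center = c(15, 18),
                              defect_radius = 4, arc_radius = 10,
                              arc_sweep = 90)),
      DEFAULT = list(lattice = deft,
                     plan = list(defect_center = c(50, 65),
                                 defect_radius = 10, arc_radius = 25,
                                 arc_sweep = 180))))
  tbl[[procedure]][[size]]
}

#' Generate a deterministic procedure fixture
#'
#' Returns the lattice configuration, plan parameters and golden event
#' script for one of the three procedures. TINY fixtures (6x6 cells) are
#' sized for exhaustive brute-force oracles; DEFAULT fixtures (20x20
#' cells) exercise realistic flap geometry. Fixtures contain no random
#' numbers and are identical across runs.
#'
#' @param procedure "ELLIPSE", "H_FLAP" or "ROTATION"
#' @param size "TINY" or "DEFAULT"
#' @param pretension SURFACE pre-tension factor applied in the scene
#' @return a `flapsim_fixture` list: `lattice_config`, `plan_params`,
#'   `pretension`, `procedure`, `size`, and `events` (the golden script)
#' @export
generate_fixture <- function(procedure = c("ELLIPSE", "H_FLAP", "ROTATION"),
                             size = c("TINY", "DEFAULT"),
                             pretension = 0.9) {
  procedure <- match.arg(procedure)
  size <- match.arg(size)
  p <- fixture_params(procedure, size)
  scene <- build_fixture_scene(procedure, p$lattice, p$plan, pretension)
  structure(list(procedure = procedure, size = size,
                 lattice_config = p$lattice, plan_params = p$plan,
                 pretension = pretension,
                 events = golden_script(scene$lattice, scene$plan)),
            class = "flapsim_fixture")
}

build_fixture_scene <- function(procedure, lattice_config, plan_params,
                                pretension, config = sim_config()) {
  lat <- do.call(build_lattice, lattice_config)
  if (pretension < 1) {
    apply_pretension(lat, pretension, "SURFACE")
    relax(lat, config)
  }
  plan <- switch(procedure,
                 ELLIPSE = do.call(plan_ellipse, c(list(lat), plan_params)),
                 H_FLAP = do.call(plan_h_flap, c(list(lat), plan_params)),
                 ROTATION = do.call(plan_rotation, c(list(lat), plan_params)))
  list(lattice = lat, plan = plan, config = config)
}

#' Materialize a fixture into a ready scene
#'
#' Builds the lattice, applies the surface pre-tension, relaxes to the
#' pre-operative equilibrium and lays the incision plan.
#'
#' @param fixture from [generate_fixture()]
#' @param config a [sim_config()]
#' @return list with `lattice`, `plan`, `config`
#' @export
fixture_scene <- function(fixture, config = sim_config()) {
  build_fixture_scene(fixture$procedure, fixture$lattice_config,
                      fixture$plan_params, fixture$pretension, config)
}

# The canonical full-procedure event stream for a plan: assess, mark every
# plan vertex, cut every path, free the specimen, undermine the flaps,
# remove the specimen with forceps, test apposition, then place and
# tighten every suture in order.
golden_script <- function(lat, plan) {
  ev <- list(interaction_event("TOGGLE_LANGER"),
             interaction_event("ADVANCE"))
  for (v in unique(unlist(lapply(plan$cut_paths, `[[`, "vertices"))))
    ev <- c(ev, list(interaction_event("MARK", vertex = v)))
  for (k in seq_along(plan$cut_paths))
    ev <- c(ev, list(interaction_event("CUT", path = k)))
  ev <- c(ev, list(interaction_event("ADVANCE")))        # free the specimen
  if (length(plan$undermining_region))
    ev <- c(ev, list(interaction_event("UNDERMINE",
                                       region = plan$undermining_region)))
  if (length(plan$excision_region)) {
    ctr <- colMeans(lat$pos[unique(as.vector(
      lat$e_verts[plan$excision_region, , drop = FALSE])), , drop = FALSE])
    lift <- ctr + c(0, 0, 30)
    ev <- c(ev,
            list(interaction_event("GRAB", specimen = 1L, target = ctr),
                 interaction_event("MOVE", target = lift),
                 interaction_event("REMOVE", specimen = 1L)))
  }
  if (length(plan$rigid_edge_chain))
    ev <- c(ev, list(interaction_event("APPOSE")))
  for (k in seq_len(nrow(plan$suture_pairs)))
    ev <- c(ev, list(interaction_event("SUTURE_PLACE", pair = k),
                     interaction_event("SUTURE_TIGHTEN", pair = k)))
  ev
}

#' Replay a fixture's golden script end to end
#'
#' @param fixture from [generate_fixture()]
#' @param config a [sim_config()]
#' @return the [run_script()] result (`state` + `metrics`)
#' @export
replay_fixture <- function(fixture, config = sim_config()) {
  scene <- fixture_scene(fixture, config)
  run_script(scene$lattice, scene$plan, fixture$events, config)
}
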