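# Staged state controller: ASSESS -> MARK -> INCISE -> EXCISE_SPECIMEN ->
# UNDERMINE -> REMOVE_SPECIMEN -> APPOSE -> SUTURE -> COMPLETE, with
# UNDERMINE/APPOSE skipped for plans without the corresponding regions
# (elliptical closure). All interactions are gated; rejected events leave
# the tissue state bit-identical and are flagged back with feedback.

EVENT_KINDS <- c("TOGGLE_LANGER", "MARK", "CUT", "UNDERMINE", "GRAB",
                 "MOVE", "RELEASE", "REMOVE", "APPOSE", "SUTURE_PLACE",
                 "SUTURE_TIGHTEN", "ADVANCE")

# Which stage each event kind belongs to (TOGGLE_LANGER and ADVANCE are
# legal everywhere).
EVENT_STAGE <- list(MARK = "MARK", CUT = "INCISE", UNDERMINE = "UNDERMINE",
                    GRAB = "REMOVE_SPECIMEN", MOVE = "REMOVE_SPECIMEN",
                    RELEASE = "REMOVE_SPECIMEN", REMOVE = "REMOVE_SPECIMEN",
                    APPOSE = "APPOSE", SUTURE_PLACE = "SUTURE",
                    SUTURE_TIGHTEN = "SUTURE")

#' Construct an interaction event
#'
#' The discrete stand-in for a touch gesture: a kind plus the reference it
#' acts on (a vertex, a cut path index, an element region, a suture pair
#' index, or target coordinates).
#'
#' @param kind one of TOGGLE_LANGER, MARK, CUT, UNDERMINE, GRAB, MOVE,
#'   RELEASE, REMOVE, APPOSE, SUTURE_PLACE, SUTURE_TIGHTEN, ADVANCE
#' @param vertex,path,region,pair,specimen,element references, as needed
#' @param target 3-vector of target coordinates (GRAB/MOVE)
#' @return an `interaction_event`
#' @export
interaction_event <- function(kind, vertex = NULL, path = NULL,
                              region = NULL, pair = NULL, specimen = NULL,
                              element = NULL, target = NULL) {
  if (!kind %in% EVENT_KINDS)
    argument_error(paste0("unknown event kind: ", kind))
  structure(list(kind = kind, vertex = vertex, path = path,
                 region = region, pair = pair, specimen = specimen,
                 element = element, target = target),
            class = "interaction_event")
}

applicable_stages <- function(plan) {
  st <- STAGES
  if (length(plan$undermining_region) == 0) st <- setdiff(st, "UNDERMINE")
  if (length(plan$rigid_edge_chain) == 0) st <- setdiff(st, "APPOSE")
  if (length(plan$excision_region) == 0)
    st <- setdiff(st, c("EXCISE_SPECIMEN", "REMOVE_SPECIMEN"))
  st
}

#' Start a staged procedure
#'
#' @param lattice a `skin_lattice`
#' @param plan an `incision_plan`
#' @param config a [sim_config()]
#' @return a `procedure_state` environment
#' @export
procedure_state <- function(lattice, plan, config = sim_config()) {
  st <- new.env(parent = emptyenv())
  class(st) <- "procedure_state"
  st$lattice <- lattice
  st$plan <- plan
  st$config <- config
  st$stages <- applicable_stages(plan)
  st$stage <- st$stages[1]
  st$marked <- integer(0)
  st$specimen_id <- NA_integer_
  st$grab_handle <- NULL
  st$apposed <- FALSE
  st$assess_done <- FALSE
  st$langer_on <- FALSE
  st$event_log <- list()
  st$rejected <- 0L
  st$gap_trace <- list()
  st$appose_gaps <- NULL
  st
}

#' @export
print.procedure_state <- function(x, ...) {
  cat(sprintf("<procedure_state> %s | stage %s | %d events (%d rejected)\n",
              x$plan$procedure, x$stage, length(x$event_log), x$rejected))
  invisible(x)
}

#' Quantized digest of the tissue state
#'
#' Hash of the lattice topology (alive flags, spring endpoints, element
#' vertices, welds) and of positions quantized at the displacement
#' tolerance, so floating-point jitter below the tolerance cannot break
#' determinism checks.
#'
#' @param lattice a `skin_lattice`
#' @param quantum position quantum, mm
#' @return md5 digest string
#' @export
state_hash <- function(lattice, quantum = 1e-4) {
  lat <- lattice
  qpos <- round(lat$pos[lat$alive, , drop = FALSE] / quantum)
  idx <- which(lat$s_alive)
  txt <- c(paste(which(lat$alive), collapse = ","),
           paste(qpos, collapse = ","),
           paste(lat$s_i[idx], lat$s_j[idx], collapse = ","),
           paste(lat$e_verts[lat$e_alive, ], collapse = ","),
           paste(lat$welds, collapse = ","))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

stage_complete <- function(st) {
  lat <- st$lattice; plan <- st$plan
  switch(st$stage,
    ASSESS = isTRUE(st$assess_done),
    MARK = {
      need <- unique(unlist(lapply(plan$cut_paths, `[[`, "vertices")))
      all(need %in% st$marked)
    },
    INCISE = all(vapply(plan$cut_paths, function(p)
      path_signature(p) %in% lat$cut_log, logical(1))),
    EXCISE_SPECIMEN = !is.na(st$specimen_id),
    UNDERMINE = any(vapply(lat$undermined, function(r)
      all(plan$undermining_region %in% r), logical(1))),
    REMOVE_SPECIMEN = !is.na(st$specimen_id) &&
      isTRUE(lat$specimens[[st$specimen_id]]$removed),
    APPOSE = isTRUE(st$apposed),
    SUTURE = nrow(plan$suture_pairs) > 0 &&
      length(lat$sutures) >= nrow(plan$suture_pairs) &&
      all(vapply(seq_len(nrow(plan$suture_pairs)), function(k)
        !is.null(lat$sutures[[k]]) && lat$sutures[[k]]$status == "CLOSED",
        logical(1))),
    COMPLETE = FALSE)
}

advance_stage_if_complete <- function(st) {
  while (st$stage != "COMPLETE" && stage_complete(st)) {
    i <- match(st$stage, st$stages)
    st$stage <- st$stages[i + 1L]
  }
}

# Vertices an event touches, for plan gating.
event_vertices <- function(st, ev) {
  plan <- st$plan
  switch(ev$kind,
    MARK = ev$vertex,
    CUT = if (!is.null(ev$path) && ev$path <= length(plan$cut_paths))
      plan$cut_paths[[ev$path]]$vertices else integer(0),
    UNDERMINE = integer(0),            # region subset checked separately
    SUTURE_PLACE = ,
    SUTURE_TIGHTEN = if (!is.null(ev$pair) &&
                           ev$pair <= nrow(plan$suture_pairs))
      as.vector(plan$suture_pairs[ev$pair, ]) else integer(0),
    integer(0))
}

#' Dispatch one interaction event through the state controller
#'
#' The event is gated by stage legality and by the plan's allowed-vertex
#' sets ([interaction_gate()]). Legal tissue-modifying events dispatch to
#' the owning module and are followed by a quasi-static [relax()]; illegal
#' events are logged with feedback and cause no tissue change (the state
#' hash is untouched). The stage auto-advances whenever its completion
#' predicate becomes true. No errors are raised to the caller: every
#' rejection is in-band feedback.
#'
#' @param state a `procedure_state`
#' @param event an [interaction_event()]
#' @return the state, invisibly; inspect `state$event_log`
#' @export
advance <- function(state, event) {
  st <- state
  lat <- st$lattice
  plan <- st$plan
  reject <- function(msg) {
    st$rejected <- st$rejected + 1L
    st$event_log[[length(st$event_log) + 1L]] <-
      list(event = event, outcome = "rejected", feedback = msg)
    invisible(st)
  }
  accept <- function(msg = "") {
    st$event_log[[length(st$event_log) + 1L]] <-
      list(event = event, outcome = "accepted", feedback = msg)
    advance_stage_if_complete(st)
    invisible(st)
  }

  if (!inherits(event, "interaction_event"))
    return(reject("malformed event"))
  kind <- event$kind
  legal_stage <- EVENT_STAGE[[kind]]
  if (!is.null(legal_stage) && !identical(st$stage, legal_stage))
    return(reject(sprintf(
      "%s is not available during %s; current task: %s.", kind, st$stage,
      st$stage)))

  verts <- event_vertices(st, event)
  for (v in verts) {
    gate <- interaction_gate(plan, st$stage, v)
    if (!gate$allowed) return(reject(gate$feedback))
  }

  cfg <- st$config
  out <- switch(kind,
    TOGGLE_LANGER = { st$langer_on <- !st$langer_on; accept() },
    ADVANCE = {
      if (st$stage == "ASSESS") {
        st$assess_done <- TRUE
        accept("Assessment complete; mark the incision plan.")
      } else if (st$stage == "EXCISE_SPECIMEN") {
        res <- tryCatch(excise(lat, plan), flapsim_error = identity)
        if (inherits(res, "condition")) reject(conditionMessage(res))
        else { st$specimen_id <- res; accept("Specimen freed.") }
      } else accept()
    },
    MARK = {
      st$marked <- union(st$marked, event$vertex)
      accept()
    },
    CUT = {
      if (is.null(event$path) || event$path > length(plan$cut_paths))
        reject("no such planned cut path")
      else {
        rep <- tryCatch(vertical_cut(lat, plan$cut_paths[[event$path]]),
                        flapsim_error = identity)
        if (inherits(rep, "condition")) reject(conditionMessage(rep))
        else { relax(lat, cfg); record_gap(st); accept() }
      }
    },
    UNDERMINE = {
      region <- if (is.null(event$region)) plan$undermining_region
      else event$region
      if (!all(region %in% plan$undermining_region))
        reject("undermining outside the planned flap region")
      else {
        rep <- tryCatch(undermine(lat, region), flapsim_error = identity)
        if (inherits(rep, "condition")) reject(conditionMessage(rep))
        else { relax(lat, cfg); record_gap(st); accept() }
      }
    },
    GRAB = {
      res <- tryCatch(grab(lat, specimen_id = event$specimen,
                           target_point = event$target),
                      flapsim_error = identity)
      if (inherits(res, "condition")) reject(conditionMessage(res))
      else { st$grab_handle <- res; accept() }
    },
    MOVE = {
      if (is.null(st$grab_handle)) reject("nothing grabbed")
      else {
        res <- tryCatch(move_handle(st$grab_handle, event$target, lat),
                        flapsim_error = identity)
        if (inherits(res, "condition")) reject(conditionMessage(res))
        else { st$grab_handle <- res; relax(lat, cfg); accept() }
      }
    },
    RELEASE = {
      if (is.null(st$grab_handle)) reject("nothing grabbed")
      else { release_handle(st$grab_handle, lat); st$grab_handle <- NULL
        relax(lat, cfg); accept() }
    },
    REMOVE = {
      res <- tryCatch(remove_excised(lat, event$specimen),
                      flapsim_error = identity)
      if (inherits(res, "condition")) reject(conditionMessage(res))
      else { relax(lat, cfg); record_gap(st); accept("Specimen removed.") }
    },
    APPOSE = {
      res <- tryCatch(apposition_test(lat, plan, cfg),
                      flapsim_error = identity)
      if (inherits(res, "condition")) reject(conditionMessage(res))
      else { st$appose_gaps <- res; st$apposed <- TRUE
        accept(sprintf("Apposition residual gaps: %s mm.",
                       paste(signif(res, 3), collapse = ", "))) }
    },
    SUTURE_PLACE = {
      res <- tryCatch(place_suture(lat, plan, event$pair),
                      flapsim_error = identity)
      if (inherits(res, "condition")) reject(conditionMessage(res))
      else accept()
    },
    SUTURE_TIGHTEN = {
      s <- if (!is.null(event$pair) && event$pair <= length(lat$sutures))
        lat$sutures[[event$pair]] else NULL
      if (is.null(s)) reject("suture not placed")
      else {
        # an unconverged relax leaves the suture TIGHTENING; pull again,
        # as the user would, before giving feedback
        res <- NULL
        for (attempt in 1:3) {
          res <- tryCatch(tighten(lat, event$pair, cfg),
                          flapsim_error = identity)
          if (inherits(res, "condition") ||
                identical(res$status, "CLOSED")) break
        }
        if (inherits(res, "condition")) reject(conditionMessage(res))
        else { st$gap_trace[[length(st$gap_trace) + 1L]] <-
          list(pair = event$pair, trace = res$gap_trace)
          record_gap(st)
          accept(if (identical(res$status, "CLOSED")) "" else
            "Suture did not close; tissue still settling.") }
      }
    },
    reject("unknown event kind"))
  invisible(st)
}

record_gap <- function(st) {
  st$gap_trace[[length(st$gap_trace) + 1L]] <-
    list(stage = st$stage, gaps = wound_gap(st$lattice, st$plan))
}

#' Current wound gap per suture pair
#'
#' Euclidean distance between the (resolved) free and anchor vertex of
#' every plan suture pair. Welded pairs report the closure epsilon.
#'
#' @param lattice a `skin_lattice`
#' @param plan an `incision_plan`
#' @return numeric vector of distances, mm
#' @export
wound_gap <- function(lattice, plan) {
  lat <- lattice
  welded <- if (nrow(lat$welds)) lat$welds[, 1] else integer(0)
  vapply(seq_len(nrow(plan$suture_pairs)), function(k) {
    rp <- resolve_pair(lat, plan$suture_pairs[k, ])
    if (rp[["free"]] %in% welded) return(suture_params(lat)$closure_epsilon)
    sqrt(sum((lat$pos[rp[["free"]], ] - lat$pos[rp[["anchor"]], ])^2))
  }, numeric(1))
}

#' Replay a scripted event stream
#'
#' Folds [advance()] over an ordered event list. Deterministic: identical
#' lattice, plan, events and configuration yield an identical final state
#' hash.
#'
#' @param lattice a `skin_lattice`
#' @param plan an `incision_plan`
#' @param events list of [interaction_event()]s
#' @param config a [sim_config()]
#' @return list with the final `procedure_state` and a `metrics` bundle
#'   (final stage, state hash, wound-gap trace, spring strain summary,
#'   rejected/total event counts, per-stage event counts)
#' @export
run_script <- function(lattice, plan, events, config = sim_config()) {
  st <- procedure_state(lattice, plan, config)
  per_stage <- integer(0)
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (!inherits(ev, "interaction_event"))
      flapsim_error("flapsim_parse_error",
                    sprintf("malformed event record at index %d", i))
    per_stage[st$stage] <- (if (is.na(per_stage[st$stage])) 0L
                            else per_stage[st$stage]) + 1L
    advance(st, ev)
  }
  metrics <- list(
    procedure = plan$procedure,
    final_stage = st$stage,
    state_hash = state_hash(st$lattice, config$displacement_tolerance),
    wound_gap = wound_gap(st$lattice, plan),
    gap_trace = st$gap_trace,
    strain = spring_strain_summary(st$lattice),
    events_total = length(events),
    events_rejected = st$rejected,
    events_per_stage = as.list(per_stage),
    appose_gaps = st$appose_gaps)
  list(state = st, metrics = metrics)
}
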