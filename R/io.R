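# Configuration, native JSON state format, event streams, mesh export.

`%||%` <- function(a, b) if (is.null(a)) b else a

default_config <- function() {
  list(
    lattice = list(rows = 20L, cols = 20L, spacing = 5,
                   top_thickness = 2, bottom_thickness = 4,
                   mass_per_vertex = 1,
                   stiffness = list(HORIZONTAL = 100, VERTICAL = 100,
                                    DIAGONAL = 50),
                   damping = list(HORIZONTAL = 5, VERTICAL = 5,
                                  DIAGONAL = 5),
                   fix_base = TRUE, fix_boundary = FALSE,
                   pretension = 0.9),
    dynamics = list(dt = 0.005, max_steps = 60000L,
                    velocity_tolerance = 1e-3,
                    displacement_tolerance = 1e-4,
                    gravity = c(0, 0, 0), drag = 2,
                    speed_ceiling = 1e5, seed = 1L),
    plan = list(procedure = "ELLIPSE",
                params = list(center = c(50, 50), lesion_radius = 8,
                              ratio = 3)),
    suturing = list(stiffness_factor = 10, schedule_steps = 5L,
                    closure_epsilon = 0.05, closure_tolerance = 0.1,
                    rigid_tolerance = 1e-6),
    procedure = list(langer_direction = c(1, 0)))
}

merge_config <- function(base, override, path = character(0),
                         violations = new.env()) {
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      violations$v <- c(violations$v, paste0("unknown field: ", here))
    } else if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        violations$v <- c(violations$v, paste0(here, " must be a section"))
      else base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                      c(path, nm), violations)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

check_config <- function(cfg) {
  bad <- character(0)
  need_pos <- c("lattice.rows", "lattice.cols", "lattice.spacing",
                "lattice.top_thickness", "lattice.bottom_thickness",
                "lattice.mass_per_vertex", "dynamics.dt",
                "dynamics.max_steps", "dynamics.velocity_tolerance",
                "dynamics.displacement_tolerance",
                "suturing.closure_epsilon", "suturing.closure_tolerance")
  for (p in need_pos) {
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(val) || length(val) != 1 || val <= 0)
      bad <- c(bad, paste0(p, " must be a positive number"))
  }
  pt <- cfg$lattice$pretension
  if (!is.numeric(pt) || pt <= 0 || pt > 1)
    bad <- c(bad, "lattice.pretension must be in (0, 1]")
  if (!cfg$plan$procedure %in% c("ELLIPSE", "H_FLAP", "ROTATION"))
    bad <- c(bad, "plan.procedure must be ELLIPSE, H_FLAP or ROTATION")
  bad
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON document with sections `lattice`, `dynamics`, `plan`,
#' `suturing` and `procedure`, applies defaults to every omitted field and
#' validates the result; all violations are reported together with their
#' field paths. An empty JSON object yields the full default
#' configuration.
#'
#' @param path JSON file path, or NULL for defaults
#' @return the normalized configuration list
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  viol <- new.env(); viol$v <- character(0)
  cfg <- merge_config(default_config(), user, violations = viol)
  bad <- c(viol$v, check_config(cfg))
  if (length(bad))
    config_error(paste0("invalid configuration:\n  ",
                        paste(bad, collapse = "\n  ")))
  cfg
}

#' Serialize a lattice to its native JSON state document
#' @param lattice a `skin_lattice`
#' @param path output file; if NULL the JSON string is returned
#' @export
lattice_to_json <- function(lattice, path = NULL) {
  lat <- lattice
  doc <- list(
    format = "flapsim-lattice", version = 1L,
    meta = list(rows = lat$rows, cols = lat$cols, spacing = lat$spacing,
                top_thickness = lat$top_thickness,
                bottom_thickness = lat$bottom_thickness,
                npp = lat$npp, generation = lat$generation),
    vertices = list(pos = lat$pos, vel = lat$vel, mass = lat$mass,
                    plane = lat$plane, fixed = lat$fixed,
                    alive = lat$alive, dup_of = lat$dup_of),
    springs = list(i = lat$s_i, j = lat$s_j, rest = lat$s_rest,
                   k = lat$s_k, c = lat$s_c, cls = lat$s_cls,
                   alive = lat$s_alive),
    elements = list(tier = lat$e_tier, verts = lat$e_verts,
                    alive = lat$e_alive),
    welds = lat$welds, cut_log = lat$cut_log,
    k_by_class = lat$k_by_class, c_by_class = lat$c_by_class)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Restore a lattice from its native JSON state document
#' @param path JSON file path (or JSON string)
#' @return a `skin_lattice`
#' @export
lattice_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "flapsim-lattice"))
    config_error("not a flapsim lattice document")
  lat <- new.env(parent = emptyenv())
  class(lat) <- "skin_lattice"
  m <- doc$meta
  lat$rows <- as.integer(m$rows); lat$cols <- as.integer(m$cols)
  lat$spacing <- m$spacing; lat$npp <- as.integer(m$npp)
  lat$top_thickness <- m$top_thickness
  lat$bottom_thickness <- m$bottom_thickness
  v <- doc$vertices
  lat$pos <- matrix(as.numeric(v$pos), ncol = 3)
  lat$vel <- matrix(as.numeric(v$vel), ncol = 3)
  lat$mass <- as.numeric(v$mass); lat$plane <- as.integer(v$plane)
  lat$fixed <- as.logical(v$fixed); lat$alive <- as.logical(v$alive)
  lat$dup_of <- as.integer(v$dup_of)
  s <- doc$springs
  lat$s_i <- as.integer(s$i); lat$s_j <- as.integer(s$j)
  lat$s_rest <- as.numeric(s$rest); lat$s_k <- as.numeric(s$k)
  lat$s_c <- as.numeric(s$c); lat$s_cls <- as.integer(s$cls)
  lat$s_alive <- as.logical(s$alive)
  e <- doc$elements
  lat$e_tier <- as.integer(e$tier)
  lat$e_verts <- matrix(as.integer(e$verts), ncol = 6)
  lat$e_alive <- as.logical(e$alive)
  lat$welds <- if (length(doc$welds)) matrix(as.integer(doc$welds), ncol = 2)
  else matrix(integer(0), 0, 2)
  lat$cut_log <- as.character(doc$cut_log %||% character(0))
  lat$k_by_class <- as.numeric(doc$k_by_class)
  lat$c_by_class <- as.numeric(doc$c_by_class)
  lat$generation <- as.integer(m$generation)
  lat$specimens <- list(); lat$grabs <- list()
  lat$rigid_groups <- list(); lat$sutures <- list()
  lat$undermined <- list()
  lat$adj_generation <- -1L; lat$adj <- NULL
  validate_lattice(lat)
  lat
}

# Alive SURFACE triangles with a locally renumbered vertex table.
surface_mesh <- function(lat) {
  top <- which(lat$e_alive & lat$e_tier == TIERS[["TOP"]])
  tris <- lat$e_verts[top, 1:3, drop = FALSE]
  ids <- sort(unique(as.vector(tris)))
  list(ids = ids, pos = lat$pos[ids, , drop = FALSE],
       tris = matrix(match(tris, ids), ncol = 3))
}

#' Export the SURFACE triangle mesh
#'
#' Writes the alive surface triangles with stable (id-sorted) vertex
#' ordering as Wavefront OBJ or ASCII PLY for external inspection.
#'
#' @param lattice a `skin_lattice`
#' @param path output file
#' @param format "OBJ" or "PLY"
#' @return invisibly, the path
#' @export
export_surface_mesh <- function(lattice, path, format = c("OBJ", "PLY")) {
  format <- match.arg(format)
  m <- surface_mesh(lattice)
  con <- tryCatch(file(path, "w"), error = function(e)
    flapsim_error("flapsim_io_error", paste0("cannot write ", path)))
  on.exit(close(con))
  if (format == "OBJ") {
    writeLines("# flapsim surface mesh", con)
    writeLines(sprintf("v %.9g %.9g %.9g", m$pos[, 1], m$pos[, 2],
                       m$pos[, 3]), con)
    writeLines(sprintf("f %d %d %d", m$tris[, 1], m$tris[, 2],
                       m$tris[, 3]), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(m$pos)),
                 "property double x", "property double y",
                 "property double z",
                 paste("element face", nrow(m$tris)),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    writeLines(sprintf("%.9g %.9g %.9g", m$pos[, 1], m$pos[, 2],
                       m$pos[, 3]), con)
    writeLines(sprintf("3 %d %d %d", m$tris[, 1] - 1L, m$tris[, 2] - 1L,
                       m$tris[, 3] - 1L), con)
  }
  invisible(path)
}

event_to_list <- function(ev) {
  Filter(Negate(is.null),
         list(kind = ev$kind, vertex = ev$vertex, path = ev$path,
              region = ev$region, pair = ev$pair, specimen = ev$specimen,
              element = ev$element, target = ev$target, schema = 1L))
}

#' Write an event stream as JSON lines (one event per line)
#' @param events list of [interaction_event()]s
#' @param path output file
#' @export
write_events <- function(events, path) {
  lines <- vapply(events, function(ev)
    as.character(jsonlite::toJSON(event_to_list(ev), auto_unbox = TRUE,
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines event stream
#' @param path input file
#' @return list of [interaction_event()]s
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$kind) || !rec$kind %in% EVENT_KINDS)
      flapsim_error("flapsim_parse_error",
                    sprintf("malformed event record at line %d", i))
    interaction_event(rec$kind, vertex = rec$vertex, path = rec$path,
                      region = rec$region, pair = rec$pair,
                      specimen = rec$specimen, element = rec$element,
                      target = rec$target)
  })
}

#' Write a replay metrics bundle (JSON summary + gap-trace CSV)
#' @param metrics the `metrics` element returned by [run_script()]
#' @param dir output directory (created if missing)
#' @export
write_metrics <- function(metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- metrics[c("procedure", "final_stage", "state_hash",
                       "events_total", "events_rejected")]
  summary$max_strain <- unname(metrics$strain[["max_strain"]])
  summary$mean_strain <- unname(metrics$strain[["mean_strain"]])
  summary$wound_gap <- metrics$wound_gap
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- do.call(rbind, lapply(seq_along(metrics$gap_trace), function(i) {
    tr <- metrics$gap_trace[[i]]
    if (!is.null(tr$gaps))
      data.frame(record = i, stage = tr$stage, pair = seq_along(tr$gaps),
                 gap_mm = tr$gaps)
    else
      data.frame(record = i, stage = "SUTURE_TIGHTEN", pair = tr$pair,
                 gap_mm = tr$trace)
  }))
  if (!is.null(rows))
    utils::write.csv(rows, file.path(dir, "gap_trace.csv"),
                     row.names = FALSE)
  invisible(dir)
}
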