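#' @useDynLib flapsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Plane codes: SURFACE bounds the top (epidermis/dermis) tier above,
# INTERFACE separates the tiers, BASE bounds the fat tier below.
PLANES <- c(SURFACE = 1L, INTERFACE = 2L, BASE = 3L)
SPRING_CLASSES <- c(HORIZONTAL = 1L, VERTICAL = 2L, DIAGONAL = 3L)
TIERS <- c(TOP = 1L, BOTTOM = 2L)

plane_code <- function(plane) {
  if (is.character(plane)) {
    code <- PLANES[match(toupper(plane), names(PLANES))]
    if (anyNA(code)) stop("unknown plane: ", plane, call. = FALSE)
    unname(code)
  } else as.integer(plane)
}

#' Build a two-tier triangular-prism mass-spring skin lattice
#'
#' Constructs three congruent triangulated grids (SURFACE at z = 0,
#' INTERFACE at z = -top_thickness, BASE at z = -top_thickness -
#' bottom_thickness), each (rows+1) x (cols+1) points with every grid quad
#' split into two triangles along a consistent diagonal. Each triangle is
#' extruded into one TOP and one BOTTOM prism. Springs are derived from the
#' prisms: HORIZONTAL along triangle edges in each plane, VERTICAL between
#' vertically corresponding vertices of adjacent planes, DIAGONAL along both
#' diagonals of every rectangular prism side face, deduplicated across
#' shared faces. All rest lengths equal the as-built Euclidean distances,
#' so a fresh lattice is in exact equilibrium.
#'
#' The returned object is an environment with reference semantics: cutting,
#' suturing and dynamics operations mutate it in place, as is usual for
#' simulation state.
#'
#' @param rows,cols number of grid cells along y and x (>= 1)
#' @param spacing in-plane grid spacing, mm
#' @param top_thickness,bottom_thickness tier thicknesses, mm
#' @param mass_per_vertex point mass per vertex (arbitrary mass units)
#' @param stiffness_by_class named vector/list with entries HORIZONTAL,
#'   VERTICAL, DIAGONAL (force/length)
#' @param damping_by_class named vector/list, same names (force.time/length)
#' @param fix_base pin the BASE plane (the fat never moves; anchors the
#'   patch). Default TRUE.
#' @param fix_boundary additionally pin the outer boundary columns of all
#'   planes. Default FALSE.
#' @return a `skin_lattice` environment
#' @export
build_lattice <- function(rows, cols, spacing = 5,
                          top_thickness = 2, bottom_thickness = 4,
                          mass_per_vertex = 1,
                          stiffness_by_class = c(HORIZONTAL = 100,
                                                 VERTICAL = 100,
                                                 DIAGONAL = 50),
                          damping_by_class = c(HORIZONTAL = 5,
                                               VERTICAL = 5,
                                               DIAGONAL = 5),
                          fix_base = TRUE, fix_boundary = FALSE) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (spacing <= 0) stop("spacing must be > 0")
  if (top_thickness <= 0 || bottom_thickness <= 0)
    stop("tier thicknesses must be > 0")
  if (mass_per_vertex <= 0) stop("mass_per_vertex must be > 0")
  for (nm in names(SPRING_CLASSES)) {
    if (is.na(stiffness_by_class[nm]) || stiffness_by_class[[nm]] <= 0)
      stop("stiffness_by_class must have positive ", nm)
    if (is.na(damping_by_class[nm]) || damping_by_class[[nm]] < 0)
      stop("damping_by_class must have non-negative ", nm)
  }

  nr <- rows + 1L; nc <- cols + 1L
  npp <- nr * nc                       # points per plane
  n <- 3L * npp
  z_planes <- c(0, -top_thickness, -top_thickness - bottom_thickness)

  gc_col <- rep(rep(0:cols, times = nr), 3L)
  gc_row <- rep(rep(0:rows, each = nc), 3L)
  pos <- cbind(x = gc_col * spacing, y = gc_row * spacing,
               z = rep(z_planes, each = npp))
  plane <- rep(1:3, each = npp)

  lat <- new.env(parent = emptyenv())
  class(lat) <- "skin_lattice"
  lat$rows <- as.integer(rows); lat$cols <- as.integer(cols)
  lat$spacing <- spacing; lat$npp <- npp
  lat$top_thickness <- top_thickness; lat$bottom_thickness <- bottom_thickness
  lat$pos <- unname(pos)
  lat$vel <- matrix(0, n, 3)
  lat$mass <- rep(mass_per_vertex, n)
  lat$plane <- as.integer(plane)
  lat$fixed <- rep(FALSE, n)
  lat$alive <- rep(TRUE, n)
  lat$dup_of <- integer(n)             # 0 = original
  lat$k_by_class <- as.numeric(stiffness_by_class[names(SPRING_CLASSES)])
  lat$c_by_class <- as.numeric(damping_by_class[names(SPRING_CLASSES)])

  if (fix_base) lat$fixed[plane == PLANES[["BASE"]]] <- TRUE
  if (fix_boundary) {
    bnd <- gc_col == 0 | gc_col == cols | gc_row == 0 | gc_row == rows
    lat$fixed[bnd] <- TRUE
  }

  # grid vertex id in plane p (1..3), row r, col c (0-based)
  vid <- function(p, r, c) (p - 1L) * npp + r * nc + c + 1L

  # two triangles per quad; the split diagonal alternates with cell parity
  # (union-jack pattern) so snapped cut paths can follow either diagonal
  # direction and the surface metric is direction-isotropic
  cells <- expand.grid(r = 0:(rows - 1L), c = 0:(cols - 1L))
  even <- (cells$r + cells$c) %% 2L == 0L
  tri <- function(p) {
    r <- cells$r; c <- cells$c
    # even cells: diagonal (r,c)-(r+1,c+1); odd cells: (r+1,c)-(r,c+1)
    a <- vid(p, r, c); b <- vid(p, r + 1L, c)
    d <- vid(p, r + 1L, c + 1L); e <- vid(p, r, c + 1L)
    t_even <- rbind(cbind(a, b, d)[even, , drop = FALSE],
                    cbind(a, d, e)[even, , drop = FALSE])
    t_odd <- rbind(cbind(a, b, e)[!even, , drop = FALSE],
                   cbind(b, d, e)[!even, , drop = FALSE])
    rbind(t_even, t_odd)
  }
  s_tri <- tri(1L); i_tri <- tri(2L); b_tri <- tri(3L)
  ev <- rbind(cbind(s_tri, i_tri), cbind(i_tri, b_tri))
  lat$e_verts <- matrix(as.integer(ev), nrow(ev))
  lat$e_tier <- rep(c(TIERS[["TOP"]], TIERS[["BOTTOM"]]),
                    each = nrow(s_tri))
  lat$e_alive <- rep(TRUE, nrow(lat$e_verts))

  lat$s_i <- integer(0); lat$s_j <- integer(0)
  lat$s_rest <- numeric(0); lat$s_k <- numeric(0); lat$s_c <- numeric(0)
  lat$s_cls <- integer(0); lat$s_alive <- logical(0)

  lat$generation <- 0L
  lat$welds <- matrix(integer(0), 0, 2)
  lat$specimens <- list()
  lat$grabs <- list()
  lat$rigid_groups <- list()
  lat$sutures <- list()
  lat$suture_params <- SUTURE_DEFAULTS
  lat$cut_log <- character(0)
  lat$undermined <- list()
  lat$adj_generation <- -1L
  lat$adj <- NULL

  sync_springs(lat)
  lat$generation <- 1L
  lat
}

#' @export
print.skin_lattice <- function(x, ...) {
  cat(sprintf(
    "<skin_lattice> %dx%d cells, spacing %g mm | %d/%d vertices, %d/%d springs, %d/%d prisms alive | generation %d\n",
    x$rows, x$cols, x$spacing, sum(x$alive), length(x$alive),
    sum(x$s_alive), length(x$s_alive), sum(x$e_alive), length(x$e_alive),
    x$generation))
  invisible(x)
}

pair_key <- function(i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  paste0(a, "_", b)
}

# Follow dup_of chains back to the as-built original vertex id.
dup_root <- function(lat, v) {
  r <- v
  repeat {
    parent <- lat$dup_of[r]
    done <- parent == 0L
    if (all(done)) return(r)
    r[!done] <- parent[!done]
  }
}

# The 15 spring slots of one prism, as (column of upper idx, column of
# lower idx | class). Columns of e_verts: u1 u2 u3 l1 l2 l3.
PRISM_EDGES <- rbind(
  cbind(1L, 2L, SPRING_CLASSES[["HORIZONTAL"]]),
  cbind(2L, 3L, SPRING_CLASSES[["HORIZONTAL"]]),
  cbind(1L, 3L, SPRING_CLASSES[["HORIZONTAL"]]),
  cbind(4L, 5L, SPRING_CLASSES[["HORIZONTAL"]]),
  cbind(5L, 6L, SPRING_CLASSES[["HORIZONTAL"]]),
  cbind(4L, 6L, SPRING_CLASSES[["HORIZONTAL"]]),
  cbind(1L, 4L, SPRING_CLASSES[["VERTICAL"]]),
  cbind(2L, 5L, SPRING_CLASSES[["VERTICAL"]]),
  cbind(3L, 6L, SPRING_CLASSES[["VERTICAL"]]),
  cbind(1L, 5L, SPRING_CLASSES[["DIAGONAL"]]),   # side face (1,2)
  cbind(2L, 4L, SPRING_CLASSES[["DIAGONAL"]]),
  cbind(2L, 6L, SPRING_CLASSES[["DIAGONAL"]]),   # side face (2,3)
  cbind(3L, 5L, SPRING_CLASSES[["DIAGONAL"]]),
  cbind(1L, 6L, SPRING_CLASSES[["DIAGONAL"]]),   # side face (1,3)
  cbind(3L, 4L, SPRING_CLASSES[["DIAGONAL"]])
)

# Endpoint pairs + classes required by the alive prism elements,
# deduplicated across shared faces.
required_spring_pairs <- function(lat) {
  ev <- lat$e_verts[lat$e_alive, , drop = FALSE]
  if (nrow(ev) == 0)
    return(list(i = integer(0), j = integer(0), cls = integer(0)))
  i <- as.vector(ev[, PRISM_EDGES[, 1]])
  j <- as.vector(ev[, PRISM_EDGES[, 2]])
  cls <- rep(PRISM_EDGES[, 3], each = nrow(ev))
  a <- pmin(i, j); b <- pmax(i, j)
  keep <- !duplicated(paste0(a, "_", b))
  list(i = a[keep], j = b[keep], cls = cls[keep])
}

# Reconcile the spring set against the alive elements: create springs for
# newly required endpoint pairs (properties inherited from the ancestral
# pair through dup_of chains, so pre-tensioned rest lengths survive
# duplication), tombstone springs whose pair is no longer element-backed.
sync_springs <- function(lat) {
  req <- required_spring_pairs(lat)
  req_key <- pair_key(req$i, req$j)

  alive_idx <- which(lat$s_alive)
  alive_key <- pair_key(lat$s_i[alive_idx], lat$s_j[alive_idx])

  severed <- alive_idx[!(alive_key %in% req_key)]
  if (length(severed)) lat$s_alive[severed] <- FALSE

  new_sel <- !(req_key %in% alive_key)
  created <- integer(0)
  if (any(new_sel)) {
    ni <- req$i[new_sel]; nj <- req$j[new_sel]; ncls <- req$cls[new_sel]
    if (length(lat$s_i)) {
      # ancestral lookup: root pair of every historic spring
      hist_key <- pair_key(dup_root(lat, lat$s_i), dup_root(lat, lat$s_j))
      anc <- match(pair_key(dup_root(lat, ni), dup_root(lat, nj)), hist_key)
      rest <- ifelse(is.na(anc), NA_real_, lat$s_rest[anc])
      kk <- ifelse(is.na(anc), NA_real_, lat$s_k[anc])
      cc <- ifelse(is.na(anc), NA_real_, lat$s_c[anc])
      cls_in <- ifelse(is.na(anc), ncls, lat$s_cls[anc])
    } else {
      rest <- kk <- cc <- rep(NA_real_, length(ni)); cls_in <- ncls
    }
    miss <- is.na(rest)
    if (any(miss)) {  # as-built springs: rest = current distance
      d <- lat$pos[ni[miss], , drop = FALSE] - lat$pos[nj[miss], , drop = FALSE]
      rest[miss] <- sqrt(rowSums(d^2))
      kk[miss] <- lat$k_by_class[ncls[miss]]
      cc[miss] <- lat$c_by_class[ncls[miss]]
    }
    created <- length(lat$s_i) + seq_along(ni)
    lat$s_i <- c(lat$s_i, as.integer(ni))
    lat$s_j <- c(lat$s_j, as.integer(nj))
    lat$s_rest <- c(lat$s_rest, rest)
    lat$s_k <- c(lat$s_k, kk); lat$s_c <- c(lat$s_c, cc)
    lat$s_cls <- c(lat$s_cls, as.integer(cls_in))
    lat$s_alive <- c(lat$s_alive, rep(TRUE, length(ni)))
  }
  invisible(list(severed = severed, created = created))
}

#' Pre-tension the horizontal springs of one plane
#'
#' Shortens the rest length of every alive HORIZONTAL spring whose both
#' endpoints lie in the given plane to `factor` times its current endpoint
#' distance. With the default factor 0.9 on the SURFACE plane this puts the
#' epidermis sheet under baseline tension, so incised wounds gape open when
#' the lattice is relaxed -- the mechanism behind realistic wound opening.
#'
#' @param lattice a `skin_lattice`
#' @param factor ratio in (0, 1]; 0.9 reproduces natural skin tension
#' @param plane "SURFACE", "INTERFACE" or "BASE"
#' @return number of springs modified (invisibly the lattice is mutated)
#' @export
apply_pretension <- function(lattice, factor = 0.9, plane = "SURFACE") {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]")
  p <- plane_code(plane)
  sel <- which(lattice$s_alive &
                 lattice$s_cls == SPRING_CLASSES[["HORIZONTAL"]] &
                 lattice$plane[lattice$s_i] == p &
                 lattice$plane[lattice$s_j] == p)
  if (length(sel)) {
    d <- lattice$pos[lattice$s_i[sel], , drop = FALSE] -
      lattice$pos[lattice$s_j[sel], , drop = FALSE]
    lattice$s_rest[sel] <- factor * sqrt(rowSums(d^2))
  }
  length(sel)
}

# Lazily cached vertex -> incident alive spring index, invalidated by the
# generation counter on every topology change.
get_adjacency <- function(lat) {
  if (!identical(lat$adj_generation, lat$generation)) {
    idx <- which(lat$s_alive)
    v <- c(lat$s_i[idx], lat$s_j[idx])
    lat$adj <- split(rep(idx, 2L), v)
    lat$adj_generation <- lat$generation
  }
  lat$adj
}

incident_springs <- function(lat, v) {
  adj <- get_adjacency(lat)
  unique(unlist(adj[as.character(v)], use.names = FALSE))
}

# The vertically corresponding vertex one plane below (or above) v,
# found through the alive VERTICAL spring.
vertical_partner <- function(lat, v, below = TRUE) {
  sp <- incident_springs(lat, v)
  sp <- sp[lat$s_cls[sp] == SPRING_CLASSES[["VERTICAL"]]]
  other <- ifelse(lat$s_i[sp] == v, lat$s_j[sp], lat$s_i[sp])
  want <- lat$plane[v] + if (below) 1L else -1L
  hit <- other[lat$plane[other] == want]
  if (length(hit) == 0) NA_integer_ else as.integer(hit[[1]])
}

# Elements (row indices) whose vertex tuple contains v, alive only.
elements_with_vertex <- function(lat, v, tier = NULL) {
  hit <- which(lat$e_alive & rowSums(matrix(lat$e_verts %in% v,
                                            nrow(lat$e_verts))) > 0)
  if (!is.null(tier)) hit <- hit[lat$e_tier[hit] == TIERS[[tier]]]
  hit
}

element_centroid <- function(lat, e) {
  colMeans(lat$pos[lat$e_verts[e, ], , drop = FALSE])
}

#' Validate lattice structural invariants
#'
#' Checks that alive springs join distinct alive vertices, that no two
#' alive springs share an endpoint pair, that every alive prism edge is
#' backed by an alive spring, that masses are positive and that fixed
#' vertices have zero velocity. Stops with a message on the first
#' violation.
#'
#' @param lattice a `skin_lattice`
#' @return TRUE invisibly
#' @export
validate_lattice <- function(lattice) {
  lat <- lattice
  if (any(lat$mass <= 0)) stop("non-positive vertex mass")
  if (any(abs(lat$vel[lat$fixed & lat$alive, ]) > 0))
    stop("fixed vertex with non-zero velocity")
  idx <- which(lat$s_alive)
  if (any(lat$s_i[idx] == lat$s_j[idx])) stop("degenerate spring endpoints")
  if (!all(lat$alive[lat$s_i[idx]] & lat$alive[lat$s_j[idx]]))
    stop("alive spring references tombstoned vertex")
  key <- pair_key(lat$s_i[idx], lat$s_j[idx])
  if (anyDuplicated(key)) stop("duplicate alive spring pair")
  if (any(lat$s_rest[idx] <= 0) || any(lat$s_k[idx] <= 0) ||
      any(lat$s_c[idx] < 0))
    stop("invalid spring constants")
  ev <- lat$e_verts[lat$e_alive, , drop = FALSE]
  if (nrow(ev)) {
    if (!all(lat$alive[as.vector(ev)])) stop("alive element references tombstoned vertex")
    if (any(apply(ev, 1, anyDuplicated) > 0)) stop("element with repeated vertex")
    req <- required_spring_pairs(lat)
    if (!all(pair_key(req$i, req$j) %in% key))
      stop("prism edge not backed by an alive spring")
  }
  invisible(TRUE)
}

# Counts used throughout the package and tests.
alive_counts <- function(lat) {
  c(vertices = sum(lat$alive), springs = sum(lat$s_alive),
    elements = sum(lat$e_alive))
}

# SURFACE ids of the as-built grid, row-major; helper for plans/tests.
surface_grid_ids <- function(lat) seq_len(lat$npp)

surface_vertex_at <- function(lat, r, c) {
  r * (lat$cols + 1L) + c + 1L
}
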