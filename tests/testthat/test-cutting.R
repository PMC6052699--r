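open_path <- function(lat, r, c0, len, through = FALSE) {
  v0 <- flapsim:::surface_vertex_at(lat, r, c0)
  list(vertices = v0 + 0:(len - 1L), closed = FALSE,
       through_thickness = through)
}

test_that("open vertical cut duplicates 2 (L-2) vertices, top tier only", {
  for (L in c(3L, 4L, 6L)) {
    lat <- build_lattice(6, 6)
    rep <- vertical_cut(lat, open_path(lat, 3L, 0L, L))
    expect_length(rep$duplicated_vertices, 2L * (L - 2L))
    expect_valid_lattice(lat)
  }
})

test_that("a two-vertex open path is a degenerate taper: no duplication", {
  lat <- build_lattice(4, 4)
  n0 <- sum(lat$s_alive)
  rep <- vertical_cut(lat, open_path(lat, 2L, 1L, 2L))
  expect_length(rep$duplicated_vertices, 0)
  expect_length(rep$severed_springs, 0)
  expect_identical(sum(lat$s_alive), n0)
})

test_that("cuts conserve elements and never orphan springs", {
  lat <- build_lattice(6, 6)
  e0 <- sum(lat$e_alive)
  vertical_cut(lat, open_path(lat, 3L, 1L, 5L))
  expect_identical(sum(lat$e_alive), e0)
  expect_valid_lattice(lat)
  # cut locality: only vertices incident to the path may move, and the
  # topology edit itself moves nothing at all
  lat2 <- build_lattice(6, 6)
  p0 <- lat2$pos
  vertical_cut(lat2, open_path(lat2, 2L, 0L, 4L))
  expect_identical(lat2$pos[seq_len(nrow(p0)), ], p0)
})

test_that("re-cutting a severed path is a reported no-op", {
  lat <- build_lattice(6, 6)
  path <- open_path(lat, 3L, 1L, 4L)
  r1 <- vertical_cut(lat, path)
  expect_false(r1$noop)
  h1 <- state_hash(lat)
  r2 <- vertical_cut(lat, path)
  expect_true(r2$noop)
  expect_identical(state_hash(lat), h1)
})

test_that("closed through cut separates the region into its own component", {
  lat <- build_lattice(6, 6)
  plan <- plan_ellipse(lat, c(15, 15), 4, ratio = 2.5)
  vertical_cut(lat, plan$cut_paths[[1]])
  expect_valid_lattice(lat)
  comp <- oracle_components(lat)
  ext <- flapsim:::specimen_extent(lat, plan$excision_region)
  inside <- comp[as.character(ext$vertices)]
  outside <- comp[as.character(setdiff(which(lat$alive), ext$vertices))]
  expect_length(unique(inside), 1)
  expect_false(unique(inside) %in% unique(outside))
})

test_that("cut path validation catches bad inputs", {
  lat <- build_lattice(4, 4)
  v0 <- flapsim:::surface_vertex_at(lat, 1L, 0L)
  non_adj <- list(vertices = c(v0, v0 + 3L), closed = FALSE,
                  through_thickness = FALSE)
  expect_error(vertical_cut(lat, non_adj), class = "flapsim_topology_error")
  lat$alive[v0] <- FALSE
  dead <- list(vertices = c(v0, v0 + 1L), closed = FALSE,
               through_thickness = FALSE)
  expect_error(vertical_cut(lat, dead), class = "flapsim_topology_error")
})

test_that("undermining severs exactly the interior interface-to-fat springs", {
  lat <- build_lattice(10, 10)
  plan <- plan_h_flap(lat, c(25, 25), 10, 5)
  for (p in plan$cut_paths) vertical_cut(lat, p)
  region <- plan$undermining_region
  # oracle before the op: interior INTERFACE vertices are those whose every
  # incident alive TOP element lies in the region
  ifc <- unique(as.vector(lat$e_verts[region, 4:6]))
  interior <- ifc[vapply(ifc, function(v) {
    els <- which(lat$e_alive &
                   rowSums(matrix(lat$e_verts == v, nrow(lat$e_verts))) > 0 &
                   lat$e_tier == 1L)
    length(els) > 0 && all(els %in% region)
  }, logical(1))]
  idx <- which(lat$s_alive)
  expected_severed <- idx[xor(lat$s_i[idx] %in% interior,
                              lat$s_j[idx] %in% interior) &
                            (lat$plane[lat$s_i[idx]] == 3L |
                               lat$plane[lat$s_j[idx]] == 3L)]
  rep <- undermine(lat, region)
  expect_valid_lattice(lat)
  expect_length(rep$duplicated_vertices, length(interior))
  severed_to_base <- rep$severed_springs[
    lat$plane[lat$s_i[rep$severed_springs]] == 3L |
      lat$plane[lat$s_j[rep$severed_springs]] == 3L]
  expect_setequal(severed_to_base, expected_severed)
  # flap-side interface vertices keep no alive spring to the BASE plane
  for (v in interior) {
    inc <- flapsim:::incident_springs(lat, v)
    other <- ifelse(lat$s_i[inc] == v, lat$s_j[inc], lat$s_i[inc])
    expect_false(any(lat$plane[other] == 3L))
  }
})

test_that("undermining an empty region changes nothing", {
  lat <- build_lattice(4, 4)
  h0 <- state_hash(lat)
  rep <- undermine(lat, integer(0))
  expect_true(rep$noop)
  expect_identical(state_hash(lat), h0)
})

test_that("excise demands full detachment and then partitions the tissue", {
  lat <- build_lattice(6, 6)
  plan <- plan_ellipse(lat, c(15, 15), 4, ratio = 2.5)
  expect_error(excise(lat, plan), class = "flapsim_precondition_error")
  err <- tryCatch(excise(lat, plan), flapsim_precondition_error = identity)
  expect_gt(length(err$attaching_springs), 0)
  vertical_cut(lat, plan$cut_paths[[1]])
  id <- excise(lat, plan)
  sp <- lat$specimens[[id]]
  expect_identical(sort(intersect(plan$excision_region, sp$elements)),
                   sort(plan$excision_region))
  # specimen vertices and remainder partition the alive vertices
  expect_length(intersect(sp$vertices, setdiff(which(lat$alive),
                                               sp$vertices)), 0)
  expect_setequal(c(sp$vertices, setdiff(which(lat$alive), sp$vertices)),
                  which(lat$alive))
})
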