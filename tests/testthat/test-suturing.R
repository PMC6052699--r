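# A wounded TINY ellipse scene ready for suturing.
sutured_scene <- function(pretension = 0.9) {
  cfg <- sim_config()
  lat <- build_lattice(6, 6)
  if (pretension < 1) {
    apply_pretension(lat, pretension, "SURFACE")
    relax(lat, cfg)
  }
  plan <- plan_ellipse(lat, c(15, 15), 4, ratio = 2.5)
  vertical_cut(lat, plan$cut_paths[[1]])
  relax(lat, cfg)
  id <- excise(lat, plan)
  remove_excised(lat, id)
  relax(lat, cfg)
  list(lat = lat, plan = plan, cfg = cfg)
}

test_that("elliptical closure pairs are BOTH_PULL; tightening closes them", {
  sc <- sutured_scene()
  s <- place_suture(sc$lat, sc$plan, 1L)
  expect_identical(s$mode, "BOTH_PULL")
  expect_identical(s$status, "PLACED")
  out <- tighten(sc$lat, 1L, sc$cfg)
  expect_identical(out$status, "CLOSED")
  rp <- sc$lat$sutures[[1]]
  gap <- sqrt(sum((sc$lat$pos[rp$free, ] - sc$lat$pos[rp$anchor, ])^2))
  expect_lte(gap, 0.1)
  # the gap trace shrinks monotonically under quasi-static tightening
  expect_true(all(diff(out$gap_trace) <= sc$cfg$displacement_tolerance))
})

test_that("suture ordering is enforced wound-centre outward", {
  sc <- sutured_scene()
  expect_error(place_suture(sc$lat, sc$plan, 2L),
               class = "flapsim_ordering_error")
  place_suture(sc$lat, sc$plan, 1L)
  tighten(sc$lat, 1L, sc$cfg)
  expect_silent(place_suture(sc$lat, sc$plan, 2L))
})

test_that("a pair already within tolerance closes with an empty schedule", {
  sc <- sutured_scene()
  pair <- sc$plan$suture_pairs[1, ]
  sc$lat$pos[pair[1], ] <- sc$lat$pos[pair[2], ] + c(0.01, 0, 0)
  place_suture(sc$lat, sc$plan, 1L)
  out <- tighten(sc$lat, 1L, sc$cfg)
  expect_identical(out$status, "CLOSED")
  expect_length(out$gap_trace, 0)
})

test_that("welded pairs never separate in later relaxations", {
  sc <- sutured_scene()
  for (k in seq_len(nrow(sc$plan$suture_pairs))) {
    place_suture(sc$lat, sc$plan, k)
    tighten(sc$lat, k, sc$cfg)
  }
  # disturb and relax again
  free <- which(!sc$lat$fixed & sc$lat$alive)
  sc$lat$pos[free, 3] <- sc$lat$pos[free, 3] + 0.2
  relax(sc$lat, sc$cfg)
  gaps <- wound_gap(sc$lat, sc$plan)
  expect_true(all(gaps <= 0.05 + sc$cfg$displacement_tolerance))
})

test_that("rotation-plan sutures fix the defect-edge anchor", {
  cfg <- sim_config()
  fix <- generate_fixture("ROTATION", "TINY")
  scene <- fixture_scene(fix, cfg)
  lat <- scene$lattice
  plan <- scene$plan
  for (p in plan$cut_paths) vertical_cut(lat, p)
  relax(lat, cfg)
  excise(lat, plan)
  undermine(lat, plan$undermining_region)
  relax(lat, cfg)
  remove_excised(lat, 1L)
  relax(lat, cfg)
  s <- place_suture(lat, plan, 1L)
  expect_identical(s$mode, "ANCHOR_FIXED")
  expect_true(lat$fixed[s$anchor])
  anchor_p0 <- lat$pos[s$anchor, ]
  out <- tighten(lat, 1L, cfg)
  expect_identical(out$status, "CLOSED")
  expect_lte(sqrt(sum((lat$pos[s$anchor, ] - anchor_p0)^2)),
             cfg$displacement_tolerance)
})

test_that("rigidified chains move isometrically under perturbation", {
  cfg <- sim_config()
  lat <- build_lattice(6, 6)
  apply_pretension(lat, 0.9, "SURFACE")
  v0 <- flapsim:::surface_vertex_at(lat, 2L, 1L)
  chain <- v0 + 0:3
  g <- rigidify_edge(lat, chain)
  d0 <- as.matrix(stats::dist(lat$pos[chain, ]))
  relax(lat, cfg)
  d1 <- as.matrix(stats::dist(lat$pos[chain, ]))
  expect_equal(d1, d0, tolerance = 1e-6)
  # two-point chain: separation preserved exactly by the rigid fit
  lat2 <- build_lattice(3, 3)
  apply_pretension(lat2, 0.85, "SURFACE")
  ch2 <- c(1L, 2L)
  rigidify_edge(lat2, ch2)
  sep0 <- sqrt(sum((lat2$pos[1, ] - lat2$pos[2, ])^2))
  relax(lat2, cfg)
  sep1 <- sqrt(sum((lat2$pos[1, ] - lat2$pos[2, ])^2))
  expect_equal(sep1, sep0, tolerance = 1e-9)
})

test_that("deactivated rigidity restores plain spring dynamics", {
  mk <- function(rigidify) {
    lat <- build_lattice(4, 4)
    apply_pretension(lat, 0.9, "SURFACE")
    if (rigidify) {
      g <- rigidify_edge(lat, 1:3)
      release_rigid(lat, g)
    }
    relax(lat, sim_config())
    lat$pos
  }
  expect_identical(mk(TRUE), mk(FALSE))
})

test_that("rigid chain argument validation", {
  lat <- build_lattice(2, 2)
  expect_error(rigidify_edge(lat, 1L), class = "flapsim_argument_error")
  expect_error(rigidify_edge(lat, c(1L, 1L, 2L)),
               class = "flapsim_argument_error")
})

test_that("apposition testing reports gaps and restores the prior state", {
  cfg <- sim_config()
  fix <- generate_fixture("ROTATION", "TINY")
  scene <- fixture_scene(fix, cfg)
  lat <- scene$lattice; plan <- scene$plan
  expect_error(apposition_test(lat, plan, cfg),
               class = "flapsim_precondition_error")
  for (p in plan$cut_paths) vertical_cut(lat, p)
  relax(lat, cfg)
  excise(lat, plan)
  undermine(lat, plan$undermining_region)
  relax(lat, cfg)
  remove_excised(lat, 1L)
  relax(lat, cfg)
  h0 <- state_hash(lat, quantum = 0.05)
  ref <- lat$pos[plan$rigid_edge_chain, ]
  d0 <- as.matrix(stats::dist(ref))
  gaps <- apposition_test(lat, plan, cfg)
  expect_true(all(is.finite(gaps)))
  expect_gt(length(gaps), 0)
  # rigid chain kept its shape through the test, and the state came back
  d1 <- as.matrix(stats::dist(lat$pos[plan$rigid_edge_chain, ]))
  expect_equal(d1, d0, tolerance = 1e-4)
  expect_identical(state_hash(lat, quantum = 0.05), h0)
})
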