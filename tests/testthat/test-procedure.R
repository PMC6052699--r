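tiny_ellipse_scene <- function() {
  fix <- generate_fixture("ELLIPSE", "TINY")
  list(fix = fix, scene = fixture_scene(fix))
}

test_that("events in the wrong stage are rejected without tissue change", {
  ts <- tiny_ellipse_scene()
  st <- procedure_state(ts$scene$lattice, ts$scene$plan, ts$scene$config)
  expect_identical(st$stage, "ASSESS")
  h0 <- state_hash(st$lattice)
  advance(st, interaction_event("CUT", path = 1L))
  last <- st$event_log[[length(st$event_log)]]
  expect_identical(last$outcome, "rejected")
  expect_gt(nchar(last$feedback), 0)
  expect_identical(state_hash(st$lattice), h0)
  expect_identical(st$stage, "ASSESS")
})

test_that("off-plan interactions are flagged and change nothing", {
  ts <- tiny_ellipse_scene()
  st <- procedure_state(ts$scene$lattice, ts$scene$plan, ts$scene$config)
  advance(st, interaction_event("ADVANCE"))
  expect_identical(st$stage, "MARK")
  h0 <- state_hash(st$lattice)
  off <- setdiff(seq_len(st$lattice$npp),
                 ts$scene$plan$allowed_vertices_by_stage$MARK)[1]
  advance(st, interaction_event("MARK", vertex = off))
  last <- st$event_log[[length(st$event_log)]]
  expect_identical(last$outcome, "rejected")
  expect_identical(state_hash(st$lattice), h0)
})

test_that("an empty script stays in ASSESS with zero metrics", {
  ts <- tiny_ellipse_scene()
  out <- run_script(ts$scene$lattice, ts$scene$plan, list(),
                    ts$scene$config)
  expect_identical(out$metrics$final_stage, "ASSESS")
  expect_identical(out$metrics$events_total, 0L)
  expect_identical(out$metrics$events_rejected, 0L)
})

test_that("all three TINY golden scripts complete deterministically", {
  for (p in c("ELLIPSE", "H_FLAP", "ROTATION")) {
    fix <- generate_fixture(p, "TINY")
    r1 <- replay_fixture(fix)
    expect_identical(r1$metrics$final_stage, "COMPLETE")
    expect_identical(r1$metrics$events_rejected, 0L)
    # every suture closed, specimen gone
    lat <- r1$state$lattice
    n_pairs <- nrow(r1$state$plan$suture_pairs)
    expect_true(all(vapply(seq_len(n_pairs), function(k)
      lat$sutures[[k]]$status == "CLOSED", logical(1))))
    expect_false(any(lat$e_alive[lat$specimens[[1]]$elements]))
    r2 <- replay_fixture(fix)
    expect_identical(r2$metrics$state_hash, r1$metrics$state_hash)
  }
})

test_that("stage order is monotone along a golden replay", {
  fix <- generate_fixture("ELLIPSE", "TINY")
  scene <- fixture_scene(fix)
  st <- procedure_state(scene$lattice, scene$plan, scene$config)
  trace <- character(0)
  for (ev in fix$events) {
    advance(st, ev)
    trace <- c(trace, st$stage)
  }
  idx <- match(trace, st$stages)
  expect_true(all(diff(idx) >= 0))
  expect_identical(trace[length(trace)], "COMPLETE")
})

test_that("dropping a required suture event stalls in SUTURE", {
  fix <- generate_fixture("ELLIPSE", "TINY")
  is_tighten <- vapply(fix$events, function(e)
    e$kind == "SUTURE_TIGHTEN", logical(1))
  drop <- utils::tail(which(is_tighten), 1)
  dropped_pair <- fix$events[[drop]]$pair
  fix$events <- fix$events[-drop]
  res <- replay_fixture(fix)
  expect_identical(res$metrics$final_stage, "SUTURE")
  lat <- res$state$lattice
  status <- vapply(seq_len(nrow(res$state$plan$suture_pairs)), function(k) {
    s <- if (k <= length(lat$sutures)) lat$sutures[[k]] else NULL
    if (is.null(s)) "ABSENT" else s$status
  }, character(1))
  expect_true(all(status[-dropped_pair] == "CLOSED"))
  expect_false(status[dropped_pair] == "CLOSED")
})

test_that("dropping the removal event stalls before wound closure", {
  fix <- generate_fixture("ELLIPSE", "TINY")
  is_rm <- vapply(fix$events, function(e) e$kind == "REMOVE", logical(1))
  fix$events <- fix$events[-which(is_rm)]
  res <- replay_fixture(fix)
  expect_identical(res$metrics$final_stage, "REMOVE_SPECIMEN")
})

test_that("wound gaps reflect cutting and closure", {
  fix <- generate_fixture("ELLIPSE", "TINY")
  scene <- fixture_scene(fix)
  lat <- scene$lattice; plan <- scene$plan; cfg <- scene$config
  pre <- wound_gap(lat, plan)
  expect_true(all(pre > 0))
  vertical_cut(lat, plan$cut_paths[[1]])
  relax(lat, cfg)
  excise(lat, plan)
  remove_excised(lat, 1L)
  relax(lat, cfg)
  post <- wound_gap(lat, plan)
  expect_true(all(post > pre))          # pre-tension makes the wound gape
  for (k in seq_len(nrow(plan$suture_pairs))) {
    place_suture(lat, plan, k)
    tighten(lat, k, cfg)
  }
  expect_true(all(wound_gap(lat, plan) <= 0.1))
})

test_that("exhaustive orderings on a minimal alphabet: completion needs every required event", {
  # minimal macro-event alphabet for the TINY ellipse: cut, free+remove
  # specimen (fused), suture pair k (place+tighten fused). COMPLETE must be
  # reached exactly when the script contains cut before removal before all
  # sutures -- verified by replaying every permutation of the macro events.
  fix <- generate_fixture("ELLIPSE", "TINY")
  scene0 <- fixture_scene(fix)
  n_pairs <- nrow(scene0$plan$suture_pairs)
  mark_events <- Filter(function(e) e$kind %in% c("TOGGLE_LANGER", "ADVANCE",
                                                  "MARK"),
                        fix$events[seq_len(2 + length(
                          scene0$plan$allowed_vertices_by_stage$MARK))])
  macro <- list(
    cut = list(interaction_event("CUT", path = 1L),
               interaction_event("ADVANCE")),
    rm = list(interaction_event("GRAB", specimen = 1L,
                                target = c(15, 15, 0)),
              interaction_event("REMOVE", specimen = 1L)),
    sut = unlist(lapply(seq_len(n_pairs), function(k)
      list(interaction_event("SUTURE_PLACE", pair = k),
           interaction_event("SUTURE_TIGHTEN", pair = k))),
      recursive = FALSE))
  perms <- list(c("cut", "rm", "sut"), c("cut", "sut", "rm"),
                c("rm", "cut", "sut"), c("rm", "sut", "cut"),
                c("sut", "cut", "rm"), c("sut", "rm", "cut"))
  for (ord in perms) {
    scene <- fixture_scene(fix)
    events <- c(mark_events, unlist(lapply(ord, function(k) macro[[k]]),
                                    recursive = FALSE))
    res <- run_script(scene$lattice, scene$plan, events, scene$config)
    if (identical(ord, c("cut", "rm", "sut"))) {
      expect_identical(res$metrics$final_stage, "COMPLETE")
    } else {
      expect_false(identical(res$metrics$final_stage, "COMPLETE"))
    }
  }
})
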