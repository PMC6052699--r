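# Plan geometry on an unrelaxed lattice is purely combinatorial, so these
# tests run on modest grids without any dynamics.

fresh <- function(rows = 12, cols = 12) build_lattice(rows, cols, spacing = 5)

test_that("plans are pure functions of lattice and parameters", {
  lat1 <- fresh(); lat2 <- fresh()
  p1 <- plan_ellipse(lat1, c(30, 30), 6)
  p2 <- plan_ellipse(lat2, c(30, 30), 6)
  expect_identical(p1$cut_paths, p2$cut_paths)
  expect_identical(p1$suture_pairs, p2$suture_pairs)
  expect_identical(p1$excision_region, p2$excision_region)
})

test_that("ellipse loop is connected, alive, and keeps the 3:1 template shape", {
  lat <- build_lattice(20, 20, spacing = 5)
  plan <- plan_ellipse(lat, c(50, 50), 8, ratio = 3)
  loop <- plan$cut_paths[[1]]$vertices
  expect_true(plan$cut_paths[[1]]$closed)
  # every consecutive pair (including the wrap) joined by an alive spring
  keys <- alive_spring_keys(lat)
  nxt <- c(loop[-1], loop[1])
  expect_true(all(paste0(pmin(loop, nxt), "_", pmax(loop, nxt)) %in% keys))
  expect_true(all(lat$alive[loop]))
  # snapped bounding box aspect ratio within 20% of the template's 3:1
  xy <- lat$pos[loop, 1:2]
  aspect <- diff(range(xy[, 1])) / diff(range(xy[, 2]))
  expect_gt(aspect, 3 * 0.8)
  expect_lt(aspect, 3 * 1.2)
  # no fixed or rigid edges in simple closure; excision region non-empty
  expect_length(plan$fixed_edge_vertices, 0)
  expect_length(plan$rigid_edge_chain, 0)
  expect_gt(length(plan$excision_region), 0)
})

test_that("ellipse suture pairs straddle the long axis, ordered centre-out", {
  lat <- fresh()
  plan <- plan_ellipse(lat, c(30, 30), 6)
  sp <- plan$suture_pairs
  expect_gt(nrow(sp), 1)
  wf <- lat$pos[sp[, 1], 2] - 30
  wa <- lat$pos[sp[, 2], 2] - 30
  expect_true(all(wf > 0 & wa < 0))     # opposite sides of the axis
  tt <- abs(lat$pos[sp[, 1], 1] - 30)
  expect_true(all(diff(tt) >= -1e-9))   # centre outward
})

test_that("degenerate ellipse geometry raises a planning error", {
  lat <- fresh()
  expect_error(plan_ellipse(lat, c(30, 30), 1), class = "flapsim_planning_error")
  expect_error(plan_ellipse(lat, c(58, 30), 6), class = "flapsim_planning_error")
})

test_that("H-flap flaps are disjoint, edge-connected rectangles", {
  lat <- fresh(14, 14)
  plan <- plan_h_flap(lat, c(35, 35), 10, 15)
  expect_identical(plan$procedure, "H_FLAP")
  expect_length(plan$cut_paths, 5)      # square + 4 limbs
  # split the undermining region into the two flap rectangles by x
  und <- plan$undermining_region
  cx <- vapply(und, function(e) mean(lat$pos[lat$e_verts[e, 1:3], 1]),
               numeric(1))
  left <- und[cx < 35]; right <- und[cx > 35]
  expect_gt(length(left), 0)
  expect_gt(length(right), 0)
  expect_length(intersect(left, right), 0)
  # region-growing oracle: each flap is edge-connected over shared vertices
  grow <- function(els) {
    seen <- els[1]; frontier <- els[1]
    while (length(frontier)) {
      vs <- unique(as.vector(lat$e_verts[frontier, ]))
      nxt <- setdiff(els[vapply(els, function(e)
        any(lat$e_verts[e, ] %in% vs), logical(1))], seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(els)
  }
  expect_true(grow(left))
  expect_true(grow(right))
})

test_that("H-flap defect outline matches an independent enumeration", {
  lat <- fresh(14, 14)
  h <- 10
  plan <- plan_h_flap(lat, c(35, 35), h, 15)
  outline <- plan$cut_paths[[1]]$vertices
  # brute force: all as-built surface vertices lying on the square frame
  surf <- which(lat$plane == 1L)
  on_frame <- surf[vapply(surf, function(v) {
    x <- lat$pos[v, 1]; y <- lat$pos[v, 2]
    onv <- (abs(x - 25) < 1e-9 | abs(x - 45) < 1e-9) &
      y >= 25 - 1e-9 & y <= 45 + 1e-9
    onh <- (abs(y - 25) < 1e-9 | abs(y - 45) < 1e-9) &
      x >= 25 - 1e-9 & x <= 45 + 1e-9
    onv || onh
  }, logical(1))]
  expect_setequal(outline, on_frame)
})

test_that("H-flap with zero limb length degenerates to direct closure", {
  lat <- fresh(14, 14)
  plan <- plan_h_flap(lat, c(35, 35), 10, 0)
  expect_length(plan$cut_paths, 1)
  expect_length(plan$undermining_region, 0)
  expect_true(all(plan$suture_pairs[, 1] != plan$suture_pairs[, 2]))
})

test_that("rotation arc length approximates the continuous arc", {
  # fine lattice: staircase inflation of the snapped polyline shrinks with
  # the spacing
  lat <- build_lattice(40, 40, spacing = 2.5)
  plan <- plan_rotation(lat, c(50, 65), 10, 25, 180)
  arc <- plan$cut_paths[[2]]$vertices
  seg <- lat$pos[arc[-1], 1:2] - lat$pos[arc[-length(arc)], 1:2]
  polylen <- sum(sqrt(rowSums(seg^2)))
  expect_lt(abs(polylen - pi * 25) / (pi * 25), 0.15)
})

test_that("rotation rigid chain and fixed edge sit on the defect outline", {
  lat <- build_lattice(20, 20, spacing = 5)
  plan <- plan_rotation(lat, c(50, 65), 10, 25, 180)
  outline <- plan$cut_paths[[1]]$vertices
  expect_true(all(plan$fixed_edge_vertices %in% outline))
  expect_true(all(plan$rigid_edge_chain %in% outline))
  # contiguity: consecutive chain vertices adjacent on the outline cycle
  n <- length(outline)
  posn <- match(plan$rigid_edge_chain, outline)
  gaps <- (diff(posn)) %% n
  expect_true(all(gaps %in% c(1L, n - 1L)))
  # apposition pairs: free on the leading (flap) side, anchor on the fixed
  sp <- plan$suture_pairs
  app <- sp[sp[, 1] != sp[, 2], , drop = FALSE]
  expect_true(all(app[, 2] %in% plan$fixed_edge_vertices))
  expect_gt(length(plan$undermining_region), 0)
})

test_that("interaction gate equals explicit allowed-set membership", {
  lat <- fresh()
  plan <- plan_ellipse(lat, c(30, 30), 6)
  for (stage in names(plan$allowed_vertices_by_stage)) {
    allowed <- plan$allowed_vertices_by_stage[[stage]]
    probe <- unique(c(allowed, setdiff(seq_len(50), allowed)))
    for (v in probe) {
      g <- interaction_gate(plan, stage, v)
      expect_identical(g$allowed, v %in% allowed)
      if (!g$allowed) expect_gt(nchar(g$feedback), 0) else
        expect_identical(g$feedback, "")
    }
  }
  expect_error(interaction_gate(plan, "NOT_A_STAGE", 1),
               class = "flapsim_argument_error")
})

test_that("langer alignment returns the acute axis angle", {
  lat <- fresh()
  p0 <- plan_ellipse(lat, c(30, 30), 6, langer_direction = c(1, 0))
  expect_equal(langer_alignment(p0), 0)
  p0$long_axis <- c(0, 1)
  expect_equal(langer_alignment(p0), 90)
  p0$long_axis <- c(1, 1)
  expect_equal(langer_alignment(p0), 45)
  pr <- plan_rotation(build_lattice(20, 20), c(50, 65), 10, 25)
  expect_true(is.na(langer_alignment(pr)))
})

test_that("finer lattices snap closer to the continuous template", {
  d_hausdorff <- function(spacing) {
    rows <- as.integer(120 / spacing)
    lat <- build_lattice(rows, rows, spacing = spacing)
    plan <- plan_ellipse(lat, c(60, 60), 10, ratio = 3)
    loop <- lat$pos[plan$cut_paths[[1]]$vertices, 1:2]
    t <- seq(0, 2 * pi, length.out = 720)
    tmpl <- cbind(60 + 30 * cos(t), 60 + 10 * sin(t))
    d <- function(a, b) max(apply(a, 1, function(p)
      min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))))
    max(d(loop, tmpl), d(tmpl, loop))
  }
  expect_lt(d_hausdorff(5 / 2), d_hausdorff(5))
})
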