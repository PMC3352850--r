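# Synthetic moving-letter environment: glyphs, trajectories, frames, noise,
# trial generation and expected responses.

test_that("glyph bitmaps are distinct, 4x4, and dense enough for the motion windows", {
  gs <- lapply(c("T", "L", "J"), glyph_bitmap)
  for (g in gs) {
    expect_equal(dim(g), c(4, 4))
    expect_true(all(g %in% c(0L, 1L)))
    expect_equal(sum(g), 12)
  }
  expect_false(identical(gs[[1]], gs[[2]]))
  expect_false(identical(gs[[1]], gs[[3]]))
  expect_false(identical(gs[[2]], gs[[3]]))
})

test_that("there are exactly 8 trajectories pairing 4 corners with 2 directions", {
  tt <- trajectory_table()
  expect_equal(nrow(tt), 8)
  expect_equal(sort(unique(tt$corner)), sort(c("UL", "UR", "LL", "LR")))
  expect_equal(sort(unique(tt$direction)), c("lateral", "vertical"))
  expect_equal(nrow(unique(tt[, c("corner", "direction")])), 8)
  # the opposite map is an involution onto the diagonal corner, same axis
  expect_equal(tt$opposite[tt$opposite], tt$traj)
  for (i in 1:8) {
    opp <- tt[tt$traj == tt$opposite[i], ]
    expect_equal(opp$direction, tt$direction[i])
    expect_false(opp$corner == tt$corner[i])
  }
})

test_that("frames advance one pixel per speed step, clip, and empty on exit", {
  tr <- make_stimulus_trial("T", 1) # upper-left, lateral (rightward)
  f0 <- render_frame(tr, 0)
  expect_equal(f0[1:4, 1:4], glyph_bitmap("T"), ignore_attr = TRUE)
  expect_equal(sum(f0), 12)
  # one speed period later the glyph has moved exactly 1 pixel right
  f1 <- render_frame(tr, 10)
  expect_equal(f1[1:4, 2:5], glyph_bitmap("T"), ignore_attr = TRUE)
  expect_equal(sum(f1[, 1]), 0)
  # within a dwell the frame is constant
  expect_equal(render_frame(tr, 13), f1)
  # after the full traversal the field is blank
  expect_equal(sum(render_frame(tr, trial_duration())), 0)
  # a trajectory from the right edge moves leftward and clips at the border
  tr2 <- make_stimulus_trial("L", 2)
  expect_equal(render_frame(tr2, 0)[1:4, 7:10], glyph_bitmap("L"),
    ignore_attr = TRUE
  )
  f_late <- render_frame(tr2, 80) # anchor has moved 8 px left of col 6
  expect_lt(sum(f_late), 12) # partially out on the left
})

test_that("noiseless frames never exceed the objects' pixel budget and overlap ORs", {
  two <- make_stimulus_trial(c("T", "L"), c(1, 5))
  for (t in seq(0, 90, by = 10)) {
    f <- render_frame(two, t)
    expect_true(all(f %in% c(0L, 1L)))
    expect_lte(sum(f), 24)
  }
})

test_that("trajectory coverage spans the retina edges", {
  # over all 8 trajectories, anchors visit every position along each edge
  tt <- trajectory_table()
  for (i in 1:8) {
    tr <- make_stimulus_trial("T", i)
    anchors <- vapply(seq(0, 90, by = 10), function(t) {
      f <- render_frame(tr, t)
      if (sum(f) == 0) NA_integer_ else which(f == 1L)[1]
    }, integer(1))
    expect_gte(sum(!is.na(anchors)), 10)
  }
})

test_that("noise injection flips pixels independently at the stated rate", {
  f <- matrix(0L, 10, 10)
  expect_equal(inject_noise(f, 0), f)
  expect_equal(inject_noise(f, 1), matrix(1L, 10, 10))
  on <- matrix(1L, 10, 10)
  expect_equal(inject_noise(on, 1), matrix(0L, 10, 10))
  set.seed(20)
  flips <- replicate(400, sum(inject_noise(f, 0.08)))
  expect_equal(mean(flips), 8, tolerance = 0.08) # ~8 of 100 pixels per tick
  # binarity and shape preserved
  g <- inject_noise(render_frame(make_stimulus_trial("J", 3), 0), 0.3)
  expect_equal(dim(g), c(10, 10))
  expect_true(all(g %in% c(0L, 1L)))
})

test_that("random trials follow the object mix and are seed-reproducible", {
  set.seed(31)
  singles <- replicate(2000, make_trial("single"), simplify = FALSE)
  letters <- vapply(singles, function(tr) tr$letters[1], character(1))
  trajs <- vapply(singles, function(tr) tr$trajs[1], integer(1))
  expect_lt(max(abs(as.numeric(table(letters)) / 2000 - 1 / 3)), 0.04)
  expect_lt(max(abs(as.numeric(table(trajs)) / 2000 - 1 / 8)), 0.03)

  set.seed(32)
  twos <- replicate(10000, make_trial("two_object"), simplify = FALSE)
  kind <- vapply(twos, function(tr) paste(tr$letters, collapse = ""), character(1))
  expect_lt(abs(mean(kind == "T") - 0.25), 0.02)
  expect_lt(abs(mean(kind == "L") - 0.25), 0.02)
  expect_lt(abs(mean(kind == "TL") - 0.50), 0.02)

  set.seed(99)
  a <- replicate(20, make_trial("two_object", noise_p = 0.1), simplify = FALSE)
  set.seed(99)
  b <- replicate(20, make_trial("two_object", noise_p = 0.1), simplify = FALSE)
  expect_identical(a, b)
})

test_that("expected responses implement catch-T / avoid-L / ignore-J", {
  tt <- trajectory_table()
  # target: catcher at the T's own arrival placement
  expect_equal(expected_response(make_stimulus_trial("T", 1)), 1)
  # avoidance: catcher at the placement opposite the L's
  expect_equal(
    expected_response(make_stimulus_trial("L", 1)),
    tt$opposite[tt$traj == 1]
  )
  # distractor alone: no motor response expected
  expect_true(is.na(expected_response(make_stimulus_trial("J", 4))))
  # with both objects the target wins
  expect_equal(expected_response(make_stimulus_trial(c("T", "L"), c(3, 6))), 3)
  expect_equal(expected_response(make_stimulus_trial(c("L", "T"), c(3, 6))), 6)
})
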