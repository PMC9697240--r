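# Stacking and hydrogen-bond detectors and their trajectory aggregation.

test_that("adjacent fiber bases are stacked, distant ones are not", {
  b <- build_fiber("C6")
  r1 <- get_residue(b, "A", 1)
  r2 <- get_residue(b, "A", 2)
  rec <- is_stacked(r1, r2)
  expect_true(rec$stacked)
  expect_lt(rec$min_heavy_distance, 4)
  expect_lt(rec$center_distance, 5)
  expect_true(rec$normal_angle < 45 || rec$normal_angle > 135)
  # same pair translated 20 A apart fails the distance criteria
  r2far <- r2
  r2far$atoms$x <- r2far$atoms$x + 20
  rec2 <- is_stacked(r1, r2far)
  expect_false(rec2$stacked)
  expect_gt(rec2$min_heavy_distance, 4)
  expect_gt(rec2$center_distance, 5)
})

test_that("coplanar side-by-side bases fail on the center criterion", {
  b <- build_fiber("C2")
  r1 <- get_residue(b, "A", 1)
  r2 <- r1
  r2$atoms$x <- r2$atoms$x + 6    # in-plane shift: parallel normals
  rec <- is_stacked(r1, r2)
  expect_lt(rec$normal_angle, 1)
  expect_gt(rec$center_distance, 5)
  expect_false(rec$stacked)
})

test_that("stacking diagnostics are symmetric in the two residues", {
  b <- build_fiber("ACGT")
  for (pair in list(c(1, 2), c(2, 4), c(1, 3))) {
    a <- is_stacked(get_residue(b, "A", pair[1]),
                    get_residue(b, "A", pair[2]))
    r <- is_stacked(get_residue(b, "A", pair[2]),
                    get_residue(b, "A", pair[1]))
    expect_equal(a$stacked, r$stacked)
    expect_equal(a$min_heavy_distance, r$min_heavy_distance,
                 tolerance = 1e-12)
    expect_equal(a$center_distance, r$center_distance, tolerance = 1e-12)
    expect_equal(a$normal_angle, r$normal_angle, tolerance = 1e-12)
  }
})

test_that("enlarging thresholds never unstacks a stacked pair", {
  set.seed(5)
  b <- build_fiber("C6")
  s <- perturb_steps(b, jitter = c(rise = 0.8, roll = 20, slide = 0.5),
                     seed = 5)
  thr0 <- default_thresholds()
  thr1 <- thr0; thr1$heavy <- 5; thr1$center <- 6.5; thr1$normal <- 60
  for (i in 1:5) {
    r1 <- get_residue(s, "A", i); r2 <- get_residue(s, "A", i + 1)
    if (is_stacked(r1, r2, thr0)$stacked)
      expect_true(is_stacked(r1, r2, thr1)$stacked)
  }
})

test_that("an ideal Watson-Crick G.C pair carries three hydrogen bonds", {
  gc <- build_fiber("G1", duplex = TRUE, add_hydrogens = TRUE)
  hb <- find_hbonds(gc)
  expect_equal(nrow(hb), 3)
  expect_true(all(hb$distance_XY < 3.3))
  expect_true(all(hb$angle_XHY > 150))
  # the canonical triple: N1-H1...N3, N2-H21...O2, N4-H42...O6
  key <- paste(hb$donor_atom, hb$acceptor_atom)
  expect_setequal(key, c("N1 N3", "N2 O2", "N4 O6"))
  # A.T pairs carry two
  at <- build_fiber("A1", duplex = TRUE, add_hydrogens = TRUE)
  expect_equal(nrow(find_hbonds(at)), 2)
})

test_that("bonds beyond the distance or angle windows are rejected", {
  # donor N-H on residue 1, acceptor O on residue 2, geometry constructed
  mk <- function(dXY, angle) {
    Y <- c(0, 0, 0)
    H <- c(1.0, 0, 0)
    # place X so that d(X, Y) = dXY and the angle X-H-Y equals `angle`
    u <- function(r) H + r * c(cos((180 - angle) * pi / 180),
                               sin((180 - angle) * pi / 180), 0)
    r <- uniroot(function(r) sqrt(sum(u(r)^2)) - dXY, c(0.1, 10),
                 tol = 1e-12)$root
    X <- u(r)
    atoms <- data.frame(name = c("N3", "H3", "O2"),
                        element = c("N", "H", "O"),
                        chain = "A", resno = c(1L, 1L, 2L),
                        base = c("T", "T", "C"), stringsAsFactors = FALSE)
    nucleic_structure(atoms, list(rbind(Y, H, X)))
  }
  good <- find_hbonds(mk(2.9, 170))
  expect_equal(nrow(good), 1)
  expect_equal(good$distance_XY, 2.9, tolerance = 1e-6)
  expect_equal(good$angle_XHY, 170, tolerance = 1e-6)
  expect_equal(nrow(find_hbonds(mk(3.5, 179))), 0)   # too far
  expect_equal(nrow(find_hbonds(mk(2.9, 140))), 0)   # too bent
  # the thresholds are exclusive bounds: geometry just past them fails
  expect_equal(nrow(find_hbonds(mk(3.3 + 1e-6, 170))), 0)
  expect_equal(nrow(find_hbonds(mk(2.9, 150 - 1e-6))), 0)
  expect_equal(nrow(find_hbonds(mk(3.3 - 1e-6, 150 + 1e-6))), 1)
})

test_that("hydrogen-free structures demand explicit opt-in", {
  b <- build_fiber("C3")
  expect_error(find_hbonds(b), "idealize_h")
  expect_silent(find_hbonds(b, idealize_h = TRUE))
})

test_that("all detections are rigid-motion invariant", {
  s <- build_fiber("A2C2", duplex = TRUE, add_hydrogens = TRUE)
  hb0 <- find_hbonds(s)
  rec0 <- is_stacked(get_residue(s, "A", 1), get_residue(s, "A", 2))
  for (seed in 1:3) {
    rig <- rand_rigid(seed + 30)
    sm <- apply_rigid_structure(s, rig)
    hb <- find_hbonds(sm)
    expect_equal(nrow(hb), nrow(hb0))
    expect_equal(hb$distance_XY, hb0$distance_XY, tolerance = 1e-9)
    expect_equal(hb$angle_XHY, hb0$angle_XHY, tolerance = 1e-9)
    rec <- is_stacked(get_residue(sm, "A", 1), get_residue(sm, "A", 2))
    expect_equal(rec$min_heavy_distance, rec0$min_heavy_distance,
                 tolerance = 1e-9)
    expect_equal(rec$center_distance, rec0$center_distance,
                 tolerance = 1e-9)
    expect_equal(rec$normal_angle, rec0$normal_angle, tolerance = 1e-9)
  }
})

test_that("detections match the brute-force reference exactly", {
  b <- build_fiber("A2C2A2", add_hydrogens = TRUE)
  traj <- make_mock_trajectory(b, 6, p_stack = c(1, 0.5, 0, 1, 0.5),
                               sigma = 0.05, seed = 12)
  s <- traj$structure
  ts <- trajectory_stats(s)
  n <- nrow(residue_table(s))
  for (m in seq_len(n_models(s))) {
    one <- nucleic_structure(s$atoms, s$models[m])
    ref <- brute_stacked_pairs(one)
    # adjacent fractions recomputed from the brute-force matrix
    for (k in seq_len(nrow(ts$stack_fractions))) {
      i <- ts$stack_fractions$step[k]
      det <- is_stacked(get_residue(s, "A", i, m),
                        get_residue(s, "A", i + 1, m))
      expect_identical(det$stacked, ref[i, i + 1])
    }
    expect_equal(nrow(find_hbonds(one)), brute_hbonds(one))
  }
})

test_that("identical snapshots give unit fractions and zero elsewhere", {
  b <- build_fiber("C4")
  s <- nucleic_structure(b$atoms, rep(b$models, 3))
  ts <- trajectory_stats(s)
  expect_equal(ts$stack_fractions$fraction, rep(1, 3))
  expect_true(all(ts$nonadjacent$count == 0))
  expect_equal(ts$n_models, 3)
})

test_that("hydrogen-bond persistence counts consecutive detections", {
  gc <- build_fiber("G1", duplex = TRUE, add_hydrogens = TRUE)
  # three identical models: each of 3 bonds persists twice
  s <- nucleic_structure(gc$atoms, rep(gc$models, 3))
  ts <- trajectory_stats(s)
  expect_equal(ts$hbond_total, 9)
  expect_equal(ts$hbond_persistent, 6)
})
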