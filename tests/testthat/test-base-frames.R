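# Base reference frames: superposition fit, normals, centers, pair frames.

template_residue <- function(base = "C", rig = NULL) {
  std <- standard_base(base)
  res <- structure(list(base = base, chain = "A", resno = 1L,
                        atoms = std), class = "nucleotide")
  if (!is.null(rig)) res <- apply_rigid_residue(res, rig)
  res
}

test_that("the standard base in its own frame fits to the identity", {
  fr <- fit_base_frame(template_residue("A"))
  expect_equal(fr$axes, diag(3), tolerance = 1e-9)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(fr$fit_rmsd, 1e-9)
})

test_that("a known rigid motion of the standard base is recovered", {
  for (seed in 1:5) {
    rig <- rand_rigid(seed)
    fr <- fit_base_frame(template_residue("G", rig))
    expect_equal(fr$axes, rig$R, tolerance = 1e-9)
    expect_equal(fr$origin, rig$t, tolerance = 1e-9)
    expect_lt(fr$fit_rmsd, 1e-9)
  }
})

test_that("mirror-image coordinates still yield a proper rotation", {
  # a planar base is achiral, so chirality is probed with a deterministic
  # out-of-plane deformation before reflecting through the base plane
  res <- template_residue("T")
  res$atoms$z <- 0.25 * sin(seq_len(nrow(res$atoms)))
  fr_bent <- fit_base_frame(res)
  mirrored <- res
  mirrored$atoms$z <- -mirrored$atoms$z
  fr <- fit_base_frame(mirrored)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  # a proper rotation cannot null the reflection: the residual exceeds the
  # chiral deformation left in the bent original's own fit
  expect_gt(fr$fit_rmsd, fr_bent$fit_rmsd * 0.99)
  expect_gt(fr$fit_rmsd, 0.05)
})

test_that("missing ring atoms are reported by name", {
  res <- template_residue("A")
  res$atoms <- res$atoms[res$atoms$name != "N7", ]
  expect_error(fit_base_frame(res), "N7")
})

test_that("base normals are covariant and robust to slight pucker", {
  res <- template_residue("C")           # planar, in the xy-plane
  expect_equal(abs(base_normal(res)[3]), 1, tolerance = 1e-9)
  rig <- rand_rigid(11)
  n_rot <- base_normal(apply_rigid_residue(res, rig))
  expect_equal(n_rot, as.vector(rig$R %*% base_normal(res)),
               tolerance = 1e-9)
  # displace ring atoms out of plane by +-0.05 A
  set.seed(3)
  res2 <- res
  res2$atoms$z <- res2$atoms$z + runif(nrow(res2$atoms), -0.05, 0.05)
  ang <- acos(min(1, abs(sum(base_normal(res2) * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("base centers follow the mass-weighted definition", {
  res <- template_residue("C")
  at <- res$atoms[res$atoms$name != "C1'", ]   # the nucleobase proper
  masses <- c(C = 12.011, N = 14.007, O = 15.999)
  w <- masses[at$element]
  manual <- colSums(as.matrix(at[, c("x", "y", "z")]) * w) / sum(w)
  expect_equal(base_center(res), unname(manual), tolerance = 1e-12)
  # unweighted centroid differs from the mass-weighted center
  expect_false(isTRUE(all.equal(base_center(res, mass_weighted = FALSE),
                                unname(manual), tolerance = 1e-6)))
  # two equal-mass atoms at +-d average to the midpoint
  res2 <- res
  res2$atoms <- data.frame(name = c("N1", "N3"), element = "N",
                           x = c(1, -1), y = c(2, -2), z = c(0.5, -0.5))
  expect_equal(base_center(res2), c(0, 0, 0), tolerance = 1e-12)
})

test_that("pair frames average flipped partners along the geodesic", {
  flip <- diag(c(1, -1, -1))
  f1 <- base_frame(c(0, 0, 0), diag(3))
  # partner that coincides with f1 after flipping
  f2 <- base_frame(c(0, 0, 0), diag(3) %*% flip)
  pf <- pair_frame(f1, f2)
  expect_equal(pf$axes, diag(3), tolerance = 1e-9)
  # pure propeller: +-theta about the shared x-axis -> bisector
  theta <- 14
  r_p <- function(a) nucgeom:::rot_about(c(1, 0, 0), a)
  fa <- base_frame(c(0, 0, 0), r_p(theta))
  fb <- base_frame(c(0, 0, 0), r_p(-theta) %*% flip)
  pf2 <- pair_frame(fa, fb)
  expect_equal(pf2$axes, diag(3), tolerance = 1e-9)
  # anti-aligned z-axes after flipping are rejected
  f_bad <- base_frame(c(0, 0, 0), diag(3))
  expect_error(pair_frame(f1, f_bad), "90 degrees")
})

test_that("fiber duplex pair-frame origins lie on the helix axis", {
  d <- build_fiber("G4C2", duplex = TRUE)
  f1 <- fit_frames(d, "A")
  f2 <- fit_frames(d, "B")
  n <- length(f1)
  for (i in seq_len(n)) {
    pf <- pair_frame(f1[[i]], f2[[n + 1 - i]])
    # generator helix axis is the z-axis through the origin
    expect_lt(sqrt(sum(pf$origin[1:2]^2)), 0.1)
  }
})

test_that("frames, normals and centers are rigid-motion covariant", {
  s <- build_fiber("ACGT")
  res <- get_residue(s, "A", 2)
  rig <- rand_rigid(21)
  res_m <- apply_rigid_residue(res, rig)
  fr <- fit_base_frame(res)
  fr_m <- fit_base_frame(res_m)
  expect_equal(fr_m$axes, rig$R %*% fr$axes, tolerance = 1e-9)
  expect_equal(fr_m$origin, as.vector(rig$R %*% fr$origin + rig$t),
               tolerance = 1e-9)
  expect_equal(base_center(res_m),
               as.vector(rig$R %*% base_center(res) + rig$t),
               tolerance = 1e-9)
})

test_that("refitting a re-emitted standard base is idempotent", {
  fr0 <- fit_base_frame(template_residue("G", rand_rigid(5)))
  # re-emit the standard base from the fitted frame, then refit
  std <- standard_base("G")
  xyz <- as.matrix(std[, c("x", "y", "z")]) %*% t(fr0$axes)
  xyz <- sweep(xyz, 2, fr0$origin, `+`)
  res <- structure(list(base = "G", chain = "A", resno = 1L,
                        atoms = data.frame(name = std$name,
                                           element = std$element,
                                           x = xyz[, 1], y = xyz[, 2],
                                           z = xyz[, 3])),
                   class = "nucleotide")
  fr1 <- fit_base_frame(res)
  expect_equal(fr1$axes, fr0$axes, tolerance = 1e-9)
  expect_equal(fr1$origin, fr0$origin, tolerance = 1e-9)
})
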