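test_that("resampling is uniform, idempotent and endpoint-preserving", {
  line <- centerline(rbind(c(0, 0, 0), c(0, 0, 10)))
  rs <- resample_centerline(line, 1)
  expect_equal(nrow(rs$points), 11L)
  expect_lt(max(abs(diff(rs$arclength) - 1)), 1e-6)
  expect_equal(rs$points[1, ], c(0, 0, 0))
  expect_equal(rs$points[11, ], c(0, 0, 10))
  rs2 <- resample_centerline(rs, 1)
  expect_identical(rs2$points, rs$points)

  # arclength preserved within 0.1% on a smooth arc
  t <- seq(0, pi / 2, length.out = 400)
  arc <- centerline(cbind(10 * cos(t), 10 * sin(t), 0))
  rs3 <- resample_centerline(arc, 0.25)
  expect_lt(abs(total_arclength(rs3) - total_arclength(arc)) /
              total_arclength(arc), 0.001)
  expect_error(resample_centerline(line, 11), "smaller than")
  expect_error(resample_centerline(line, 0), "positive")
})

test_that("frames are orthonormal and rotation-minimizing", {
  # straight line: constant frame
  line <- centerline(cbind(0, 0, seq(0, 10, length.out = 21)))
  expect_lt(max(abs(sweep(line$normal, 2, line$normal[1, ]))), 1e-12)

  # orthonormality on a batch of smooth curves
  t <- seq(0, 3 * pi, length.out = 300)
  curves <- list(cbind(4 * cos(t), 4 * sin(t), 0.8 * t),
                 cbind(t, sin(t), cos(2 * t)))
  for (p in curves) {
    cl <- centerline(p)
    expect_lt(max(abs(rowSums(cl$tangent * cl$normal))), 1e-8)
    expect_lt(max(abs(rowSums(cl$tangent * cl$binormal))), 1e-8)
    expect_lt(max(abs(rowSums(cl$normal * cl$binormal))), 1e-8)
    expect_lt(max(abs(rowSums(cl$normal^2) - 1)), 1e-8)
    # rotation-minimizing: consecutive frame rotation < 10 degrees
    dn <- rowSums(cl$normal[-1, ] * cl$normal[-nrow(p), ])
    expect_gt(min(dn), cos(10 * pi / 180))
  }

  # planar 90-degree arc: the in-plane frame axis rotates exactly with
  # the tangent (90 degrees end to end)
  ta <- seq(0, pi / 2, length.out = 200)
  arc <- centerline(cbind(10 * cos(ta), 10 * sin(ta), 0))
  inplane <- if (abs(arc$normal[1, 3]) > 0.99) arc$binormal else arc$normal
  ang <- acos(max(-1, min(1, sum(inplane[1, ] * inplane[200, ]))))
  expect_lt(abs(ang * 180 / pi - 90), 0.5)

  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1))),
               "coincident")
})

test_that("helix frame twist relative to Frenet matches the torsion integral", {
  a <- 2; b <- 0.8
  t <- seq(0, 6 * pi, length.out = 600)
  cl <- centerline(cbind(a * cos(t), a * sin(t), b * t))
  frenet_n <- cbind(-cos(t), -sin(t), 0)
  # angle of the RMF normal relative to the Frenet normal, unwrapped
  frenet_b <- cbind(b * sin(t), -b * cos(t), a) / sqrt(a^2 + b^2)
  ang <- atan2(rowSums(cl$normal * frenet_b), rowSums(cl$normal * frenet_n))
  ang <- ang - cumsum(c(0, round(diff(ang) / (2 * pi)))) * 2 * pi
  total_twist <- abs(ang[length(ang)] - ang[1])
  torsion <- b / (a^2 + b^2)
  expected <- torsion * total_arclength(cl)
  expect_lt(abs(total_twist - expected) / expected, 0.02)
})

test_that("extraction recovers the axis of a straight tube", {
  st <- fix_straight()
  cl <- extract_centerline(st$mesh, c(0, 0, 4), c(0, 0, 26))
  dev <- sqrt(cl$points[, 1]^2 + cl$points[, 2]^2)
  expect_lt(mean(dev), 0.1)
  expect_lt(max(abs(cl$radius - 2.25) / 2.25), 0.01)
  expect_true(all(inside_mesh(cl$points, st$mesh)))
  # determinism
  cl2 <- extract_centerline(st$mesh, c(0, 0, 4), c(0, 0, 26))
  expect_identical(cl$points, cl2$points)
})

test_that("extraction follows the bend of a curved tube", {
  ct <- fix_curved()
  tc <- ct$truth$centerline
  L <- total_arclength(tc)
  ends <- fvstent:::interp_centerline(tc, c(2, L - 2))
  cl <- extract_centerline(ct$mesh, ends$points[1, ], ends$points[2, ])
  dev <- sqrt((sqrt(cl$points[, 1]^2 + cl$points[, 2]^2) - 10)^2 +
                cl$points[, 3]^2)
  expect_lt(mean(dev), 0.1)
  expect_lt(abs(total_arclength(cl) - (L - 4)) / (L - 4), 0.02)
  expect_true(all(inside_mesh(cl$points, ct$mesh)))
})

test_that("the forward cone keeps the centerline out of the aneurysm sac", {
  ph <- fix_aneurysm()
  tc <- ph$truth$centerline
  L <- total_arclength(tc)
  ends <- fvstent:::interp_centerline(tc, c(3, L - 3))
  cl <- extract_centerline(ph$mesh, ends$points[1, ], ends$points[2, ])
  expect_lt(max(cl$radius), 1.5 * 2.25)
  expect_true(all(inside_mesh(cl$points, ph$mesh)))
})

test_that("extraction rejects bad seeds", {
  st <- fix_straight()
  expect_error(extract_centerline(st$mesh, c(10, 10, 5), c(0, 0, 26)),
               "outside")
  expect_error(extract_centerline(st$mesh, c(0, 0, 4), c(10, 10, 5)),
               "outside")
})
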