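test_that("direction vectors follow the spherical convention and normalize", {
  expect_equal(direction_to_vector(0, 0), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(direction_to_vector(90, 90), c(0, 1, 0), tolerance = 1e-12)
  set.seed(1)
  for (k in 1:200) {
    d <- random_direction()
    v <- direction_to_vector(d["phi"], d["theta"])
    expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-12)
    back <- vector_to_direction(v)
    if (d["theta"] > 1 && d["theta"] < 179) {
      expect_lt(angdiff_abs(back$phi, d["phi"]), 1e-9)
      expect_lt(abs(back$theta - d["theta"]), 1e-9)
    }
  }
  expect_error(direction_to_vector(NA, 10), class = "lorefine_invalid_argument")
})

test_that("span angle matches the dot-product oracle and is symmetric", {
  expect_lt(span_angle(33, 71, 33, 71), 1e-5)
  expect_equal(span_angle(0, 0, 0, 90), 90)
  set.seed(2)
  for (k in 1:200) {
    a <- random_direction(); b <- random_direction()
    v1 <- direction_to_vector(a["phi"], a["theta"])
    v2 <- direction_to_vector(b["phi"], b["theta"])
    oracle <- 180 / pi * acos(max(min(sum(v1 * v2), 1), -1))
    expect_lt(abs(span_angle(a["phi"], a["theta"], b["phi"], b["theta"]) -
                    oracle), 1e-9)
    expect_equal(span_angle(a["phi"], a["theta"], b["phi"], b["theta"]),
                 span_angle(b["phi"], b["theta"], a["phi"], a["theta"]))
  }
  # triangle inequality on random triples
  for (k in 1:50) {
    a <- random_direction(); b <- random_direction(); c <- random_direction()
    expect_lte(span_angle(a[1], a[2], c[1], c[2]),
               span_angle(a[1], a[2], b[1], b[2]) +
                 span_angle(b[1], b[2], c[1], c[2]) + 1e-9)
  }
})

test_that("direction sets cover the sphere quasi-uniformly", {
  D90 <- generate_direction_set(90)
  set.seed(3)
  for (k in 1:100) {
    d <- random_direction()
    expect_lte(min(span_angle(d["phi"], d["theta"], D90$phi, D90$theta)), 90)
  }
  D <- generate_direction_set(2)
  area_count <- ceiling(360^2 / pi / 4)
  expect_gt(nrow(D), 0.8 * area_count)
  expect_lt(nrow(D), 1.2 * area_count)
  # nearest-neighbour spacing: brute-force scan over a sample
  idx <- sample(nrow(D), 120)
  nn <- vapply(idx, function(i)
    min(span_angle(D$phi[i], D$theta[i], D$phi[-i], D$theta[-i])), 0)
  expect_lte(max(nn), 1.5 * 2)
  # hemisphere flag restricts to theta <= 90
  Dh <- generate_direction_set(10, hemisphere = TRUE)
  expect_true(all(Dh$theta <= 90 + 1e-9))
  expect_error(generate_direction_set(0.01, max_points = 1e4),
               class = "lorefine_resource_error")
})

test_that("cone constraint keeps exactly the in-cone members plus centre", {
  D <- generate_direction_set(2)
  # all members kept; the centre is appended when absent from D
  expect_gte(nrow(constrain_directions(D, 40, 60, 180)), nrow(D))
  only <- constrain_directions(D, 40.123, 60.456, 0)
  expect_true(all(only$span < 1e-6))
  sub <- constrain_directions(D, 40, 60, 10)
  brute <- sum(span_angle(D$phi, D$theta, 40, 60) <= 10 + 1e-9)
  expect_true(nrow(sub) %in% c(brute, brute + 1))
  expect_true(all(sub$span <= 10 + 1e-9))
})

test_that("psi transport matches the rotation-matrix oracle", {
  # identity transport
  expect_equal(transported_psi(10, 40, 77, 10, 40), 77)
  # collinear closed form psi_i = phi0 + psi0 - phi_i: same meridian
  expect_lt(angdiff_abs(transported_psi(40, 30, 100, 40, 70), 40 + 100 - 40),
            1e-9)
  # over-pole path (phi_i = phi0 + 180)
  expect_lt(angdiff_abs(transported_psi(20, 40, 30, 200, 20), 20 + 30 - 200),
            1e-9)
  set.seed(4)
  for (k in 1:300) {
    a <- random_direction(); b <- random_direction()
    if (span_angle(a[1], a[2], b[1], b[2]) > 170) next
    psi0 <- runif(1, 0, 360)
    got <- transported_psi(a[1], a[2], psi0, b[1], b[2])
    expect_lt(angdiff_abs(got, transport_oracle(a[1], a[2], psi0, b[1], b[2])),
              1e-6)
    # round trip along the same arc
    back <- transported_psi(b[1], b[2], got, a[1], a[2])
    expect_lt(angdiff_abs(back, psi0), 1e-6)
  }
  expect_error(transported_psi(0, 90, 10, 180, 90),
               class = "lorefine_invalid_argument")
})

test_that("psi transport agrees with the spherical-triangle form", {
  # internal angles at the two directions of the triangle with the pole
  tri_form <- function(phi0, theta0, psi0, phi1, theta1) {
    ang_at <- function(p, q, r) {
      ep <- direction_to_vector(p[1], p[2])
      eq <- direction_to_vector(q[1], q[2])
      er <- direction_to_vector(r[1], r[2])
      tq <- eq - sum(eq * ep) * ep
      tr <- er - sum(er * ep) * ep
      acos(max(min(sum(tq * tr) / sqrt(sum(tq^2) * sum(tr^2)), 1), -1))
    }
    pole <- c(0, 0)
    B <- ang_at(c(phi0, theta0), pole, c(phi1, theta1))
    C <- ang_at(c(phi1, theta1), pole, c(phi0, theta0))
    dphi <- phi1 - phi0
    s <- if (abs(dphi) <= 180) -sign(dphi) else sign(dphi)
    psi0 + s * (180 - (B + C) * 180 / pi)
  }
  set.seed(5)
  for (k in 1:100) {
    a <- c(runif(1, 0, 360), runif(1, 20, 160))
    b <- c(a[1] + runif(1, -40, 40), a[2] + runif(1, -40, 40))
    b[2] <- min(max(b[2], 5), 175)
    psi0 <- runif(1, 0, 360)
    expect_lt(angdiff_abs(transported_psi(a[1], a[2], psi0, b[1], b[2]),
                          tri_form(a[1], a[2], psi0, b[1], b[2])), 1e-6)
  }
})

test_that("search grids have the promised structure", {
  p0 <- orientation_params(40, 60, 30, 1.5, -0.5)
  r0 <- search_range(alpha0 = 0, t1 = 0, t2 = 0,
                     directions = data.frame(phi = 40, theta = 60))
  g0 <- build_search_grid(p0, r0)
  expect_equal(nrow(g0), 1L)
  expect_equal(unname(g0$psi), 30)
  expect_equal(unname(g0$x), 1.5)
  # cardinality formula
  D <- generate_direction_set(2)
  rng <- search_range(alpha0 = 6, d1 = 2, t1 = 2, d2 = 1, t2 = 4,
                      directions = D)
  g <- build_search_grid(p0, rng)
  nd <- nrow(constrain_directions(D, 40, 60, 6))
  expect_equal(nrow(g), nd * 5 * 9 * 9)
  expect_true(all(g$span <= 6 + 1e-9))
  # preliminary point occurs exactly once
  hit <- abs(g$phi - 40) < 1e-9 & abs(g$theta - 60) < 1e-9 &
    abs(g$psi - 30) < 1e-9 & abs(g$x - 1.5) < 1e-9 & abs(g$y + 0.5) < 1e-9
  expect_equal(sum(hit), 1L)
  expect_error(build_search_grid(p0, rng, cap = 100),
               class = "lorefine_resource_error")
})

test_that("Euler matrices invert cleanly, including at the poles", {
  set.seed(6)
  for (k in 1:50) {
    ang <- c(runif(1, 0, 360), runif(1, 1, 179), runif(1, 0, 360))
    eu <- matrix_to_euler(euler_matrix(ang[1], ang[2], ang[3]))
    expect_lt(angdiff_abs(eu["phi"], ang[1]), 1e-7)
    expect_lt(abs(eu["theta"] - ang[2]), 1e-7)
    expect_lt(angdiff_abs(eu["psi"], ang[3]), 1e-7)
  }
  eu <- matrix_to_euler(euler_matrix(25, 0, 30))
  expect_equal(unname(eu["phi"]), 0)
  expect_lt(angdiff_abs(eu["psi"], 55), 1e-9)
})
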