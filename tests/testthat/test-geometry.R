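rigid_motion <- function(g, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1 - 2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
  shift <- rnorm(3, sd = 10)
  macrocycle_geometry(g$elements,
                      sweep(g$coordinates %*% t(R), 2, shift, `+`),
                      g$rings, g$path)
}

test_that("XYZ + sidecar round-trips and validates indices", {
  dir <- withr::local_tempdir()
  g <- synthetic_hexaphyrin(rep(12, 6))
  xyz <- file.path(dir, "g.xyz"); rings <- file.path(dir, "g.rings.json")
  write_xyz(g, xyz, rings)
  g2 <- read_xyz(xyz, rings)
  expect_equal(g2$coordinates, g$coordinates, tolerance = 1e-6)
  expect_equal(g2$elements, g$elements)
  expect_length(g2$rings, 6)
  expect_equal(g2$rings, lapply(g$rings, as.integer))

  # 1-based convention: atom index 0 must be rejected
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(rings = c(list(c(0, 1, 2, 3)), g$rings[2:6])),
                       bad)
  expect_error(read_xyz(xyz, bad), "1-based")
  # rings must have at least 4 atoms
  small <- file.path(dir, "small.json")
  jsonlite::write_json(list(rings = c(list(c(1, 2, 3)), g$rings[2:6])), small)
  expect_error(read_xyz(xyz, small), "fewer than 4")
  # malformed coordinate lines are reported
  txt <- readLines(xyz)
  txt[4] <- "C 1.0 abc 2.0"
  bad_xyz <- file.path(dir, "bad.xyz")
  writeLines(txt, bad_xyz)
  expect_error(read_xyz(bad_xyz, rings), "non-numeric")
})

test_that("phi_p reproduces constructed inter-ring angles", {
  expect_equal(phi_p(synthetic_hexaphyrin(rep(0, 6))), 0, tolerance = 1e-9)
  expect_equal(phi_p(synthetic_hexaphyrin(rep(10, 6))), 10, tolerance = 1e-7)
  # mixed sequence: arithmetic mean of the constructed angles
  expect_equal(phi_p(synthetic_hexaphyrin(c(10, 10, 10, 10, 10, 40))), 15,
               tolerance = 1e-7)
  expect_error(synthetic_hexaphyrin(c(1, 1, 1, 1, 1, 80)), "infeasible")
})

test_that("pi_index follows the cosine product and the Moebius sign rule", {
  flat <- synthetic_hexaphyrin(rep(0, 6))
  expect_equal(pi_index(flat), 1, tolerance = 1e-9)
  g10 <- synthetic_hexaphyrin(rep(10, 6))
  expect_equal(pi_index(g10), cos(10 * pi / 180)^6, tolerance = 1e-7)
  expect_equal(classify_topology(pi_index(g10)), "Hueckel")

  gm <- synthetic_hexaphyrin(moebius = TRUE)
  expect_lt(pi_index(gm), 0)
  expect_equal(classify_topology(pi_index(gm)), "Moebius")
  expect_lte(abs(pi_index(gm)), 1)

  expect_equal(classify_topology(0.88), "Hueckel")
  expect_equal(classify_topology(-0.45), "Moebius")
  expect_equal(classify_topology(1e-12), "Hueckel")
  expect_error(classify_topology(0), "indeterminate")
})

test_that("descriptors are invariant under rigid motion and |pi| <= 1", {
  for (seed in 1:5) {
    g <- synthetic_hexaphyrin(rep(5 * seed %% 25 + 2, 6))
    gr <- rigid_motion(g, seed)
    expect_equal(phi_p(gr), phi_p(g), tolerance = 1e-9)
    expect_equal(pi_index(gr), pi_index(g), tolerance = 1e-9)
    expect_lte(abs(pi_index(g)), 1)
  }
})

test_that("inversion-center detection accepts C_i sets and rejects perturbed ones", {
  # paired point set {x, -x} with matching elements
  set.seed(8)
  half <- matrix(rnorm(15, sd = 3), 5, 3)
  els <- c("C", "N", "C", "O", "H")
  g <- macrocycle_geometry(c(els, els), rbind(half, -half),
                           rings = list(1:5, 6:10))
  expect_true(detect_inversion_center(g)$centrosymmetric)
  expect_equal(detect_inversion_center(g)$center, c(0, 0, 0))

  # one displaced atom breaks it at tight tolerance
  pert <- rbind(half, -half)
  pert[3, ] <- pert[3, ] + c(0.5, 0, 0)
  gp <- macrocycle_geometry(c(els, els), pert, rings = list(1:5, 6:10))
  expect_false(detect_inversion_center(gp, tol = 0.1)$centrosymmetric)

  # mismatched elements at inversion-image positions break it too
  els2 <- c(els, c("C", "N", "C", "O", "F"))
  gel <- macrocycle_geometry(els2, rbind(half, -half),
                             rings = list(1:5, 6:10))
  expect_false(detect_inversion_center(gel)$centrosymmetric)

  # regular hexagon of identical atoms has an exact inversion image
  ang <- 2 * pi * (0:5) / 6
  hexa <- macrocycle_geometry(rep("C", 6), cbind(cos(ang), sin(ang), 0),
                              rings = list(1:6))
  expect_true(detect_inversion_center(hexa)$centrosymmetric)

  # invariance under atom reordering
  perm <- sample(10)
  gperm <- macrocycle_geometry(c(els, els)[perm],
                               rbind(half, -half)[perm, ],
                               rings = list(1:5, 6:10))
  expect_true(detect_inversion_center(gperm)$centrosymmetric)
})

test_that("topology_descriptors bundles the geometry summary", {
  d <- topology_descriptors(synthetic_hexaphyrin(rep(10, 6)))
  expect_equal(d$phi_p, 10, tolerance = 1e-7)
  expect_equal(d$topology, "Hueckel")
  expect_true(d$aromatic_by_pi)    # pi = cos(10 deg)^6 = 0.91 >= 0.30
  dm <- topology_descriptors(synthetic_hexaphyrin(moebius = TRUE))
  expect_equal(dm$topology, "Moebius")
  expect_false(dm$aromatic_by_pi)
})

test_that("degenerate rings are rejected by the plane fit", {
  line <- cbind(1:5, 0, 0)
  g <- macrocycle_geometry(rep("C", 10), rbind(line, line + 10),
                           rings = list(1:5, 6:10))
  expect_error(phi_p(g), "degenerate|collinear")
})
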