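test_that("dihedral angle reproduces cis/trans and the atan2 oracle", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                              c(0, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                                  c(0, -1, 0))), 180)
  set.seed(11)
  for (i in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), "coincide")
})

test_that("cross distances equal brute-force norms and ignore translation", {
  m <- gen_gate_geometry(toy_gate_spec(noise_sd = 0.3, seed = 6))
  i1 <- which(m$chain == "A" & m$resno == 625 & m$elety == "CA")
  i2 <- which(m$chain == "C" & m$resno == 625 & m$elety == "CA")
  brute <- sqrt(sum((as.numeric(m[i1, c("x", "y", "z")]) -
                       as.numeric(m[i2, c("x", "y", "z")]))^2))
  expect_equal(cross_distance(m, 625, c("A", "C")), brute, tolerance = 1e-12)
  mt <- m; mt$x <- mt$x + 11; mt$z <- mt$z - 4
  expect_equal(cross_distance(mt, 625, c("A", "C")), brute, tolerance = 1e-12)
  expect_error(cross_distance(m, 625, c("A", "Z")), "not found")
})

test_that("gate RMSD is zero under rigid motion and matches bio3d", {
  m <- gen_gate_geometry(toy_gate_spec(noise_sd = 0.2, seed = 7))
  expect_equal(gate_rmsd(m, m), 0, tolerance = 1e-9)
  r <- matrix(c(cos(1), sin(1), 0, -sin(1), cos(1), 0, 0, 0, 1), 3, 3)
  mr <- m
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% r
  mr$x <- xyz[, 1] + 3; mr$y <- xyz[, 2]; mr$z <- xyz[, 3] - 1
  expect_equal(gate_rmsd(mr, m), 0, tolerance = 1e-9)
  # independent superposition oracle: bio3d fit + rmsd
  md <- gen_gate_geometry(toy_gate_spec(noise_sd = 0.4, seed = 8))
  sel <- select_atoms(m, resno = 614:625, elety = c("C", "O", "N", "CA", "CB"))
  a <- as.numeric(t(as.matrix(m[sel, c("x", "y", "z")])))
  b <- as.numeric(t(as.matrix(md[sel, c("x", "y", "z")])))
  oracle <- bio3d::rmsd(a, b, fit = TRUE)   # bio3d rounds to 3 decimals
  expect_lt(abs(gate_rmsd(md, m) - oracle), 5e-4)
  fitted <- suppressWarnings(bio3d::fit.xyz(a, b))
  oracle_exact <- sqrt(mean((fitted - a)^2) * 3)
  expect_equal(gate_rmsd(md, m), oracle_exact, tolerance = 1e-9)
  expect_error(gate_rmsd(m[m$chain != "D", ], m), "differ")
})

test_that("bend angle recovers a constructed kink at the hinge", {
  # collinear CA chain: zero bend
  straight <- structure_model(data.frame(
    chain = "A", resno = 610:626, resid = "ALA", elety = "CA", elesy = "C",
    x = 3, y = 0, z = 1.5 * (610:626 - 618), stringsAsFactors = FALSE))
  expect_lt(bend_angle(straight, "A"), 1e-6)
  # 30-degree kink above the hinge
  kinked <- straight
  above <- kinked$resno > 618
  dz <- 1.5 * (kinked$resno[above] - 618)
  kinked$x[above] <- 3 + dz * sin(pi / 6)
  kinked$z[above] <- dz * cos(pi / 6)
  expect_equal(bend_angle(kinked, "A"), 30, tolerance = 0.5)
  # the same kink placed far from the hinge window leaves the hinge flat
  far <- straight
  hi <- far$resno > 623
  dz2 <- 1.5 * (far$resno[hi] - 623)
  far$x[hi] <- 3 + dz2 * sin(pi / 6)
  far$z[hi] <- 1.5 * (623 - 618) + dz2 * cos(pi / 6)
  expect_lt(bend_angle(far, "A", flank = 4), 5)
  expect_error(bend_angle(straight[straight$resno > 617, ], "A"), "at least 3")
})

test_that("pore area equals the shoelace value and ignores vertex order", {
  sq <- structure_model(data.frame(
    chain = c("A", "B", "C", "D"), resno = 621, resid = "ALA",
    elety = "CA", elesy = "C",
    x = c(2, -2, -2, 2), y = c(2, 2, -2, -2), z = 0,
    stringsAsFactors = FALSE))
  expect_equal(pore_area(sq, 621), 16, tolerance = 1e-12)
  # permuting the chain order must not change the area
  perm <- sq[c(3, 1, 4, 2), ]
  expect_equal(pore_area(structure_model(as.data.frame(perm)), 621), 16,
               tolerance = 1e-12)
  # irregular quadrilateral vs an independent triangle-split oracle
  v <- matrix(c(3, 0.5, -2, 1.8, -2.5, -1.1, 1.2, -3), 4, 2, byrow = TRUE)
  irr <- sq
  irr$x <- v[, 1]; irr$y <- v[, 2]
  tri <- function(a, b, c_) abs((b[1] - a[1]) * (c_[2] - a[2]) -
                                  (c_[1] - a[1]) * (b[2] - a[2])) / 2
  ord <- order(atan2(v[, 2] - mean(v[, 2]), v[, 1] - mean(v[, 1])))
  vo <- v[ord, ]
  oracle <- tri(vo[1, ], vo[2, ], vo[3, ]) + tri(vo[1, ], vo[3, ], vo[4, ])
  expect_equal(pore_area(structure_model(as.data.frame(irr)), 621), oracle,
               tolerance = 1e-9)
})

test_that("features are invariant under rigid transforms of the frame", {
  m <- align_to_gate_origin(gen_gate_geometry(
    toy_gate_spec(noise_sd = 0.2, seed = 12,
                  bend_flags = c(FALSE, TRUE, FALSE, TRUE))))
  f0 <- gate_feature_vector(m)
  th <- 0.7
  r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- m
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% r
  mr$x <- xyz[, 1] + 2; mr$y <- xyz[, 2] - 1; mr$z <- xyz[, 3] + 5
  f1 <- gate_feature_vector(mr)
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("zero-noise generator output reproduces every feature target", {
  sp <- toy_gate_spec(chi1_targets = c(-65, 45, 180, -170),
                      ring_radii = c(r617 = 4, r621 = 4.5, r625 = 6))
  m <- gen_gate_geometry(sp)
  f <- gate_feature_vector(m)
  expect_equal(unname(f[paste0("chi1_", c("A", "B", "C", "D"))]),
               sp$chi1_targets, tolerance = 1e-9)
  expect_equal(unname(f["d625_AC"]), 12, tolerance = 1e-9)
  expect_equal(unname(f["d617_AC"]), 8, tolerance = 1e-9)
})

test_that("feature encoding standardises, pairs angles, and wraps", {
  set.seed(21)
  feats <- cbind(chi1 = runif(500, -170, 170), d = rnorm(500, 10, 2))
  enc <- encode_features(feats)
  expect_equal(sd(enc[, "d"]), 1, tolerance = 1e-9)
  expect_equal(var(enc[, "chi1.sin"]) + var(enc[, "chi1.cos"]), 1,
               tolerance = 1e-9)
  # invertible for angles
  back <- atan2(enc[, "chi1.sin"], enc[, "chi1.cos"]) * 180 / pi
  expect_equal(back, unname(feats[, "chi1"]), tolerance = 1e-9)
  # constant angle dropped with warning, two columns fewer
  feats2 <- cbind(feats, chi1_const = 42)
  expect_warning(enc2 <- encode_features(feats2), "constant angle")
  expect_equal(ncol(enc2), ncol(enc))
  # wraparound: 179 and -179 are near-neighbours in encoded space
  f3 <- cbind(chi1 = c(rep(179, 50), rep(-179, 50)))
  e3 <- suppressWarnings(encode_features(f3))
  scale <- sqrt(sum(e3[1, ]^2))  # radius of the encoded circle
  gap <- sqrt(sum((e3[1, ] - e3[100, ])^2))
  expect_equal(gap, 2 * sin(1 * pi / 180) * scale, tolerance = 1e-6)
  expect_lt(gap / scale, 0.05)   # tiny relative to the encoded circle
})

test_that("LBD metrics recover constructed clamshell geometry", {
  # synthetic LBD: D1 = fixed triad, D2 = triad below it, per chain
  mk <- function(rot_deg = 0) {
    rows <- list()
    for (ch in c("A", "B", "C", "D")) {
      base <- switch(ch, A = c(20, 0), B = c(0, 20), C = c(-20, 0),
                     D = c(0, -20))
      d1 <- cbind(x = base[1] + c(0, 2, 1), y = base[2] + c(0, 0, 2),
                  z = c(30, 30, 32))
      d2 <- cbind(x = base[1] + c(0, 2, 1), y = base[2] + c(0, 0, 2),
                  z = c(20, 20, 22))
      if (rot_deg != 0) {
        th <- rot_deg * pi / 180
        r <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0,
                      sin(th), 0, cos(th)), 3, 3)
        ctr <- colMeans(d1)
        d2 <- sweep(sweep(d2, 2, ctr) %*% r, 2, -ctr)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = c(701:703, 711:713), resid = "ALA",
        elety = "CA", elesy = "C",
        x = c(d1[, 1], d2[, 1]), y = c(d1[, 2], d2[, 2]),
        z = c(d1[, 3], d2[, 3]), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = 635, resid = "ALA", elety = "CA", elesy = "C",
        x = base[1], y = base[2], z = 25, stringsAsFactors = FALSE)
    }
    structure_model(do.call(rbind, rows))
  }
  apo <- mk(0)
  same <- lbd_metrics(apo, apo, d1_resnos = 701:703, d2_resnos = 711:713)
  expect_true(all(abs(same$alpha) < 1e-6))
  closed <- lbd_metrics(mk(20), apo, d1_resnos = 701:703,
                        d2_resnos = 711:713)
  expect_equal(unname(closed$alpha), rep(20, 4), tolerance = 0.1)
  # marker separation: A and C sit 40 apart by construction
  expect_equal(unname(same$d635["AD"]),
               sqrt(sum((c(20, 0) - c(0, -20))^2)), tolerance = 1e-9)
  expect_error(lbd_metrics(apo, apo), "partitions")
})
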