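test_that("generated fixtures round-trip every order parameter", {
  cases <- list(
    list(d_WC = 0.30, d_HG = 0.60, chi = -120, theta = -5, phi = 10,
         n_waters = 8),                       # WC-like
    list(d_WC = 0.60, d_HG = 0.30, chi = 60, theta = -8, phi = -150,
         n_waters = 8),                       # HG-like
    list(d_WC = 0.45, d_HG = 0.45, chi = 179, theta = -60, phi = -90,
         n_waters = 25),                      # open, solvent-exposed
    list(d_WC = 0.40, d_HG = 0.50, chi = 0, theta = 30, phi = 135,
         n_waters = 12))
  for (cs in cases) {
    fx <- do.call(build_fixture, cs)
    d <- hbond_distances(fx$frame)
    expect_equal(unname(d["d_WC"]), cs$d_WC, tolerance = 1e-6)
    expect_equal(unname(d["d_HG"]), cs$d_HG, tolerance = 1e-6)
    expect_equal(unname(d["d_BP"]), 0.29, tolerance = 1e-6)
    expect_equal(glycosidic_chi(fx$frame), cs$chi, tolerance = 1e-6)
    expect_equal(opening_theta(fx$frame, fx$theta_selections), cs$theta,
                 tolerance = 1e-6)
    expect_equal(rolling_phi(fx$frame), cs$phi, tolerance = 1e-6)
    expect_equal(count_waters(fx$frame), cs$n_waters)
  }
})

test_that("the progress coordinate reproduces the WC and HG values", {
  expect_equal(round(lambda_from_distances(0.3, 0.6), 2), 0.46)
  expect_equal(round(lambda_from_distances(0.6, 0.3), 2), 1.11)
  wc <- build_fixture(d_WC = 0.30, d_HG = 0.60)
  d <- hbond_distances(wc$frame)
  expect_equal(round(lambda_from_distances(d[["d_WC"]], d[["d_HG"]]), 2),
               0.46)
  hg <- build_fixture(d_WC = 0.60, d_HG = 0.30)
  d <- hbond_distances(hg$frame)
  expect_equal(round(lambda_from_distances(d[["d_WC"]], d[["d_HG"]]), 2),
               1.11)
})

test_that("the progress coordinate is scale-invariant and monotone", {
  set.seed(6)
  for (i in 1:20) {
    dw <- runif(1, 0.1, 1); dh <- runif(1, 0.1, 1); cc <- runif(1, 0.1, 10)
    expect_equal(lambda_from_distances(cc * dw, cc * dh),
                 lambda_from_distances(dw, dh))
  }
  expect_equal(lambda_from_distances(0.37, 0.37), pi / 4)
  expect_gt(lambda_from_distances(0.4, 0.5),
            lambda_from_distances(0.3, 0.5))
  expect_lt(lambda_from_distances(0.3, 0.6),
            lambda_from_distances(0.3, 0.5))
  expect_error(lambda_from_distances(0, 0), "undefined")
  expect_error(lambda_from_distances(-0.1, 0.5), "non-negative")
})

test_that("dihedral construction fixes the glycosidic sign convention", {
  # planar cis/trans constructions and a +90 degree rotation about the axis
  for (target in c(0, 180, 90, -90, 37.5)) {
    fx <- build_fixture(chi = target)
    expect_equal(glycosidic_chi(fx$frame), target, tolerance = 1e-6)
  }
  # collinear O4'-C1'-N9 triple
  atoms <- data.frame(
    residue_id = "4DA'",
    atom_name = c("O4'", "C1'", "N9", "C4"),
    x = c(0, 1, 2, 3), y = c(0, 0, 0, 1), z = 0)
  expect_error(glycosidic_chi(labeled_frame(atoms)), "collinear")
})

test_that("the opening angle is zero for the aligned construction", {
  fx <- build_fixture(theta = 0)
  expect_equal(opening_theta(fx$frame, fx$theta_selections), 0,
               tolerance = 1e-6)
  for (target in c(-22, -50, 65)) {
    fx <- build_fixture(theta = target)
    expect_equal(opening_theta(fx$frame, fx$theta_selections), target,
                 tolerance = 1e-6)
  }
  # a stacked, in-helix geometry stays near zero opening
  fx <- build_fixture(theta = -5)
  expect_lt(abs(opening_theta(fx$frame, fx$theta_selections)), 10)
  # zero-length arm
  sel <- fx$theta_selections
  sel$I <- sel$II
  expect_error(opening_theta(fx$frame, sel), "zero-length")
})

test_that("the rolling angle covers perpendicular and parallel cases", {
  for (target in c(90, -90, 0, 180, 10, -135)) {
    fx <- build_fixture(phi = target)
    expect_equal(rolling_phi(fx$frame), target, tolerance = 1e-6)
  }
})

test_that("water counting uses a strict cutoff and ignores order", {
  fx <- build_fixture(n_waters = 0)
  expect_equal(count_waters(fx$frame), 0L)
  n6 <- atom_position(fx$frame, "4DA'", "N6")
  fr <- labeled_frame(fx$frame$atoms,
                      water_oxygens = rbind(n6 + c(0.59, 0, 0),
                                            n6 + c(0, 0.61, 0)))
  expect_equal(count_waters(fr), 1L)
  fx12 <- build_fixture(n_waters = 12, n_waters_outside = 4)
  expect_equal(count_waters(fx12$frame), 12L)
  w <- fx12$frame$water_oxygens
  set.seed(7)
  fr_perm <- labeled_frame(fx12$frame$atoms,
                           water_oxygens = w[sample(nrow(w)), ])
  expect_equal(count_waters(fr_perm), 12L)
})

test_that("all order parameters are invariant under rigid motions", {
  fx <- build_fixture(d_WC = 0.35, d_HG = 0.55, chi = -47, theta = -33,
                      phi = 71, n_waters = 9)
  ref <- c(hbond_distances(fx$frame),
           chi = glycosidic_chi(fx$frame),
           theta = opening_theta(fx$frame, fx$theta_selections),
           phi = rolling_phi(fx$frame),
           nw = count_waters(fx$frame))
  set.seed(8)
  for (i in 1:5) {
    fr <- transform_frame(fx$frame, random_rotation(), runif(3, -5, 5))
    got <- c(hbond_distances(fr),
             chi = glycosidic_chi(fr),
             theta = opening_theta(fr, fx$theta_selections),
             phi = rolling_phi(fr),
             nw = count_waters(fr))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("inconsistent fixture targets and missing atoms raise errors", {
  expect_error(build_fixture(d_WC = 0.05, d_HG = 0.9), "do not intersect")
  fx <- build_fixture()
  expect_error(atom_position(fx$frame, "4DA'", "XX"), "atom not found")
  expect_error(count_waters(fx$frame, c("9DT", "N6")), "not found")
  pm <- default_hbond_pairs(adenine = "nope")
  expect_error(hbond_distances(fx$frame, pm), "nope")
})

test_that("order_param_vector bundles the per-frame values", {
  fx <- build_fixture(d_WC = 0.30, d_HG = 0.60, chi = -120, theta = -5,
                      phi = 10, n_waters = 8)
  v <- order_param_vector(fx$frame, fx$theta_selections)
  expect_equal(v$lambda, atan2(0.3, 0.6), tolerance = 1e-6)
  expect_equal(v$chi, -120, tolerance = 1e-6)
  expect_equal(v$theta, -5, tolerance = 1e-6)
  expect_equal(v$n_water, 8L)
})

test_that("coordinate frames round-trip through the text format", {
  fx <- build_fixture(n_waters = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_frame(fx$frame, path)
  back <- read_frame(path)
  expect_equal(back$atoms$residue_id, fx$frame$atoms$residue_id)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(fx$frame$atoms[, c("x", "y", "z")]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$water_oxygens, fx$frame$water_oxygens,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(count_waters(back), 4L)
})
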