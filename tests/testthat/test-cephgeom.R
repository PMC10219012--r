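test_that("calibration rescales by the reference ratio and round-trips", {
  lm <- ceph_landmarks(
    Pi = c(0, 0), Ns = c(400, 92), Ie = c(200, 0), Dc = c(100, -10),
    Ref0 = c(0, 0), Ref1 = c(0, 100), ref_distance_mm = 50
  )
  cal <- calibrate_landmarks(lm)
  expect_equal(unname(cal$x[cal$landmark == "Ie"]), 100)
  expect_equal(unname(cal$y[cal$landmark == "Ie"]), 0)
  expect_true(attr(cal, "calibrated"))

  # ref distance equal to the pixel distance: identity mapping
  lm_id <- ceph_landmarks(
    Pi = c(0, 0), Ns = c(100, 23), Ie = c(95, -40), Dc = c(60, -38),
    Ref0 = c(0, -60), Ref1 = c(0, 40), ref_distance_mm = 100
  )
  cal_id <- calibrate_landmarks(lm_id)
  expect_equal(cal_id$x, lm_id$x)
  expect_equal(cal_id$y, lm_id$y)

  # round-trip oracle: scale a known-mm set by an arbitrary factor, then
  # calibrate back
  set.seed(41)
  for (s in c(0.3, 2.7, 11)) {
    truth <- invert_mounting(
      runif(1, -20, 20), runif(1, 10, 50), runif(1, 60, 120),
      fixture_facebow()
    )
    px <- truth
    px$x <- px$x * s
    px$y <- px$y * s
    attr(px, "calibrated") <- FALSE
    back <- calibrate_landmarks(px)
    expect_equal(back$x, truth$x, tolerance = 1e-12)
    expect_equal(back$y, truth$y, tolerance = 1e-12)
  }

  bad <- ceph_landmarks(
    Pi = c(0, 0), Ns = c(100, 23), Ie = c(95, -40), Dc = c(60, -38),
    Ref0 = c(1, 1), Ref1 = c(1, 2), ref_distance_mm = 50
  )
  bad$y[bad$landmark == "Ref1"] <- 1 # force coincident scaling markers
  expect_error(calibrate_landmarks(bad), "Degenerate scaling")
  expect_error(
    ceph_landmarks(
      Pi = c(0, 0), Ns = c(100, 23), Ie = c(95, -40), Dc = c(60, -38),
      Ref0 = c(1, 1), Ref1 = c(1, 1), ref_distance_mm = 50
    ),
    "must differ"
  )
})

test_that("axis-orbital line is tangent to the nasal-support circle", {
  fb <- facebow_spec(d_ns_mm = 20)
  lm <- ceph_landmarks(
    Pi = c(0, 0), Ns = c(100, 20), Ie = c(95, -40), Dc = c(60, -38),
    Ref0 = c(0, -60), Ref1 = c(50, -60), ref_distance_mm = 50,
    calibrated = TRUE
  )
  aop <- construct_aop(lm, fb)
  expect_equal(aop$direction, c(1, 0), tolerance = 1e-12)
  expect_equal(aop$b, c(100, 0), tolerance = 1e-12)

  # degenerate tangent: d_ns = 0 puts the line through Ns itself
  aop0 <- construct_aop(lm, facebow_spec(d_ns_mm = 0))
  expect_equal(aop0$b, c(100, 20), tolerance = 1e-9)

  # property: the returned line always sits at distance d_ns from Ns
  set.seed(42)
  for (i in 1:50) {
    d_ns <- runif(1, 0, 40)
    lmr <- ceph_landmarks(
      Pi = c(0, 0), Ns = c(runif(1, 60, 140), runif(1, d_ns, 60)),
      Ie = c(95, -40), Dc = c(60, -38),
      Ref0 = c(0, -60), Ref1 = c(50, -60), ref_distance_mm = 50,
      calibrated = TRUE
    )
    aopr <- construct_aop(lmr, facebow_spec(d_ns_mm = d_ns))
    ns <- c(lmr$x[lmr$landmark == "Ns"], lmr$y[lmr$landmark == "Ns"])
    dist_line <- abs((ns[1] - aopr$point[1]) * (-aopr$direction[2]) +
      (ns[2] - aopr$point[2]) * aopr$direction[1])
    expect_equal(dist_line, d_ns, tolerance = 1e-9)
    # b is the foot of the perpendicular from Ns
    expect_equal(sum((ns - aopr$b) * aopr$direction), 0, tolerance = 1e-9)
  }

  # Ns closer to the anchor than d_ns: no tangent line exists
  lm_close <- ceph_landmarks(
    Pi = c(0, 0), Ns = c(5, 5), Ie = c(95, -40), Dc = c(60, -38),
    Ref0 = c(0, -60), Ref1 = c(50, -60), ref_distance_mm = 50,
    calibrated = TRUE
  )
  expect_error(construct_aop(lm_close, fb), "Infeasible facebow")
})

test_that("mounting computation inverts the landmark synthesis", {
  fb <- fixture_facebow()
  for (triple in list(c(11, 27, 88), c(8, 36, 99), c(2, 36, 86), c(-5, 30, 90))) {
    lm <- invert_mounting(triple[1], triple[2], triple[3], fb)
    got <- compute_mounting(lm, fb)
    expect_equal(got$alpha_deg, triple[1], tolerance = 1e-6)
    expect_equal(got$axv_mm, triple[2], tolerance = 1e-6)
    expect_equal(got$axh_mm, triple[3], tolerance = 1e-6)
  }

  # parallel planes: alpha exactly 0
  lm0 <- invert_mounting(0, 30, 90, fb)
  expect_equal(compute_mounting(lm0, fb)$alpha_deg, 0, tolerance = 1e-12)

  # property sweep over 1000 random feasible triples
  set.seed(43)
  worst <- 0
  for (i in 1:1000) {
    tr <- c(runif(1, -30, 30), runif(1, 5, 60), runif(1, 40, 130))
    lm <- invert_mounting(tr[1], tr[2], tr[3], fb,
      ns_x_mm = runif(1, 80, 120), ie_dc_span_mm = runif(1, 25, 45)
    )
    got <- unlist(compute_mounting(lm, fb))
    worst <- max(worst, abs(got - tr))
  }
  expect_lt(worst, 1e-6)

  expect_error(invert_mounting(95, 30, 90, fb), "Infeasible")
  expect_error(invert_mounting(10, -1, 90, fb), "Infeasible")
})

test_that("mounting values are invariant under rigid motion of the landmarks", {
  fb <- fixture_facebow()
  base <- invert_mounting(11, 27, 88, fb)
  ref <- compute_mounting(base, fb)
  set.seed(44)
  for (i in 1:20) {
    theta <- runif(1, -30, 30) * pi / 180
    shift <- runif(2, -200, 200)
    moved <- transform_landmarks(base, theta, shift)
    got <- compute_mounting(moved, fb)
    expect_equal(got$alpha_deg, ref$alpha_deg, tolerance = 1e-9)
    expect_equal(got$axv_mm, ref$axv_mm, tolerance = 1e-9)
    expect_equal(got$axh_mm, ref$axh_mm, tolerance = 1e-9)
  }
})

test_that("derived articulator values satisfy the right-triangle identity", {
  # Pythagorean triple
  d <- derive_articulator_values(tibble::tibble(axv_mm = 4, axh_mm = 3))
  expect_equal(d$ie_ax_mm, 5)
  expect_equal(d$balkwill_deg, atan(4 / 3) * 180 / pi, tolerance = 1e-12)

  # degenerate: axis on the occlusal plane
  d0 <- derive_articulator_values(tibble::tibble(axv_mm = 0, axh_mm = 1))
  expect_equal(d0$ie_ax_mm, 1)
  expect_equal(d0$balkwill_deg, 0)

  # cluster-1 mean geometry
  d1 <- derive_articulator_values(tibble::tibble(axv_mm = 36.2, axh_mm = 98.9))
  expect_equal(d1$ie_ax_mm, 105.3, tolerance = 0.05)
  expect_equal(d1$balkwill_deg, 20.1, tolerance = 0.005)

  # identity holds across random values, and ie_ax dominates both legs
  set.seed(45)
  tbl <- tibble::tibble(axv_mm = runif(50, 0, 60), axh_mm = runif(50, 1, 130))
  dd <- derive_articulator_values(tbl)
  expect_equal(dd$ie_ax_mm^2, dd$axh_mm^2 + dd$axv_mm^2, tolerance = 1e-12)
  expect_true(all(dd$ie_ax_mm >= pmax(dd$axv_mm, dd$axh_mm)))
  expect_error(
    derive_articulator_values(tibble::tibble(axv_mm = 1, axh_mm = 0)),
    "undefined"
  )

  expect_equal(bonwill_norm_mm, 101.6)
  expect_equal(balkwill_norm_range_deg, c(18, 25))
})

test_that("presets round half-up, not half-even", {
  expect_equal(round_half_up(c(26.5, 2.5, 2.4, 88.1)), c(27, 3, 2, 88))
  got <- round_presets(table3_centers())
  expect_equal(got$alpha_deg, c(8, 11, 2))
  expect_equal(got$axv_mm, c(36, 27, 36))
  expect_equal(got$axh_mm, c(99, 88, 86))
  expect_equal(got$phenotype, table3_centers()$phenotype)
})
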