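test_that("alpha is the square root of the factor count", {
  expect_equal(ccd_alpha(3), sqrt(3))
  expect_equal(ccd_alpha(1), 1)
  expect_equal(ccd_alpha(4), 2)
  expect_error(ccd_alpha(0), "integer")
})

test_that("half-fraction corners have positive sign product and complete the cube", {
  hf <- half_fraction_corners(3)
  expect_equal(nrow(hf), 4L)
  expect_true(all(apply(hf, 1, prod) == 1))
  expect_true(all(sqrt(rowSums(hf^2)) == sqrt(3)))
  mirror <- -hf
  all8 <- unique(rbind(hf, mirror))
  expect_equal(nrow(all8), 8L)
})

test_that("one CCD iteration has the right point counts and geometry", {
  sub1 <- subregion_first(design_space(), 0.7)
  pts <- generate_ccd(sub1, include_center = TRUE)
  expect_equal(nrow(pts), 11L)
  expect_equal(sum(pts$role == "center"), 1L)
  expect_equal(sum(pts$role == "axial"), 6L)
  expect_equal(sum(pts$role == "factorial"), 4L)
  expect_equal(nrow(generate_ccd(sub1, include_center = FALSE)), 10L)

  coded <- as.matrix(pts[, paste0("coded_", c("flowrate", "temperature",
                                              "dilution"))])
  # spherical design: every non-center point on the coded unit sphere
  radii <- sqrt(rowSums(coded^2))
  expect_equal(radii[pts$role != "center"],
               rep(1, 10), tolerance = 1e-12)
  # all real coordinates inside the subregion
  for (nm in c("flowrate", "temperature", "dilution")) {
    expect_true(all(pts[[nm]] >= sub1$center[nm] - sub1$half_span[nm] -
                      1e-9))
    expect_true(all(pts[[nm]] <= sub1$center[nm] + sub1$half_span[nm] +
                      1e-9))
  }
})

test_that("first subregion is the centered fraction of each axis", {
  space <- design_space()
  sub <- subregion_first(space, 0.7)
  expect_equal(unname(sub$center["flowrate"]), 1.1)
  expect_equal(unname(sub$half_span["flowrate"]), 0.63)
  expect_equal(unname(sub$center["dilution"] - sub$half_span["dilution"]),
               9.4)
  full <- subregion_first(space, 1)
  expect_equal(unname(full$half_span["temperature"]), 5)
  expect_error(subregion_first(space, 0), "fraction")
})

test_that("design coordinates reproduce the reported campaign runs", {
  # axial and factorial coordinates of the first iteration, and the
  # second iteration around each observed best point, match the
  # published campaign values
  space <- design_space()
  sub1 <- subregion_first(space, 0.7)
  pts1 <- generate_ccd(sub1)
  # dilution axial low point: (1.1 mL/min, 30 C, dilution 9.4)
  ax <- pts1[pts1$role == "axial" & pts1$coded_dilution == -1, ]
  expect_equal(ax$flowrate, 1.1)
  expect_equal(ax$temperature, 30)
  expect_equal(ax$dilution, 9.4)
  # factorial corner (+,+,-): (1.464 mL/min, 32.02 C, 14.73)
  corner <- pts1[pts1$role == "factorial" & pts1$coded_flowrate > 0 &
                   pts1$coded_dilution < 0, ]
  expect_equal(corner$flowrate, 1.1 + 0.63 / sqrt(3), tolerance = 1e-12)
  expect_equal(corner$dilution, 22 - 12.6 / sqrt(3), tolerance = 1e-12)

  # zooming on the dilution-axial best reaches dilution 4.36
  sub2 <- subregion_second(space, sub1,
                           c(flowrate = 1.1, temperature = 30,
                             dilution = 9.4))
  pts2 <- generate_ccd(sub2, include_center = FALSE, iteration = 2L)
  expect_equal(min(pts2$dilution), 4.36, tolerance = 1e-9)
  expect_equal(unname(sub2$half_span["flowrate"]), 0.252)
  expect_equal(unname(sub2$center["flowrate"] - sub2$half_span["flowrate"]),
               0.848)
})

test_that("second subregion stays inside the space for any best point", {
  space <- design_space()
  sub1 <- subregion_first(space, 0.7)
  set.seed(11)
  for (i in 1:25) {
    best <- sub1$center + runif(3, -1, 1) * sub1$half_span
    names(best) <- names(sub1$center)
    sub2 <- subregion_second(space, sub1, best, 0.4)
    pts <- generate_ccd(sub2, include_center = FALSE, iteration = 2L)
    for (nm in c("flowrate", "temperature", "dilution")) {
      b <- space$bounds[[nm]]
      expect_true(all(pts[[nm]] >= b[1] - 1e-9 & pts[[nm]] <= b[2] + 1e-9))
    }
  }
  # centered best keeps the regions concentric
  sub2c <- subregion_second(space, sub1, sub1$center, 0.4)
  expect_equal(sub2c$center, sub1$center)
  expect_error(subregion_second(space, sub1,
                                c(flowrate = 0.1, temperature = 30,
                                  dilution = 22)),
               "inside")
})

test_that("coverage fraction matches the two-stage zoom arithmetic", {
  expect_equal(coverage_fraction(0.7, 0.4), 0.98)
  expect_equal(coverage_fraction(1, 0.5), 1)
  expect_equal(coverage_fraction(0.5, 0.5), 0.75)
  expect_error(coverage_fraction(0, 0.4), "fraction")
})

test_that("coded and real coordinates convert exactly both ways", {
  sub <- subregion_first(design_space(), 0.7)
  expect_equal(unname(coded_to_real(c(0, 0, 0), sub)),
               unname(sub$center))
  set.seed(5)
  for (i in 1:10) {
    coded <- runif(3, -1, 1)
    names(coded) <- names(sub$center)
    expect_equal(real_to_coded(coded_to_real(coded, sub), sub), coded,
                 tolerance = 1e-12)
  }
})

test_that("select_best maximizes STY with run-order tie-breaking", {
  res <- data.frame(run_index = 1:3, sty = c(3, 9, 7))
  expect_equal(select_best(res)$run_index, 2L)
  tie <- data.frame(run_index = 1:2, sty = c(5, 5))
  expect_equal(select_best(tie)$run_index, 1L)
  expect_error(select_best(res[0, ]), "no results")
})

test_that("campaign plans are deterministic with 11 + 10 = 21 runs", {
  config <- campaign_config()
  p1 <- plan_campaign(config)
  expect_equal(nrow(p1$points), 11L)
  best <- c(flowrate = 1.1, temperature = 30, dilution = 9.4)
  full <- plan_campaign(config, best = best)
  expect_equal(nrow(full$points), 21L)
  expect_equal(sum(full$points$iteration == 2L), 10L)
  expect_equal(full$alpha, sqrt(3))
  # second-iteration center is the first-iteration best (not re-run)
  expect_equal(unname(full$subregion_2$center), unname(best))
  expect_false(any(full$points$iteration == 2L &
                     full$points$role == "center"))
  # determinism: identical config gives an identical plan
  expect_identical(plan_campaign(config, best = best)$points, full$points)
  # containment in the full design space
  for (nm in c("flowrate", "temperature", "dilution")) {
    b <- design_space()$bounds[[nm]]
    expect_true(all(full$points[[nm]] >= b[1] & full$points[[nm]] <= b[2]))
  }
})
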