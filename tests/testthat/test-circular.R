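test_that("axial bearing handles meridian, equator and argument order", {
  expect_equal(axial_bearing(39, -117, 41, -117), 0)
  expect_equal(axial_bearing(0, -117, 0, -115), 90)
  expect_error(axial_bearing(39, -117, 39, -117), "coincident")

  # folding makes the ordering irrelevant up to meridian convergence,
  # which is bounded by dlon * sin(lat); sub-half-degree for pairs whose
  # longitude separation is small
  set.seed(3)
  for (i in 1:50) {
    lat1 <- runif(1, 38, 42); lon1 <- runif(1, -120, -114)
    lat2 <- lat1 + runif(1, -2, 2); lon2 <- lon1 + runif(1, -2, 2)
    if (lat1 == lat2 && lon1 == lon2) next
    f <- axial_bearing(lat1, lon1, lat2, lon2)
    r <- axial_bearing(lat2, lon2, lat1, lon1)
    d <- min(abs(f - r), 180 - abs(f - r))
    bound <- abs(lon2 - lon1) * sin(max(abs(c(lat1, lat2))) * pi / 180)
    expect_lte(d, bound + 1e-6)
    if (abs(lon2 - lon1) < 0.7) expect_lt(d, 0.5)
  }
})

test_that("spherical bearing matches the geodesic oracle within 0.2 degrees", {
  skip_if_not_installed("geosphere")
  set.seed(5)
  for (i in 1:50) {
    lat1 <- runif(1, 36, 44); lon1 <- runif(1, -122, -112)
    lat2 <- runif(1, 36, 44); lon2 <- runif(1, -122, -112)
    if (lat1 == lat2 && lon1 == lon2) next
    mine <- axial_bearing(lat1, lon1, lat2, lon2)
    oracle <- geosphere::bearing(c(lon1, lat1), c(lon2, lat2)) %% 180
    d <- min(abs(mine - oracle), 180 - abs(mine - oracle))
    expect_lt(d, 0.2)
  }
})

test_that("locality bearing resolves ids and orders them lexicographically", {
  locs <- data.frame(locality_id = c("B", "A"), name = c("b", "a"),
                     lat = c(41, 39), lon = c(-117, -117))
  expect_equal(locality_bearing(locs, "A", "B"),
               locality_bearing(locs, "B", "A"))
  expect_error(locality_bearing(locs, "A", "Z"), "unresolvable")
  expect_error(locality_bearing(locs, "A", "A"), "undefined")
})

test_that("axial summary doubles, averages and halves back", {
  s <- axial_summary(rep(23, 5))
  expect_equal(s$mu, 23)
  expect_equal(s$mu_reciprocal, 203)
  expect_equal(s$rbar, 1)

  # orthogonal axes cancel after doubling
  s0 <- axial_summary(c(0, 90))
  expect_equal(s0$rbar, 0, tolerance = 1e-12)
  expect_true(is.na(s0$mu))

  expect_error(axial_summary(c(10, 190)), "\\[0, 180\\)")
})

test_that("mean axis is recovered from concentrated axial samples", {
  set.seed(17)
  ok <- 0L
  for (r in 1:20) {
    a2 <- phylodapp:::rvonmises(200, 2 * 23 * pi / 180, 5)
    ang <- ((a2 * 180 / pi) / 2) %% 180
    mu <- axial_summary(ang)$mu
    dev <- min(abs(mu - 23), 180 - abs(mu - 23))
    if (dev < 5) ok <- ok + 1L
  }
  expect_gte(ok, 19)
})

test_that("Rayleigh statistic and series P behave at the extremes", {
  n <- 12
  r <- rayleigh_test(rep(37, n))
  expect_equal(r$statistic, n)
  expect_lt(r$p_value, 1e-4)
  # the survey's printed statistic falls below the 0.001 band at its n
  expect_lt(phylodapp:::rayleigh_series_p(10.538, 30), 0.001)
  # rotation invariance of Z
  set.seed(23)
  a <- runif(20, 0, 180)
  expect_equal(rayleigh_test(a)$statistic,
               rayleigh_test((a + 57) %% 180)$statistic,
               tolerance = 1e-9)
})

test_that("Rao spacing statistic hits its analytic extremes", {
  n <- 10
  equal <- seq(0, 180 - 180 / n, by = 180 / n)  # doubled: equally spaced
  expect_equal(rao_spacing_test(equal)$statistic, 0, tolerance = 1e-9)
  clustered <- rep(23, n) + seq(0, 1e-9, length.out = n)
  expect_equal(rao_spacing_test(clustered)$statistic, 360 - 360 / n,
               tolerance = 1e-6)
  expect_error(rao_spacing_test(c(1, 2, 3)), "n >= 4")
})

test_that("packaged Rao critical values match a fresh null simulation", {
  set.seed(29)
  u <- replicate(3000, phylodapp:::rao_stat(runif(30, 0, 180)))
  emp95 <- unname(stats::quantile(u, 0.95))
  packaged <- phylodapp:::rao_critical(30)$c005
  # Monte-Carlo error of the 3000-rep 95th percentile is ~ +/- 0.6 deg
  expect_lt(abs(emp95 - packaged), 2)
})

test_that("Kuiper series P reproduces the standard critical points", {
  expect_lt(abs(phylodapp:::kuiper_series_p(1.747) - 0.050), 0.002)
  expect_lt(phylodapp:::kuiper_series_p(2.712), 0.01)
  # V* for a tightly clustered sample is large, P small
  k <- kuiper_test(rep(90, 10) + seq(0, 1e-6, length.out = 10))
  expect_lt(k$p_value, 1e-6)
})

test_that("two-sample tests are calm on exchangeable or identical input", {
  set.seed(31)
  a <- runif(12, 0, 180)
  # identical multisets: W near null expectation, U2 exactly 0
  expect_gt(suppressWarnings(mww_test(a, a))$p_value, 0.5)
  expect_equal(suppressWarnings(watson_u2_test(a, a))$statistic, 0,
               tolerance = 1e-12)
  expect_error(mww_test(rep(10, 6), rep(10, 6)), "identical")
})

test_that("Watson series P reproduces the standard critical points", {
  expect_lt(abs(phylodapp:::watson_series_p(0.268) - 0.010), 0.001)
  expect_lt(phylodapp:::watson_series_p(0.402), 0.001)
})

test_that("chi-square tail of the MWW statistic matches the closed form", {
  expect_equal(stats::pchisq(14.72, 2, lower.tail = FALSE),
               exp(-14.72 / 2), tolerance = 1e-12)
  expect_lt(stats::pchisq(14.72, 2, lower.tail = FALSE), 0.001)
})

test_that("two-sample statistics are invariant under a common axis shift", {
  set.seed(37)
  a <- runif(15, 0, 180); b <- runif(20, 0, 180)
  for (shift in c(30, 77, 121)) {
    expect_equal(mww_test(a, b)$statistic,
                 mww_test((a + shift) %% 180, (b + shift) %% 180)$statistic,
                 tolerance = 1e-6)
    expect_equal(watson_u2_test(a, b)$statistic,
                 watson_u2_test((a + shift) %% 180,
                                (b + shift) %% 180)$statistic,
                 tolerance = 1e-6)
  }
})

test_that("heavy ties trigger the midrank warning", {
  a <- c(rep(10, 10), 20, 30); b <- c(rep(10, 5), 40, 50, 60, 70, 80)
  expect_warning(mww_test(a, b), "tie")
})

test_that("dapp pipeline carries provenance and matches the pair count", {
  cfg <- sim_config(seed = 4242)
  geo <- simulate_localities_and_sharing(cfg)
  dp <- dapp_pipeline(geo$sharing, geo$localities, geo$pattern_assignment)
  expect_equal(nrow(dp$bearings), sharing_pairs(geo$sharing)$n_pairs)
  expect_true(all(c("haplotype_id", "locality_a", "locality_b", "angle",
                    "pattern") %in% names(dp$bearings)))
  expect_true(all(dp$bearings$angle >= 0 & dp$bearings$angle < 180))
  # designed pattern sizes: 30 axial pairs north-south, 36 web
  expect_equal(length(dp$patterns$northsouth$angles), 30)
  expect_equal(length(dp$patterns$web$angles), 36)
  # two-sample comparison present for the pattern pair
  expect_length(dp$comparisons, 1)
  expect_s3_class(dp$comparisons[[1]]$mww, "circ_test")

  # single shared haplotype at 2 localities: one bearing, underpowered
  sh1 <- geo$sharing[geo$sharing$n_localities == 2, ][1, ]
  dp1 <- dapp_pipeline(sh1, geo$localities,
                       stats::setNames("solo", sh1$haplotype_id))
  expect_equal(nrow(dp1$bearings), 1)
  expect_true(dp1$patterns$solo$underpowered)
  expect_null(dp1$patterns$solo$rayleigh)

  expect_error(dapp_pipeline(geo$sharing, geo$localities,
                             geo$pattern_assignment[-1]),
               "without a pattern label")
})

test_that("designed orientation patterns separate under the pipeline", {
  cfg <- sim_config(seed = 5150)
  geo <- simulate_localities_and_sharing(cfg)
  dp <- dapp_pipeline(geo$sharing, geo$localities, geo$pattern_assignment)
  # concentrated north-south axis: uniformity rejected
  expect_lt(dp$patterns$northsouth$rayleigh$p_value, 0.01)
  mu <- dp$patterns$northsouth$summary$mu
  expect_lt(min(abs(mu - 20), 180 - abs(mu - 20)), 15)
  # two-sample tests separate the two patterns
  expect_lt(dp$comparisons[[1]]$mww$p_value, 0.05)
  expect_lt(dp$comparisons[[1]]$watson_u2$p_value, 0.05)
})
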