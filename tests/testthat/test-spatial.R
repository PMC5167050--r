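test_that("Geary's C on the four-point line equals the hand-computed 0.30", {
  v <- c(1, 2, 3, 4)
  coords <- cbind(x = 0:3, y = 0)
  expect_equal(geary_c(v, coords, d = 1), 0.30)
  expect_error(geary_c(v, coords, d = 0.5), "no neighbors")
  expect_warning(cc <- geary_c(rep(2, 4), coords, d = 1), "zero variance")
  expect_true(is.na(cc))
})

test_that("Geary's C is invariant under affine transformation of the values", {
  set.seed(12)
  coords <- subplot_grid()[c("x", "y")]
  v <- rnorm(60)
  for (d in c(3.5, 5)) {
    expect_equal(geary_c(3.2 * v - 7, coords, d), geary_c(v, coords, d))
  }
})

test_that("spatially permuted values average to C of about 1", {
  set.seed(13)
  coords <- subplot_grid()[c("x", "y")]
  v <- rnorm(60)
  cs <- vapply(1:1000, function(i) geary_c(sample(v), coords, 3.5),
               numeric(1))
  expect_lt(abs(mean(cs) - 1), 0.05)
})

test_that("profiles rise with distance on clustered surveys and flatten when shuffled", {
  sim <- simulate_bait_survey(separated_config(sharpness = 4), seed = 13)
  s <- sim$survey
  p <- suppressMessages(geary_profile(s, "Sol", transform = "log1p"))
  expect_true(is.na(p$mean_c[["2.5"]]))  # below the grid spacing
  focal <- c("Sol", "Nyl", "Mon", "Phe", "Bra")
  mc <- rowMeans(sapply(focal, function(sp)
    suppressMessages(geary_profile(s, sp, transform = "log1p"))$mean_c))
  expect_lt(mc[["3.5"]], mc[["6"]])

  set.seed(14)
  obs <- s$observations
  for (d in unique(obs$date)) for (t in unique(obs$time)) {
    sel <- obs$date == d & obs$time == t
    obs[sel, s$species] <- obs[sel, s$species][sample(sum(sel)), ]
  }
  shuffled <- bait_survey(obs, s$subplots, species = s$species)
  p2 <- suppressMessages(geary_profile(shuffled, "Sol",
                                       transform = "log1p"))
  expect_true(all(abs(p2$mean_c[!is.na(p2$mean_c)] - 1) < 0.12))
})

test_that("single-snapshot profiles equal the snapshot values and constants are skipped", {
  counts <- cbind(A = c(5, 6, 1, 0, 9, 2), Z = rep(3, 6))
  s <- toy_bait_survey(counts, spacing = c(3, 3))
  p <- geary_profile(s, "A", bands = c(3.5, 6.5))
  expect_equal(p$snapshots, 1)
  expect_equal(unname(p$mean_c), unname(p$C[1, ]))
  expect_message(pz <- geary_profile(s, "Z", bands = c(3.5, 6.5)),
                 "constant")
  expect_equal(pz$snapshots, 0)
})

test_that("the quadratic distance model recovers exact coefficients", {
  d <- seq(2.5, 6, 0.5)
  exact <- data.frame(d = d, C = 0.2 + 0.1 * d + 0.01 * d^2)
  f <- fit_quadratic(exact)
  expect_equal(unname(f$coefficients), c(0.2, 0.1, 0.01), tolerance = 1e-9)
  flat <- fit_quadratic(data.frame(d = d, C = 0.8))
  expect_equal(unname(flat$coefficients[2:3]), c(0, 0), tolerance = 1e-12)
  expect_error(fit_quadratic(data.frame(d = c(1, 2), C = c(1, 1))),
               "3 distinct")
  sim <- simulate_bait_survey(generator_config(), seed = 15)
  pf <- fit_quadratic(suppressMessages(geary_profile(sim$survey, "Bra")))
  expect_gte(pf$r_squared, 0)
  expect_lte(pf$r_squared, 1)
})

test_that("the neighborhood-radius rule reads the profile as documented", {
  prof <- structure(list(species = "X", bands = c(2.5, 3, 4, 5, 6),
                         mean_c = c(0.7, 0.8, 0.9, 0.99, 1.0)),
                    class = "geary_profile")
  expect_equal(select_radius(prof, tau = 0.05), 4)
  none <- prof; none$mean_c <- rep(1.2, 5)
  expect_warning(r <- select_radius(none), "falling back")
  expect_equal(r, 2.5)
  expect_equal(select_radius(prof, override = c(X = 3)), 3)
})

test_that("neighborhood abundance averages the right tiles", {
  s <- toy_bait_survey(cbind(A = c(6, 0, 12)), spacing = c(3, 3))
  nb <- neighborhood_abundance(s, "A", radius = 3.5)
  expect_equal(nb$neighborhood, c(0, 9, 0))  # centre sees 6 and 12
  nb_far <- neighborhood_abundance(s, "A", radius = 100)
  expect_equal(nb_far$neighborhood, c(6, 9, 3))  # grand mean minus self
  expect_message(nb_none <- neighborhood_abundance(s, "A", radius = 2),
                 "without neighbors")
  expect_true(all(is.na(nb_none$neighborhood)))
  expect_error(neighborhood_abundance(s, "A", radius = 0), "radius")
})
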