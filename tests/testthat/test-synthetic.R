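test_that("identity transition matrices freeze the latent groups", {
  cfg <- generator_config()
  I <- diag(length(cfg$states))
  dimnames(I) <- list(cfg$states, cfg$states)
  sim <- simulate_bait_survey(generator_config(T12 = I, T23 = I), seed = 3)
  expect_true(all(sim$truth$latent$g1 == sim$truth$latent$g2))
  expect_true(all(sim$truth$latent$g2 == sim$truth$latent$g3))
})

test_that("a lone species with zero off-group rate monopolizes its baits", {
  sp <- data.frame(code = "Sol", tier = "dominant")
  cfg <- generator_config(species = sp,
                          in_group_mean = c(dominant = 30),
                          out_mean = c(dominant = 0))
  sim <- simulate_bait_survey(cfg, seed = 4)
  st <- latent_states(sim)
  m <- counts_matrix(sim$survey)
  expect_true(all(m[st == "ND", "Sol"] == 0))
  big <- st == "Sol" & m[, "Sol"] > 20
  expect_gt(sum(big), 50)
  ctrl <- apply(m[big, , drop = FALSE], 1, controlling_species)
  expect_true(all(ctrl == "Sol"))
})

test_that("balanced transition sampling recovers the generating matrices from latent states", {
  sim <- simulate_bait_survey(generator_config(), seed = 1)
  tr <- sim$truth
  seqs <- as.matrix(tr$latent[paste0("g", 1:3)])
  expect_equal(nrow(seqs), 240)
  tm <- transition_model(seqs, states = tr$states)
  expect_equal(sum(tm$counts$t12), 240)
  expect_equal(sum(tm$counts$t23), 240)
  expect_lt(max(abs(tm$probs$t12 - tr$T12[tr$states, tr$states])), 0.05)
  expect_lt(max(abs(tm$probs$t23 - tr$T23[tr$states, tr$states])), 0.05)
})

test_that("multinomial latent sequences are Markov: time-3 state independent of time-1 given time-2", {
  cfg <- generator_config(transition_sampling = "multinomial")
  lat <- do.call(rbind, lapply(1:10, function(sd)
    simulate_bait_survey(cfg, seed = 200 + sd)$truth$latent))
  for (s2 in c("ND", "Sol")) {
    sel <- lat$g2 == s2
    tab <- table(lat$g1[sel], lat$g3[sel])
    tab <- tab[rowSums(tab) >= 20, colSums(tab) > 0, drop = FALSE]
    p <- suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("pitfall day/night means reflect the activity multipliers", {
  cfg <- generator_config(n_replicates = 50)
  p <- simulate_pitfall_survey(cfg, seed = 5)
  day <- p$records$interval == "day"
  r <- mean(p$records$Phe[day]) / mean(p$records$Phe[!day])
  expect_equal(r, 1.6 / 0.4, tolerance = 0.1)  # law-of-large-numbers check
})

test_that("a zero-rate species yields all-zero pitfall counts", {
  base <- generator_config()$pitfall_base
  base["Car"] <- 0
  p <- simulate_pitfall_survey(generator_config(pitfall_base = base),
                               seed = 6)
  expect_true(all(p$records$Car == 0))
})

test_that("day-night contrasts on a no-contrast species reject near the alpha rate", {
  cfg <- generator_config(n_replicates = 1)
  rej <- vapply(1:300, function(sd) {
    p <- simulate_pitfall_survey(cfg, seed = 1000 + sd)
    kruskal_wallis(p$records$Odo, p$records$interval)$p.value < 0.05
  }, logical(1))  # Odo multiplier is 1:1 by default
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("short-range autocorrelation strengthens with the kernel correlation length", {
  c_short <- vapply(c(0.5, 2, 6), function(kr) {
    sim <- simulate_bait_survey(separated_config(kernel_range = kr,
                                                 sharpness = 4), seed = 11)
    o <- sim$survey$observations
    s1 <- bait_survey(o[o$time == 1, ], sim$survey$subplots,
                      species = sim$survey$species)
    mean(vapply(c("Sol", "Nyl", "Mon", "Phe", "Bra"), function(sp)
      suppressMessages(geary_profile(s1, sp,
                                     transform = "log1p"))$mean_c[["3.5"]],
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(c_short) < 0))  # larger range => lower C at 3.5 m
})

test_that("degenerate generator configurations are rejected", {
  expect_error(generator_config(species = default_species()[0, ]),
               "no species")
  expect_error(generator_config(n_cols = 0), "n_cols")
  bad <- generator_config()$T12
  bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(generator_config(T12 = bad), "sum to 1")
})
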