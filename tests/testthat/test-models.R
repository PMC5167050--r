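pipeline_groups_t1 <- function(survey, k = 7, seed = 1) {
  a <- cluster_observations(survey, k = k, seed = seed)
  labels <- name_groups(a, survey)[a$group]
  obs <- survey$observations
  data.frame(subplot = obs$subplot[obs$time == 1],
             date = obs$date[obs$time == 1],
             group = labels[obs$time == 1])
}

test_that("the model frame holds the documented design", {
  sim <- simulate_bait_survey(generator_config(), seed = 3)
  s <- sim$survey
  g1 <- pipeline_groups_t1(s)
  radii <- c(Sol = 4, Nyl = 5, Mon = 4, Phe = 3.5, Bra = 5)
  fr <- build_model_frame(s, "Sol", radii, g1)
  expect_equal(nrow(fr), 720)
  covs <- attr(fr, "covariates")
  expect_setequal(covs, c(paste0("local_", c("Nyl", "Mon", "Phe", "Bra")),
                          paste0("nbr_", names(radii)), "time"))
  expect_equal(fr$response, s$observations$Sol)
  expect_equal(nlevels(fr$session), 12)        # 4 dates x 3 times
  expect_false(anyNA(fr[covs]))
  # neighborhood covariates agree with the standalone computation
  nb <- neighborhood_abundance(s, "Phe", 3.5)
  expect_equal(fr$nbr_Phe, nb$neighborhood)
  expect_error(build_model_frame(s, "Sol", radii, g1[-1, ]),
               "missing time-1 group")
  expect_error(build_model_frame(s, "Sol", c(Sol = 2), g1), "all rows")
})

test_that("variance inflation matches its closed forms", {
  set.seed(41)
  n <- 200
  a <- rnorm(n); b <- rnorm(n)
  x <- as.vector(scale(a))                     # centred, unit variance
  z <- as.vector(scale(resid(lm(b ~ a))))      # orthogonal to x, centred
  y <- 0.8 * x + sqrt(1 - 0.64) * z            # cor(x, y) = 0.8 exactly
  v <- vif(data.frame(x = x, y = y))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  ortho <- vif(data.frame(a = x, b = z))
  expect_equal(unname(ortho), c(1, 1), tolerance = 1e-10)
  dup <- data.frame(a = x, b = z, c = x)
  expect_true(is.infinite(max(vif(dup))))
  scr <- vif_screen(dup, threshold = 3)
  expect_true(!("a" %in% scr$keep) || !("c" %in% scr$keep))
  expect_length(scr$keep, 2)
  expect_error(vif(data.frame(a = 1:3)), "2 covariates")
})

test_that("iterative screening never inflates a survivor above its previous VIF", {
  set.seed(42)
  n <- 300
  z <- rnorm(n)
  X <- data.frame(a = z + rnorm(n, sd = 0.3), b = z + rnorm(n, sd = 0.3),
                  c = z + rnorm(n, sd = 0.3), d = rnorm(n))
  scr <- vif_screen(X, threshold = 2)
  for (i in seq_along(scr$trace)[-1]) {
    prev <- scr$trace[[i - 1]]
    cur <- scr$trace[[i]]
    expect_true(all(cur[names(cur)] <= prev[names(cur)] + 1e-8))
  }
})

test_that("backward selection keeps real effects with their signs and honours alpha = 1", {
  set.seed(43)
  n <- 720
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  df <- data.frame(response = rpois(n, exp(0.2 + 0.5 * x1 - 0.5 * x2)),
                   x1 = x1, x2 = x2, x3 = x3)
  m <- backward_select(df, covariates = c("x1", "x2", "x3"), engine = "glm")
  expect_setequal(m$terms, c("x1", "x2"))
  cf <- coef(m$fit)
  expect_gt(cf[["x1"]], 0)
  expect_lt(cf[["x2"]], 0)
  expect_equal(m$path$dropped, "x3")
  full <- backward_select(df, covariates = c("x1", "x2", "x3"),
                          engine = "glm", alpha = 1)
  expect_setequal(full$terms, c("x1", "x2", "x3"))
  expect_equal(nrow(full$path), 0)
})

test_that("single-term LRT p-values are uniform under the null", {
  set.seed(45)
  n <- 360
  pv <- vapply(1:500, function(i) {
    df <- data.frame(y = rpois(n, 2), x = rnorm(n))
    full <- glm(y ~ x, family = poisson(), data = df)
    red <- glm(y ~ 1, family = poisson(), data = df)
    pchisq(max(0, 2 * (logLik(full) - logLik(red))), 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("random-structure comparison prefers the generating structure", {
  set.seed(44)
  n_sess <- 12; per <- 60
  sess <- factor(rep(seq_len(n_sess), each = per))
  b <- rnorm(n_sess, sd = 1)
  df <- data.frame(response = rpois(n_sess * per,
                                    exp(0.5 + b[as.integer(sess)])),
                   x = rnorm(n_sess * per), time = 1,
                   session = sess,
                   group1 = factor(rep(c("A", "B"), length.out = n_sess * per)))
  rc <- random_structure_compare(df, covariates = "x")
  expect_true(rc$structure %in% c("intercept", "slope"))
  expect_lt(rc$aic[["intercept"]], rc$aic[["none"]])

  df0 <- df
  df0$response <- rpois(nrow(df0), exp(0.5))
  rc0 <- random_structure_compare(df0, covariates = "x")
  expect_lte(rc0$aic[["none"]], min(rc0$aic) + 2.5)  # no variance: simplest fits

  df1 <- df[df$session == 1, ]
  df1$session <- droplevels(df1$session)
  expect_error(random_structure_compare(df1, covariates = "x"),
               "single session")
  expect_message(rcg <- random_structure_compare(df, covariates = "x",
                                                 engine = "glm"),
                 "fixed effects only")
  expect_equal(rcg$structure, "none")
})

test_that("mutual local inhibition and co-dominance give the expected symmetric signs", {
  sim <- simulate_bait_survey(generator_config(), seed = 3)
  g1 <- pipeline_groups_t1(sim$survey)
  radii <- c(Sol = 4, Mon = 4)
  models <- lapply(c("Sol", "Mon"), function(f)
    backward_select(build_model_frame(sim$survey, f, radii, g1),
                    engine = "glm"))
  names(models) <- c("Sol", "Mon")
  ss <- sign_summary(models)
  expect_equal(ss$pairs$class, "-/-")

  simp <- simulate_bait_survey(generator_config(codominant_weight = 5),
                               seed = 7)
  g1p <- pipeline_groups_t1(simp$survey)
  radp <- c(Nyl = 5, Bra = 5)
  mp <- lapply(c("Nyl", "Bra"), function(f)
    backward_select(build_model_frame(simp$survey, f, radp, g1p),
                    engine = "glm"))
  names(mp) <- c("Nyl", "Bra")
  expect_equal(sign_summary(mp)$pairs$class, "+/+")
})

test_that("independent species stay unlinked in the sign summary", {
  set.seed(46)
  n <- 400
  a <- rpois(n, 2); b <- rpois(n, 2)
  fr_a <- data.frame(response = a, local_B = b)
  fr_b <- data.frame(response = b, local_A = a)
  m <- list(A = backward_select(fr_a, covariates = "local_B", engine = "glm",
                                alpha = 0.01),
            B = backward_select(fr_b, covariates = "local_A", engine = "glm",
                                alpha = 0.01))
  m$A$focal_set <- m$B$focal_set <- c("A", "B")
  ss <- sign_summary(m)
  expect_equal(ss$pairs$class, "ns")
})
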