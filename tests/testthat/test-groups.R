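test_that("two well-separated single-species blobs are perfectly split at k = 2", {
  set.seed(8)
  X <- rbind(cbind(A = rpois(30, 30), B = rpois(30, 0.2)),
             cbind(A = rpois(30, 0.2), B = rpois(30, 30)))
  a <- cluster_observations(X, k = 2, seed = 1)
  expect_length(unique(a$group[1:30]), 1)
  expect_length(unique(a$group[31:60]), 1)
  expect_true(a$group[1] != a$group[60])
})

test_that("identical observations form a single group and cannot be split", {
  X <- matrix(3, 12, 2, dimnames = list(NULL, c("A", "B")))
  a <- cluster_observations(X, k = 1, seed = 1)
  expect_equal(unique(a$group), 1L)
  expect_error(cluster_observations(X, k = 2, seed = 1), "similar")
  expect_error(cluster_observations(X, k = 13), "exceeds")
})

test_that("Ward agglomeration matches brute-force minimum-variance merging", {
  X <- matrix(c(0, 0, 0.9, 0.2, 4, 0.1, 4.8, 0.4, 10, 5, 10.4, 6.1),
              ncol = 2, byrow = TRUE)
  oracle <- ward_oracle_partitions(X)
  a <- cluster_observations(X, k = 1, transform = "none",
                            var_explained = 1, seed = 1)
  for (k in c(5, 4, 3, 2)) {
    expect_equal(partition_signature(cutree(a$ward, k)),
                 partition_signature(oracle[[nrow(X) - k]]),
                 info = paste("k =", k))
  }
})

test_that("silhouette selection finds the generating blob count", {
  set.seed(9)
  blob <- function(mu) cbind(A = rpois(25, mu[1]), B = rpois(25, mu[2]),
                             C = rpois(25, mu[3]))
  X <- rbind(blob(c(40, 1, 1)), blob(c(1, 40, 1)), blob(c(1, 1, 40)))
  expect_equal(as.integer(choose_k(X, 2, 6, seed = 1)), 3L)
  one <- matrix(rpois(120, 20), ncol = 2,
                dimnames = list(NULL, c("A", "B")))
  expect_warning(k1 <- choose_k(one, 2, 4, seed = 1), "weak")
  expect_equal(as.integer(k1), 2L)
  expect_equal(choose_k(X, 5, 5), 5)  # forced
  expect_error(choose_k(X, 4, 2), "empty")
})

test_that("groups are named by their numerically dominant species", {
  fake <- function(m) structure(list(group = seq_len(nrow(m)),
                                     group_means = m, k = nrow(m)),
                                class = "group_assignment")
  m <- rbind(c(A = 30, B = 2, C = 0),
             c(A = 12, B = 10, C = 1),
             c(A = 0.8, B = 0.6, C = 0.5),
             c(A = 0, B = 0, C = 0))
  expect_warning(l <- name_groups(fake(m)), "duplicate")
  expect_equal(l, c("A", "A+B", "ND", "ND.1"))
  expect_equal(name_groups(fake(m[1:3, , drop = FALSE])),
               c("A", "A+B", "ND"))
})

test_that("group labels are invariant to species column order", {
  sim <- simulate_bait_survey(separated_config(), seed = 5)
  s <- sim$survey
  perm <- rev(s$species)
  s2 <- bait_survey(s$observations[c("subplot", "date", "time", "period",
                                     perm)],
                    s$subplots, species = perm)
  l1 <- name_groups(cluster_observations(s, 7, seed = 1), s)
  l2 <- name_groups(cluster_observations(s2, 7, seed = 1), s2)
  expect_equal(sort(l1), sort(l2))
})

test_that("K-means refinement never increases the Ward within-group variance", {
  sim <- simulate_bait_survey(generator_config(), seed = 6)
  a <- cluster_observations(sim$survey, k = 7, seed = 1)
  expect_lte(a$withinss_kmeans, a$withinss_ward + 1e-8)
})

test_that("well-separated synthetic surveys are assigned back to their latent groups", {
  sim <- simulate_bait_survey(separated_config(), seed = 5)
  a <- cluster_observations(sim$survey, k = 7, seed = 1)
  ari <- mclust::adjustedRandIndex(a$group, latent_states(sim))
  expect_gt(ari, 0.9)
  expect_equal(as.integer(choose_k(sim$survey, 4, 8, seed = 1)), 7L)
  expect_setequal(name_groups(a, sim$survey),
                  c("Sol", "Nyl", "Mon", "Phe", "Bra", "Nyl+Bra", "ND"))
})
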