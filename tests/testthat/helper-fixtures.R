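# Shared fixture builders and independent oracles.

# tiny bait survey on a 2 x 2 grid: counts given as a matrix (rows =
# observations in (subplot, date, time) order) with species column names
toy_bait_survey <- function(counts, n_times = 1, dates = 1,
                            spacing = c(3, 3)) {
  counts <- as.matrix(counts)
  n_sub <- nrow(counts) / (n_times * length(dates))
  grid <- subplot_grid(n_cols = n_sub, n_rows = 1,
                       dx = spacing[1], dy = spacing[2])
  des <- expand.grid(subplot = grid$id, time = seq_len(n_times),
                     date = dates)
  obs <- data.frame(subplot = des$subplot, date = des$date, time = des$time,
                    period = "morning", counts, check.names = FALSE)
  bait_survey(obs, grid, species = colnames(counts), n_times = max(3, n_times))
}

# per-observation latent state of a simulated survey
latent_states <- function(sim) {
  obs <- sim$survey$observations
  lat <- sim$truth$latent
  g <- as.matrix(lat[paste0("g", 1:3)])[
    match(paste(obs$subplot, obs$date), paste(lat$subplot, lat$date)), ]
  g[cbind(seq_len(nrow(obs)), obs$time)]
}

# brute-force Ward agglomeration: at each step merge the pair of clusters
# whose union minimizes the increase in total within-cluster sum of squares
ward_oracle_partitions <- function(X) {
  X <- as.matrix(X)
  ess <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  parts <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_len(length(clusters) - 1))
      for (b in seq(a + 1, length(clusters))) {
        d <- ess(c(clusters[[a]], clusters[[b]])) -
          ess(clusters[[a]]) - ess(clusters[[b]])
        if (d < best_d - 1e-12) { best_d <- d; best <- c(a, b) }
      }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    lab <- integer(nrow(X))
    for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
    parts[[length(parts) + 1]] <- lab
  }
  parts  # partitions at k = n-1, n-2, ..., 1
}

# canonical form of a partition, for label-free comparison
partition_signature <- function(labels) {
  sets <- split(seq_along(labels), labels)
  paste(sort(vapply(sets, function(s) paste(s, collapse = ","), "")),
        collapse = "|")
}

# brute-force tie-corrected Kruskal-Wallis H
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  num <- sum(tapply(r, groups, function(ri)
    length(ri) * (mean(ri) - (n + 1) / 2)^2))
  H <- 12 / (n * (n + 1)) * num
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# generator settings with well-separated groups (low off-group noise)
separated_config <- function(...) {
  generator_config(out_mean = c(dominant = 0.05, subdominant = 0.05,
                                subordinate = 0.05),
                   out_dispersion = 1, in_group_dispersion = 20, ...)
}
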