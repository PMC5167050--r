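# Synthetic survey generator with known ground truth. Emulates the study
# design: 60 tiles in a 44 x 20 m plot sampled on 4 dates at 3 times, plus
# 54 pitfall traps x 3 day/night replicates, with a ten-species community
# of 3 dominant, 2 subdominant and 5 subordinate species.

#' Default species table of the emulated community
#'
#' Ten species codes with their configured dominance tiers: three dominant
#' (Sol, Nyl, Mon), two subdominant (Phe, Bra), five subordinate.
#'
#' @return data.frame with columns `code`, `tier`.
#' @export
default_species <- function() {
  data.frame(code = c("Sol", "Nyl", "Mon", "Phe", "Bra",
                      "Car", "Was", "Odo", "Cam", "Par"),
             tier = c(rep("dominant", 3), rep("subdominant", 2),
                      rep("subordinate", 5)),
             stringsAsFactors = FALSE)
}

.default_states <- function(species) {
  focal <- species$code[species$tier != "subordinate"]
  if (all(c("Nyl", "Bra") %in% focal)) focal <- c(focal, "NylBra")
  c(focal, "ND")
}

.uniform_row <- function(states, from, diag, nd) {
  p <- setNames(rep(0, length(states)), states)
  others <- setdiff(states, c(from, "ND"))
  p[from] <- diag
  if (length(others)) {
    p["ND"] <- nd
    p[others] <- (1 - diag - nd) / length(others)
  } else p["ND"] <- 1 - diag
  p
}

.default_transition <- function(states, diag, nd, nd_stay = 0.6) {
  T <- t(vapply(states, function(s) {
    if (s == "ND") {
      p <- setNames(rep((1 - nd_stay) / (length(states) - 1),
                        length(states)), states)
      p["ND"] <- nd_stay
      p
    } else .uniform_row(states, s, diag, nd)
  }, numeric(length(states))))
  dimnames(T) <- list(states, states)
  T
}

#' Configuration of the synthetic survey generator
#'
#' The generator draws, for each subplot and date, a latent
#' momentary-community group at sampling time 1 from a mixture weighted by
#' proximity to random per-species nest centres (exponential kernel of range
#' `kernel_range`), evolves it through the per-step transition matrices
#' `T12` and `T23`, and emits negative-binomial species counts conditional
#' on the group, scaled by morning/afternoon activity multipliers. The
#' default latent state space holds one group per focal species, one
#' Nyl+Bra co-dominance group and one group without a numerical dominant
#' ("ND").
#'
#' @param n_cols,n_rows,dx,dy subplot grid (default 10 x 6 at 4.4 x 20/6 m,
#'   i.e. 60 tiles of about 14.7 m2).
#' @param species species table as in [default_species()].
#' @param n_dates,n_times bait design (default 4 dates x 3 sampling times).
#' @param periods period label per date session (recycled to `n_dates`).
#' @param n_trap_cols,n_trap_rows,n_replicates pitfall design (default 9 x 6
#'   traps, 3 replicates, day + night).
#' @param T12,T23 row-stochastic latent transition matrices on the group
#'   state space; NULL for persistent defaults (diagonals 0.70 and 0.55,
#'   most leakage toward "ND").
#' @param transition_sampling "balanced" allocates latent transitions by
#'   largest-remainder apportionment within each origin state (realized
#'   frequencies match `T12`/`T23` to within 1/n per row); "multinomial"
#'   draws them independently.
#' @param in_group_mean expected count of the group-defining species at its
#'   own baits, by tier.
#' @param codominant_mean expected count of each partner in the co-dominance
#'   group.
#' @param codominant_dispersion negative-binomial size of the co-dominance
#'   cells (large default: near-Poisson, so co-dominance stays balanced).
#' @param codominant_weight weight of the co-dominance state in the time-1
#'   mixture, relative to a single-species group.
#' @param out_mean baseline expected count away from a species' own group,
#'   by tier.
#' @param in_group_dispersion,out_dispersion negative-binomial size
#'   parameters for the two regimes (smaller = more overdispersed).
#' @param period_mult named list: per species, multiplier applied to bait
#'   means c(morning, afternoon).
#' @param nests_per_species,kernel_range,nd_weight,sharpness spatial mixture
#'   of the time-1 group: number of random nest sites per group, kernel
#'   correlation length (metres; larger = smoother fields = stronger
#'   short-range autocorrelation), share weight of the "ND" state relative
#'   to a single-species group, and softmax temperature sharpening the
#'   standardized nest fields.
#' @param pitfall_base per-species mean pitfall count per trap-interval.
#' @param day_mult,night_mult per-species day/night activity multipliers
#'   (> 0) applied to `pitfall_base`.
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_cols = 10, n_rows = 6, dx = 4.4, dy = 20 / 6,
                             species = default_species(),
                             n_dates = 4, n_times = 3,
                             periods = c("morning", "afternoon"),
                             n_trap_cols = 9, n_trap_rows = 6,
                             n_replicates = 3,
                             T12 = NULL, T23 = NULL,
                             transition_sampling = c("balanced",
                                                     "multinomial"),
                             in_group_mean = c(dominant = 45,
                                               subdominant = 24),
                             codominant_mean = 18,
                             codominant_dispersion = 100,
                             codominant_weight = 0.8,
                             out_mean = c(dominant = 0.1, subdominant = 3,
                                          subordinate = 1.0),
                             in_group_dispersion = 5,
                             out_dispersion = 0.2,
                             period_mult = NULL,
                             nests_per_species = 8, kernel_range = 4,
                             nd_weight = NULL, sharpness = 2,
                             pitfall_base = NULL,
                             day_mult = NULL, night_mult = NULL,
                             seed = NULL) {
  transition_sampling <- match.arg(transition_sampling)
  stopifnot(n_cols >= 1, n_rows >= 1, n_dates >= 1, n_times >= 2)
  if (!nrow(species)) stop("degenerate config: no species")
  states <- .default_states(species)
  if (is.null(T12)) T12 <- .default_transition(states, diag = 0.70, nd = 0.22)
  if (is.null(T23)) T23 <- .default_transition(states, diag = 0.55, nd = 0.37)
  for (Tm in list(T12, T23)) {
    if (any(Tm < 0)) stop("transition probabilities must be >= 0")
    if (any(abs(rowSums(Tm) - 1) > 1e-8))
      stop("transition matrix rows must sum to 1")
  }
  if (!identical(dimnames(T12)[[1]], dimnames(T23)[[1]]))
    stop("T12 and T23 must share a state space")
  periods <- rep_len(periods, n_dates)
  codes <- species$code
  if (is.null(period_mult)) {
    period_mult <- setNames(rep(list(c(morning = 1, afternoon = 1)),
                                length(codes)), codes)
    for (s in intersect(c("Sol", "Mon"), codes))
      period_mult[[s]] <- c(morning = 0.7, afternoon = 1.3)
  }
  if (is.null(pitfall_base))
    pitfall_base <- setNames(c(0.5, 0.4, 0.4, 14, 2, 1.3, 0.03, 0.06,
                               0.05, 0.08)[seq_along(codes)], codes)
  if (is.null(day_mult))
    day_mult <- setNames(c(1.6, 0.4, 1.6, 1.6, 1.5, 1.5, 1, 1, 1,
                           1.4)[seq_along(codes)], codes)
  if (is.null(night_mult)) night_mult <- 2 - day_mult
  if (any(day_mult <= 0) || any(night_mult <= 0))
    stop("activity multipliers must be > 0")
  if (any(pitfall_base < 0)) stop("rates must be >= 0")
  if (is.null(nd_weight)) nd_weight <- 2  # ~1/4 of tiles start ungrouped
  structure(list(n_cols = n_cols, n_rows = n_rows, dx = dx, dy = dy,
                 species = species, states = rownames(T12),
                 n_dates = n_dates, n_times = n_times, periods = periods,
                 n_trap_cols = n_trap_cols, n_trap_rows = n_trap_rows,
                 n_replicates = n_replicates,
                 T12 = T12, T23 = T23,
                 transition_sampling = transition_sampling,
                 in_group_mean = in_group_mean,
                 codominant_mean = codominant_mean,
                 codominant_dispersion = codominant_dispersion,
                 codominant_weight = codominant_weight,
                 out_mean = out_mean,
                 in_group_dispersion = in_group_dispersion,
                 out_dispersion = out_dispersion,
                 period_mult = period_mult,
                 nests_per_species = nests_per_species,
                 kernel_range = kernel_range,
                 nd_weight = nd_weight, sharpness = sharpness,
                 pitfall_base = pitfall_base,
                 day_mult = day_mult, night_mult = night_mult,
                 seed = seed),
            class = "generator_config")
}

# group-conditional negative-binomial mean and size matrices (states x species)
.emission_matrices <- function(config) {
  sp <- config$species
  states <- config$states
  mu <- matrix(rep(config$out_mean[sp$tier], each = length(states)),
               nrow = length(states), dimnames = list(states, sp$code))
  size <- matrix(config$out_dispersion, length(states), nrow(sp),
                 dimnames = list(states, sp$code))
  for (s in intersect(states, sp$code)) {
    mu[s, s] <- config$in_group_mean[[sp$tier[sp$code == s]]]
    size[s, s] <- config$in_group_dispersion
  }
  if ("NylBra" %in% states) {
    for (s in intersect(c("Nyl", "Bra"), sp$code)) {
      mu["NylBra", s] <- config$codominant_mean
      size["NylBra", s] <- config$codominant_dispersion
    }
  }
  list(mu = mu, size = size)
}

# advance latent states one step; balanced sampling apportions destinations
# within each origin class by largest remainder, then permutes
.step_states <- function(current, Tm, balanced) {
  states <- rownames(Tm)
  out <- character(length(current))
  for (s in unique(current)) {
    idx <- which(current == s)
    n <- length(idx)
    p <- Tm[s, ]
    if (!balanced) {
      out[idx] <- sample(states, n, replace = TRUE, prob = p)
    } else {
      base <- floor(p * n)
      rem <- n - sum(base)
      if (rem > 0) {
        frac <- p * n - base
        extra <- sample(seq_along(p), rem, prob = pmax(frac, 1e-12))
        base[extra] <- base[extra] + 1
      }
      pool <- rep(states, base)
      out[idx] <- pool[sample.int(n)]
    }
  }
  out
}

# Time-1 membership weights. Each focal group gets a spatially correlated
# intensity field: a kernel-weighted sum over random nest sites with
# exponential range kernel_range, standardized across subplots so that the
# field's contrast is fixed and kernel_range controls only the SPATIAL
# coherence (larger range => smoother fields => larger same-group patches
# => stronger short-range autocorrelation). Membership is a sharpened
# softmax over the fields, and the columns are rescaled (Sinkhorn style)
# until the expected state shares hit the target: equal for single-species
# groups, codominant_weight for the co-dominance group, nd_weight for "ND".
.time1_weights <- function(config, grid) {
  states <- config$states
  focal_states <- setdiff(states, "ND")
  n <- nrow(grid)
  W <- matrix(1, n, length(states), dimnames = list(NULL, states))
  nests <- list()
  for (s in focal_states) {
    cs <- cbind(runif(config$nests_per_species, 0, config$n_cols * config$dx),
                runif(config$nests_per_species, 0, config$n_rows * config$dy))
    nests[[s]] <- cs
    u <- -log(runif(config$nests_per_species))  # exponential nest sizes
    d <- sqrt(outer(grid$x, cs[, 1], "-")^2 + outer(grid$y, cs[, 2], "-")^2)
    f <- as.vector(exp(-d / config$kernel_range) %*% u)
    z <- if (sd(f) > 0) (f - mean(f)) / sd(f) else rep(0, n)
    W[, s] <- exp(config$sharpness * z)
  }
  target <- setNames(rep(1, length(states)), states)
  if ("NylBra" %in% states) target["NylBra"] <- config$codominant_weight
  target["ND"] <- config$nd_weight
  target <- target / sum(target)
  for (it in 1:25) {
    P <- W / rowSums(W)
    W <- W * rep(target / pmax(colMeans(P), 1e-12), each = nrow(W))
  }
  list(W = W / rowSums(W), nests = nests)
}

#' Simulate a bait survey with known ground truth
#'
#' @param config a [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with elements `survey` (a [bait_survey()]) and `truth`, a
#'   list of class `ant_truth` holding the configured tiers, state space,
#'   transition matrices, nest centres, emission means, activity
#'   multipliers, the latent group states (`latent`: subplot, date,
#'   g1..g3), and the seed.
#' @export
simulate_bait_survey <- function(config, seed = config$seed) {
  if (!inherits(config, "generator_config")) stop("need a generator_config")
  if (!is.null(seed)) set.seed(seed)
  grid <- subplot_grid(config$n_cols, config$n_rows, config$dx, config$dy)
  if (!nrow(grid)) stop("degenerate config: no subplots")
  states <- config$states
  mix <- .time1_weights(config, grid)
  em <- .emission_matrices(config)
  balanced <- config$transition_sampling == "balanced"

  # latent group sequences for ALL (subplot, date) pairs, stepped jointly so
  # balanced sampling apportions destinations over the full sequence set
  n_seq <- nrow(grid) * config$n_dates
  g <- matrix(NA_character_, n_seq, config$n_times)
  g[, 1] <- apply(mix$W[rep(seq_len(nrow(grid)), config$n_dates), ], 1,
                  function(p) sample(states, 1, prob = p))
  if (config$n_times >= 2) g[, 2] <- .step_states(g[, 1], config$T12, balanced)
  if (config$n_times >= 3) g[, 3] <- .step_states(g[, 2], config$T23, balanced)
  latent <- data.frame(subplot = rep(grid$id, config$n_dates),
                       date = rep(seq_len(config$n_dates), each = nrow(grid)),
                       setNames(as.data.frame(g),
                                paste0("g", seq_len(config$n_times))))

  rows <- vector("list", config$n_dates)
  for (d in seq_len(config$n_dates)) {
    gd <- g[latent$date == d, , drop = FALSE]
    period <- config$periods[d]
    pm <- vapply(config$species$code,
                 function(s) config$period_mult[[s]][[period]], numeric(1))
    for (t in seq_len(config$n_times)) {
      mu <- em$mu[gd[, t], , drop = FALSE] *
        matrix(pm, nrow(grid), nrow(config$species), byrow = TRUE)
      size <- em$size[gd[, t], , drop = FALSE]
      counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                               size = as.vector(size)),
                       nrow = nrow(grid),
                       dimnames = list(NULL, config$species$code))
      rows[[d]] <- rbind(rows[[d]],
                         data.frame(subplot = grid$id, date = d, time = t,
                                    period = period, counts,
                                    check.names = FALSE))
    }
  }
  obs <- do.call(rbind, rows)
  survey <- bait_survey(obs, grid, species = config$species$code,
                        n_times = config$n_times)
  truth <- structure(list(species = config$species,
                          states = states,
                          T12 = config$T12, T23 = config$T23,
                          nests = mix$nests,
                          emission_mean = em$mu,
                          period_mult = config$period_mult,
                          day_mult = config$day_mult,
                          night_mult = config$night_mult,
                          latent = latent,
                          seed = seed),
                     class = "ant_truth")
  list(survey = survey, truth = truth)
}

#' Simulate a pitfall survey
#'
#' Per-trap negative-binomial counts with day and night means proportional
#' to the configured activity multipliers.
#'
#' @param config a [generator_config()].
#' @param truth optional `ant_truth` from [simulate_bait_survey()]; its
#'   activity multipliers take precedence over the config's.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a [pitfall_survey()].
#' @export
simulate_pitfall_survey <- function(config, truth = NULL,
                                    seed = config$seed) {
  if (!inherits(config, "generator_config")) stop("need a generator_config")
  if (!is.null(seed)) set.seed(seed)
  day_mult <- if (!is.null(truth)) truth$day_mult else config$day_mult
  night_mult <- if (!is.null(truth)) truth$night_mult else config$night_mult
  traps <- trap_grid(config$n_trap_cols, config$n_trap_rows,
                     config$dx, config$dy)
  if (!nrow(traps)) stop("degenerate config: no traps")
  codes <- config$species$code
  des <- expand.grid(trap = traps$id,
                     replicate = seq_len(config$n_replicates),
                     interval = c("day", "night"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- sapply(codes, function(s) {
    mu <- config$pitfall_base[[s]] *
      ifelse(des$interval == "day", day_mult[[s]], night_mult[[s]])
    rnbinom(nrow(des), mu = mu, size = config$in_group_dispersion)
  })
  pitfall_survey(cbind(des, as.data.frame(counts, check.names = FALSE)),
                 traps = traps, species = codes)
}

#' @export
print.ant_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$species), "species,",
      length(x$states), "latent groups,", nrow(x$latent), "group sequences\n")
  invisible(x)
}
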