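# Six-point abundance scale, bait-control rule and dominance-tier
# classification from per-species bait statistics.

#' Six-point abundance score of a bait count
#'
#' Bins follow the convention standard in the bait literature:
#' 1 = 1 individual, 2 = 2-5, 3 = 6-10, 4 = 11-20, 5 = 21-50, 6 = >50.
#' A count of zero means the species is absent and has no score.
#'
#' @param count vector of positive integer counts.
#' @param breaks upper bin edges of scores 1..5 (strictly increasing).
#' @return integer scores in 1..6.
#' @export
abundance_score <- function(count, breaks = c(1, 5, 10, 20, 50)) {
  if (any(count < 1)) stop("count must be >= 1 (absent species are not scored)")
  if (any(diff(breaks) <= 0)) stop("breaks must strictly increase")
  findInterval(count, c(1, breaks + 1))
}

#' Controlling species of one bait observation
#'
#' A bait is controlled by a species if (i) it is the only species present
#' and numbers more than `total_min` individuals (monopolization), or (ii)
#' several species are present, the total exceeds `total_min`, and the most
#' numerous species is at least `ratio` times as numerous as the runner-up.
#' A tie at the top means no controller.
#'
#' @param counts named vector of species counts at one bait.
#' @param total_min minimum total count, strictly exceeded.
#' @param ratio leader:runner-up multiple ("at least twice" by default).
#' @return the controlling species code, or `NA_character_` if none.
#' @export
controlling_species <- function(counts, total_min = 20, ratio = 2) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_character_)
  if (sum(counts) <= total_min) return(NA_character_)
  if (length(counts) == 1L) return(names(counts))
  ord <- sort(counts, decreasing = TRUE)
  if (ord[1] >= ratio * ord[2]) names(ord)[1] else NA_character_
}

#' Per-species bait statistics
#'
#' For every species: the percentage of all baits at which it was recorded,
#' the percentage of occupied baits it controlled, and its mean abundance
#' score (sum of scores at occupied baits divided by the number of occupied
#' baits). Control is evaluated per observation (tile x sampling time) and
#' pooled over all dates and times. Species never present get `NA` control
#' and score.
#'
#' @param survey a [bait_survey()].
#' @param config a [run_config()] providing the scale bins and control rule.
#' @return data.frame with columns `species`, `n_present`, `pct_recorded`,
#'   `pct_controlled`, `mean_score`.
#' @export
species_bait_stats <- function(survey, config = run_config()) {
  m <- counts_matrix(survey)
  if (!nrow(m)) stop("empty survey")
  ctrl <- apply(m, 1, controlling_species,
                total_min = config$control_total,
                ratio = config$control_ratio)
  out <- lapply(colnames(m), function(s) {
    present <- m[, s] >= 1
    n_present <- sum(present)
    data.frame(species = s, n_present = n_present,
               pct_recorded = 100 * mean(present),
               pct_controlled = if (n_present)
                 100 * sum(ctrl == s, na.rm = TRUE) / n_present
               else NA_real_,
               mean_score = if (n_present)
                 mean(abundance_score(m[present, s],
                                      breaks = config$scale_breaks))
               else NA_real_)
  })
  do.call(rbind, out)
}

#' Classify species into dominance tiers
#'
#' A species is dominant if it was recorded at more than `recorded_min` % of
#' all baits, controlled more than `control_dominant` % of the baits where
#' it occurred, and has a mean abundance score above `score_dominant`;
#' subdominant if recorded > `recorded_min` %, controlled >
#' `control_subdominant` % and scored above `score_subdominant`; otherwise
#' subordinate. Species with undefined statistics (never present) are
#' subordinate, with a warning. The rule is monotone: raising any statistic
#' never demotes a species.
#'
#' @param stats data.frame with columns `pct_recorded`, `pct_controlled`,
#'   `mean_score` (e.g. from [species_bait_stats()]).
#' @param config a [run_config()] providing the thresholds.
#' @return `stats` with a `tier` factor column appended
#'   (dominant/subdominant/subordinate).
#' @export
classify_dominance <- function(stats, config = run_config()) {
  need <- c("pct_recorded", "pct_controlled", "mean_score")
  if (!all(need %in% names(stats)))
    stop("stats needs columns ", paste(need, collapse = ", "))
  und <- is.na(stats$pct_controlled) | is.na(stats$mean_score) |
    is.na(stats$pct_recorded)
  if (any(und))
    warning("undefined statistics for ", sum(und),
            " species; classified subordinate")
  dom <- !und & stats$pct_recorded > config$recorded_min &
    stats$pct_controlled > config$control_dominant &
    stats$mean_score > config$score_dominant
  sub <- !und & !dom & stats$pct_recorded > config$recorded_min &
    stats$pct_controlled > config$control_subdominant &
    stats$mean_score > config$score_subdominant
  stats$tier <- factor(ifelse(dom, "dominant",
                              ifelse(sub, "subdominant", "subordinate")),
                       levels = c("dominant", "subdominant", "subordinate"))
  stats
}
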