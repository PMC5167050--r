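# Foraging-activity summaries and contrasts: occurrence and mean abundance
# per day/night interval (pitfalls) or morning/afternoon period (baits),
# with rank-based Kruskal-Wallis tests of the contrast. The unit of
# replication is one trap x replicate interval, or one bait observation.

.activity_table <- function(survey) {
  if (inherits(survey, "pitfall_survey"))
    list(tab = survey$records, by = "interval")
  else if (inherits(survey, "bait_survey"))
    list(tab = survey$observations, by = "period")
  else stop("not a survey object")
}

#' Occurrence and mean abundance per activity interval
#'
#' For each species and interval (day/night for pitfall surveys,
#' morning/afternoon for bait surveys): the percentage of records where the
#' species occurred and its mean abundance with a normal-approximation 95 %
#' confidence interval (mean +/- 1.96 SE; such intervals can dip below
#' zero for rare species).
#'
#' @param survey a [pitfall_survey()] or [bait_survey()].
#' @param species species codes (default: all).
#' @return data.frame `species`, `interval`, `n`, `pct_recorded`,
#'   `mean_abundance`, `ci_lower`, `ci_upper`.
#' @export
interval_summary <- function(survey, species = NULL) {
  at <- .activity_table(survey)
  if (is.null(species)) species <- survey$species
  out <- list()
  for (iv in unique(at$tab[[at$by]])) {
    sel <- at$tab[[at$by]] == iv
    if (!any(sel)) stop("empty interval: ", iv)
    for (s in species) {
      v <- at$tab[[s]][sel]
      se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
      out[[length(out) + 1]] <-
        data.frame(species = s, interval = iv, n = length(v),
                   pct_recorded = 100 * mean(v >= 1),
                   mean_abundance = mean(v),
                   ci_lower = mean(v) - qnorm(0.975) * se,
                   ci_upper = mean(v) + qnorm(0.975) * se)
    }
  }
  df <- do.call(rbind, out)
  df[order(match(df$species, species), df$interval), ]
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based test (delegating to [stats::kruskal.test()])
#' with the degenerate all-values-identical case handled explicitly:
#' H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 nonempty groups).
#' @return list `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need >= 2 nonempty groups")
  if (length(values) != length(groups)) stop("length mismatch")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p.value = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Activity contrasts per species
#'
#' Kruskal-Wallis test of abundance between activity intervals (day vs
#' night, or morning vs afternoon), one row per species.
#'
#' @inheritParams interval_summary
#' @return data.frame `species`, `statistic`, `df`, `p_value`.
#' @export
activity_contrast <- function(survey, species = NULL) {
  at <- .activity_table(survey)
  if (is.null(species)) species <- survey$species
  g <- at$tab[[at$by]]
  out <- lapply(species, function(s) {
    kt <- kruskal_wallis(at$tab[[s]], g)
    data.frame(species = s, statistic = kt$statistic, df = kt$df,
               p_value = kt$p.value)
  })
  do.call(rbind, out)
}
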