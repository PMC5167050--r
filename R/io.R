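# Delimited-text persistence. Surveys are persisted wide (one species per
# column) because the analysis unit is the full community snapshot: one row
# is one observation. Bait files carry the tile-centre coordinates so that a
# single file round-trips the whole survey.

#' Read a bait survey from a delimited text file
#'
#' Expects a header row and one row per (subplot, date, time) with columns
#' `subplot`, `x`, `y`, `date`, `time`, `period` and one count column per
#' species. Unknown key-like columns are treated as species and reported.
#'
#' @param path file path (CSV, or TSV with `sep = "\t"`).
#' @param species optional character vector naming the species columns; by
#'   default every non-key column is a species.
#' @param sep field separator.
#' @return a validated [bait_survey()].
#' @export
read_bait_survey <- function(path, species = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  need <- c("subplot", "x", "y", "date", "time", "period")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  sub <- unique(df[c("subplot", "x", "y")])
  if (anyDuplicated(sub$subplot))
    stop("inconsistent coordinates for a subplot id")
  subplots <- data.frame(id = sub$subplot, x = sub$x, y = sub$y)
  if (is.null(species)) {
    species <- setdiff(names(df), need)
    message("read_bait_survey: species columns: ",
            paste(species, collapse = ", "))
  } else {
    unknown <- setdiff(setdiff(names(df), need), species)
    if (length(unknown))
      message("read_bait_survey: ignoring unknown columns: ",
              paste(unknown, collapse = ", "))
  }
  bait_survey(df[c(.bait_keys, species)], subplots, species = species,
              n_times = max(df$time))
}

#' Read a pitfall survey from a delimited text file
#'
#' One row per (trap, replicate, interval); columns `trap`, `replicate`,
#' `interval` plus one count column per species ( `x`, `y` optional).
#'
#' @inheritParams read_bait_survey
#' @return a validated [pitfall_survey()].
#' @export
read_pitfall_survey <- function(path, species = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  miss <- setdiff(.pitfall_keys, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  traps <- NULL
  if (all(c("x", "y") %in% names(df))) {
    tr <- unique(df[c("trap", "x", "y")])
    if (anyDuplicated(tr$trap)) stop("inconsistent coordinates for a trap id")
    traps <- data.frame(id = tr$trap, x = tr$x, y = tr$y)
  }
  if (is.null(species)) species <- setdiff(names(df), c(.pitfall_keys, "x", "y"))
  if (!length(species)) stop("no species columns found")
  pitfall_survey(df[c(.pitfall_keys, species)], traps = traps,
                 species = species)
}

#' Write a survey to a delimited text file
#'
#' The written file round-trips losslessly through the matching reader.
#'
#' @param survey a `bait_survey` or `pitfall_survey`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path, sep = ",") UseMethod("write_survey")

#' @export
write_survey.bait_survey <- function(survey, path, sep = ",") {
  out <- merge(survey$observations,
               data.frame(subplot = survey$subplots$id,
                          x = survey$subplots$x, y = survey$subplots$y),
               by = "subplot", sort = FALSE)
  out <- out[order(out$date, out$time, out$subplot),
             c("subplot", "x", "y", "date", "time", "period", survey$species)]
  write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
write_survey.pitfall_survey <- function(survey, path, sep = ",") {
  out <- survey$records
  if (all(c("x", "y") %in% names(survey$traps))) {
    out <- merge(out, data.frame(trap = survey$traps$id,
                                 x = survey$traps$x, y = survey$traps$y),
                 by = "trap", sort = FALSE)
    out <- out[c("trap", "x", "y", "replicate", "interval", survey$species)]
  }
  out <- out[order(out$replicate, out$interval, out$trap), ]
  write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow the
#' dominance-tier criteria (recorded >10 % of baits; controlled >25 % /
#' >10 % of occupied baits; mean abundance score >3 / >2.5), the bait-control
#' rule (total >20 individuals, leader at least twice the runner-up), a
#' six-point abundance scale with upper bin edges 1, 5, 10, 20, 50, Geary
#' distance bands 2.5-6.0 m in 0.5 m steps, 10,000 Markov-chain iterations
#' and a 0.05 alpha level.
#'
#' @param recorded_min occurrence threshold (% of all baits).
#' @param control_dominant,control_subdominant control thresholds (% of
#'   occupied baits).
#' @param score_dominant,score_subdominant mean abundance-score thresholds.
#' @param scale_breaks upper bin edges of the six-point abundance scale.
#' @param control_total,control_ratio bait-control rule: minimum total count
#'   (strictly exceeded) and leader:runner-up ratio.
#' @param k number of momentary-community groups, or "auto" for silhouette
#'   selection over `k_range`.
#' @param k_range inclusive range searched when `k = "auto"`.
#' @param iterations Markov-chain simulation count.
#' @param bands Geary's C distance bands (metres).
#' @param radius_tau tolerance below 1 used by the neighborhood-radius rule.
#' @param vif_threshold variance-inflation threshold for covariate screening.
#' @param alpha significance level, in (0, 1).
#' @param seed RNG seed (integer) or NULL.
#' @return list of class `run_config`.
#' @export
run_config <- function(recorded_min = 10, control_dominant = 25,
                       control_subdominant = 10, score_dominant = 3,
                       score_subdominant = 2.5,
                       scale_breaks = c(1, 5, 10, 20, 50),
                       control_total = 20, control_ratio = 2,
                       k = "auto", k_range = c(2, 8),
                       iterations = 10000,
                       bands = seq(2.5, 6, by = 0.5),
                       radius_tau = 0.05, vif_threshold = 3,
                       alpha = 0.05, seed = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (iterations < 1) stop("iterations must be >= 1")
  if (any(diff(scale_breaks) <= 0)) stop("scale_breaks must strictly increase")
  structure(list(recorded_min = recorded_min,
                 control_dominant = control_dominant,
                 control_subdominant = control_subdominant,
                 score_dominant = score_dominant,
                 score_subdominant = score_subdominant,
                 scale_breaks = scale_breaks,
                 control_total = control_total,
                 control_ratio = control_ratio,
                 k = k, k_range = k_range,
                 iterations = as.integer(iterations),
                 bands = bands, radius_tau = radius_tau,
                 vif_threshold = vif_threshold,
                 alpha = alpha, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields present in the file override [run_config()] defaults; unknown
#' fields raise a warning.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    yaml::read_yaml(path)  # YAML is a JSON superset
  } else stop("unsupported config format: ", ext)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals[intersect(names(vals), known)])
}
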