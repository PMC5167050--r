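# Wide-format survey containers: one row per community snapshot, one count
# column per species. Coordinates are tile/trap centres in metres, origin at
# the plot corner; all distances Euclidean.

.bait_keys <- c("subplot", "date", "time", "period")
.pitfall_keys <- c("trap", "replicate", "interval")

.check_counts <- function(df, species, what = "observation") {
  for (sp in species) {
    v <- df[[sp]]
    if (is.null(v)) stop("species column missing: ", sp)
    if (!is.numeric(v)) stop("counts for '", sp, "' are not numeric")
    if (anyNA(v)) stop("missing counts for '", sp, "'")
    if (any(v < 0)) stop("negative counts for '", sp, "'")
    if (any(v != round(v))) stop("non-integer counts for '", sp, "'")
    df[[sp]] <- as.integer(round(v))
  }
  df
}

#' Regular subplot grid of tile centres
#'
#' Defaults reproduce a 44 x 20 m plot holding 60 regularly spaced subplots
#' of about 14.7 m2 each (10 columns at 4.4 m, 6 rows at 20/6 m).
#'
#' @param n_cols,n_rows grid dimensions.
#' @param dx,dy spacing between tile centres in metres.
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
subplot_grid <- function(n_cols = 10, n_rows = 6, dx = 4.4, dy = 20 / 6) {
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  data.frame(id = seq_len(nrow(g)),
             x = (g$col - 0.5) * dx,
             y = (g$row - 0.5) * dy)
}

#' Pitfall trap positions between subplots
#'
#' Defaults give 54 traps (9 x 6) located between the columns of the default
#' subplot grid.
#'
#' @inheritParams subplot_grid
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
trap_grid <- function(n_cols = 9, n_rows = 6, dx = 4.4, dy = 20 / 6) {
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  data.frame(id = seq_len(nrow(g)),
             x = g$col * dx,
             y = (g$row - 0.5) * dy)
}

#' Construct a validated bait survey
#'
#' One row of `observations` is one community snapshot: the counts of every
#' species on one tile at one (date, sampling time). The sampling date is an
#' ordinal index 1..D and each date session carries a `period` label
#' ("morning" or "afternoon"), which is a required input, never inferred.
#'
#' @param observations data.frame with key columns `subplot`, `date`, `time`
#'   (1..`n_times`), `period` and one non-negative integer column per species.
#' @param subplots registry data.frame with columns `id`, `x`, `y` (metres).
#' @param species character vector of species codes; default: every non-key
#'   column of `observations`.
#' @param n_times number of sampling times per date.
#' @return object of class `bait_survey`: list with elements `observations`,
#'   `subplots`, `species`, `n_times`.
#' @export
bait_survey <- function(observations, subplots, species = NULL, n_times = 3L) {
  observations <- as.data.frame(observations)
  subplots <- as.data.frame(subplots)
  if (!all(c("id", "x", "y") %in% names(subplots)))
    stop("subplot registry needs columns id, x, y")
  miss <- setdiff(.bait_keys, names(observations))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(species))
    species <- setdiff(names(observations), c(.bait_keys, "x", "y"))
  species <- as.character(species)
  if (!length(species)) stop("no species columns found")
  if (anyDuplicated(species)) stop("duplicate species codes")
  observations <- .check_counts(observations, species)
  if (anyDuplicated(subplots$id)) stop("duplicate subplot ids")
  if (!all(observations$subplot %in% subplots$id))
    stop("observations reference unregistered subplots")
  if (!all(observations$time %in% seq_len(n_times)))
    stop("time index outside 1..", n_times)
  if (!all(observations$period %in% c("morning", "afternoon")))
    stop("period must be 'morning' or 'afternoon'")
  key <- paste(observations$subplot, observations$date, observations$time)
  if (anyDuplicated(key)) stop("duplicate (subplot, date, time) keys")
  rownames(observations) <- NULL
  structure(list(observations = observations[c(.bait_keys, species)],
                 subplots = subplots[c("id", "x", "y")],
                 species = species,
                 n_times = as.integer(n_times)),
            class = "bait_survey")
}

#' Construct a validated pitfall survey
#'
#' One row of `records` holds the counts of every species captured in one
#' trap over one day or night interval of one replicate.
#'
#' @param records data.frame with key columns `trap`, `replicate`, `interval`
#'   ("day"/"night") and one count column per species.
#' @param traps optional trap registry (`id`, and optionally `x`, `y`).
#' @param species character vector of species codes; default: every non-key
#'   column of `records`.
#' @return object of class `pitfall_survey`.
#' @export
pitfall_survey <- function(records, traps = NULL, species = NULL) {
  records <- as.data.frame(records)
  miss <- setdiff(.pitfall_keys, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(species))
    species <- setdiff(names(records), c(.pitfall_keys, "x", "y"))
  species <- as.character(species)
  if (!length(species)) stop("no species columns found")
  if (anyDuplicated(species)) stop("duplicate species codes")
  records <- .check_counts(records, species)
  if (!all(records$interval %in% c("day", "night")))
    stop("interval must be 'day' or 'night'")
  if (is.null(traps)) {
    traps <- data.frame(id = sort(unique(records$trap)))
  } else {
    traps <- as.data.frame(traps)
    if (!"id" %in% names(traps)) stop("trap registry needs column id")
    if (anyDuplicated(traps$id)) stop("duplicate trap ids")
    if (!all(records$trap %in% traps$id))
      stop("records reference unregistered traps")
  }
  key <- paste(records$trap, records$replicate, records$interval)
  if (anyDuplicated(key)) stop("duplicate (trap, replicate, interval) keys")
  rownames(records) <- NULL
  structure(list(records = records[c(.pitfall_keys, species)],
                 traps = traps,
                 species = species),
            class = "pitfall_survey")
}

#' Extract the observations-by-species count matrix of a survey
#'
#' @param survey a `bait_survey` or `pitfall_survey`.
#' @return integer matrix, one row per observation/record, one column per
#'   species (in registry order).
#' @export
counts_matrix <- function(survey) {
  tab <- if (inherits(survey, "bait_survey")) survey$observations
         else if (inherits(survey, "pitfall_survey")) survey$records
         else stop("not a survey object")
  as.matrix(tab[survey$species])
}

#' @export
print.bait_survey <- function(x, ...) {
  cat("Bait survey:", nrow(x$observations), "observations,",
      nrow(x$subplots), "subplots,", length(x$species), "species\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pitfall_survey <- function(x, ...) {
  cat("Pitfall survey:", nrow(x$records), "records,",
      nrow(x$traps), "traps,", length(x$species), "species\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}
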