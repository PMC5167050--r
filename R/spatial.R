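# Spatial structure: Geary's C profiles over distance, the quadratic
# distance model, neighborhood-radius selection and neighborhood-abundance
# covariates. Neighborhoods are cumulative (all pairs within d), not
# annular bands.

#' Geary's C spatial autocorrelation index
#'
#' `C = (n-1) * sum_ij w_ij (x_i - x_j)^2 / (2 W sum_i (x_i - mean)^2)`
#' with binary weights `w_ij = 1` when `0 < dist(i, j) <= d`. Values below 1
#' indicate positive autocorrelation among neighbors; values near 1, none.
#'
#' @param values numeric vector (one value per location).
#' @param coords matrix or data.frame of x/y coordinates (metres).
#' @param d neighborhood distance (metres).
#' @return the index; `NA` with a warning when the values have zero
#'   variance (the index is then undefined).
#' @export
geary_c <- function(values, coords, d) {
  coords <- as.matrix(coords[, c(1, 2)])
  n <- length(values)
  if (n < 2 || nrow(coords) != n) stop("need >= 2 located values")
  D <- as.matrix(dist(coords))
  W <- D > 0 & D <= d
  if (!any(W)) stop("no neighbors within d = ", d)
  sst <- sum((values - mean(values))^2)
  if (sst == 0) {
    warning("zero variance: Geary's C undefined")
    return(NA_real_)
  }
  num <- sum(W * outer(values, values, function(a, b) (a - b)^2))
  (n - 1) * num / (2 * sum(W) * sst)
}

#' Geary's C profile of one species over distance bands
#'
#' Computes the index for the species' counts over subplots, separately for
#' every (date, sampling time) snapshot and every distance band, and
#' averages across snapshots. Snapshots in which the species shows zero
#' variance are skipped and reported.
#'
#' @param survey a [bait_survey()] with subplot coordinates.
#' @param species species code.
#' @param bands increasing distance bands in metres (default 2.5-6.0 m in
#'   0.5 m steps).
#' @param transform optional transformation of counts ("none" or "log1p").
#' @return list of class `geary_profile`: `species`, `bands`, `C` (matrix
#'   snapshots x bands), `mean_c`, `snapshots`, `skipped`.
#' @export
geary_profile <- function(survey, species, bands = seq(2.5, 6, by = 0.5),
                          transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  if (any(diff(bands) <= 0)) stop("bands must strictly increase")
  if (!species %in% survey$species) stop("unknown species: ", species)
  obs <- survey$observations
  coords <- survey$subplots[c("x", "y")]
  ids <- survey$subplots$id
  D <- as.matrix(dist(coords))
  has_pairs <- vapply(bands, function(d) any(D > 0 & D <= d), logical(1))
  if (any(!has_pairs))
    message("geary_profile(", species, "): no subplot pairs within ",
            paste(bands[!has_pairs], collapse = ", "),
            " m; those bands are NA")
  snaps <- unique(obs[c("date", "time")])
  C <- matrix(NA_real_, nrow(snaps), length(bands),
              dimnames = list(paste0("d", snaps$date, ".t", snaps$time),
                              bands))
  skipped <- character(0)
  for (r in seq_len(nrow(snaps))) {
    sel <- obs$date == snaps$date[r] & obs$time == snaps$time[r]
    v <- obs[[species]][sel][match(ids, obs$subplot[sel])]
    if (transform == "log1p") v <- log1p(v)
    if (length(unique(v)) < 2) {
      skipped <- c(skipped, rownames(C)[r])
      next
    }
    C[r, has_pairs] <- vapply(bands[has_pairs],
                              function(d) geary_c(v, coords, d), numeric(1))
  }
  if (length(skipped))
    message("geary_profile(", species, "): skipped constant snapshots: ",
            paste(skipped, collapse = ", "))
  keep <- !rownames(C) %in% skipped
  structure(list(species = species, bands = bands,
                 C = C[keep, , drop = FALSE],
                 mean_c = colMeans(C[keep, , drop = FALSE]),
                 snapshots = sum(keep), skipped = skipped),
            class = "geary_profile")
}

#' Quadratic distance model of Geary's C
#'
#' Least-squares fit of `C = alpha + beta1 d + beta2 d^2 + e` over all
#' snapshot-level index values of a profile (or over a plain `d`/`C`
#' data.frame).
#'
#' @param profile a `geary_profile`, or a data.frame with columns `d`, `C`.
#' @return list with `coefficients` (alpha, beta1, beta2), `r_squared` and
#'   the fitted `model`.
#' @export
fit_quadratic <- function(profile) {
  df <- if (inherits(profile, "geary_profile")) {
    data.frame(d = rep(profile$bands, each = nrow(profile$C)),
               C = as.vector(profile$C))
  } else as.data.frame(profile)[c("d", "C")]
  df <- df[!is.na(df$C), ]
  if (length(unique(df$d)) < 3) stop("need >= 3 distinct distance bands")
  fit <- lm(C ~ d + I(d^2), data = df)
  s <- suppressWarnings(summary(fit))
  list(coefficients = setNames(coef(fit), c("alpha", "beta1", "beta2")),
       r_squared = s$r.squared, model = fit)
}

#' Select a species' neighborhood radius from its Geary profile
#'
#' Default rule: the largest band `d` whose mean `C(d)` is at most
#' `1 - tau`, i.e. the longest distance still showing clear positive
#' autocorrelation. If no band qualifies, the smallest band is returned
#' with a warning. Published per-species radii can be imposed via
#' `override`.
#'
#' @param profile a `geary_profile`.
#' @param tau tolerance below 1 (default 0.05).
#' @param override optional named vector of radii (metres) by species; an
#'   entry for the profile's species short-circuits the rule.
#' @return radius in metres.
#' @export
select_radius <- function(profile, tau = 0.05, override = NULL) {
  if (!is.null(override) && profile$species %in% names(override))
    return(unname(override[[profile$species]]))
  ok <- which(!is.na(profile$mean_c) & profile$mean_c <= 1 - tau)
  if (!length(ok)) {
    warning("no band with mean C <= ", 1 - tau,
            "; falling back to the smallest defined band")
    return(profile$bands[which(!is.na(profile$mean_c))[1]])
  }
  profile$bands[max(ok)]
}

#' Neighborhood mean abundance covariate
#'
#' For each observation (subplot, date, time): the mean count of `species`
#' over the OTHER subplots lying within `radius` metres, at the same date
#' and sampling time. Subplots with no neighbor within `radius` get `NA`
#' and are reported.
#'
#' @param survey a [bait_survey()].
#' @param species species code.
#' @param radius neighborhood radius in metres.
#' @return data.frame `subplot`, `date`, `time`, `neighborhood`, aligned
#'   with `survey$observations` rows.
#' @export
neighborhood_abundance <- function(survey, species, radius) {
  if (radius <= 0) stop("radius must be > 0")
  if (!species %in% survey$species) stop("unknown species: ", species)
  ids <- survey$subplots$id
  D <- as.matrix(dist(survey$subplots[c("x", "y")]))
  A <- D > 0 & D <= radius
  deg <- rowSums(A)
  if (any(deg == 0))
    message("neighborhood_abundance(", species, "): ", sum(deg == 0),
            " subplot(s) without neighbors at radius ", radius)
  obs <- survey$observations
  out <- rep(NA_real_, nrow(obs))
  for (d in unique(obs$date)) for (t in unique(obs$time)) {
    sel <- which(obs$date == d & obs$time == t)
    v <- obs[[species]][sel][match(ids, obs$subplot[sel])]
    nb <- as.vector(A %*% v) / ifelse(deg > 0, deg, NA_real_)
    out[sel] <- nb[match(obs$subplot[sel], ids)]
  }
  data.frame(subplot = obs$subplot, date = obs$date, time = obs$time,
             neighborhood = out)
}

#' @export
print.geary_profile <- function(x, ...) {
  cat("Geary's C profile for", x$species, "over", x$snapshots,
      "snapshots\n")
  print(round(x$mean_c, 3))
  invisible(x)
}
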