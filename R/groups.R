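# Momentary-community typing: observations at baits are projected on
# principal components, agglomerated by Ward's minimum-variance method, and
# the cut partition is refined by K-means started from the Ward centroids.

.obs_matrix <- function(x, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  m <- if (inherits(x, "bait_survey")) counts_matrix(x) else as.matrix(x)
  storage.mode(m) <- "double"
  if (transform == "log1p") m <- log1p(m)
  m
}

.pca_scores <- function(m, var_explained) {
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) return(p$x[, 1, drop = FALSE])
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  keep <- max(1L, which(cum >= var_explained)[1])
  p$x[, seq_len(keep), drop = FALSE]
}

#' Cluster bait observations into momentary-community groups
#'
#' Abundances are log(1+x)-transformed (so a single heavily recruiting
#' species cannot dominate every component), projected on the principal
#' components explaining at least `var_explained` of the variance,
#' agglomerated with Ward's method and cut at `k`; the cut partition's
#' centroids start a K-means refinement, which can only decrease the
#' within-group variance of the Ward initialization.
#'
#' @param x a [bait_survey()] or a numeric observations-by-features matrix.
#' @param k number of groups (>= 1, <= number of observations).
#' @param transform count transformation before PCA.
#' @param var_explained proportion of variance the retained components must
#'   explain.
#' @param seed RNG seed for K-means.
#' @return list of class `group_assignment`: `group` (integer per
#'   observation), `k`, `group_means` (raw mean abundance per group x
#'   species, when `x` is a survey), `scores` (PCA projection), `ward`
#'   (the hclust tree), `withinss_ward`, `withinss_kmeans`.
#' @export
cluster_observations <- function(x, k, transform = c("log1p", "none"),
                                 var_explained = 0.9, seed = NULL) {
  m <- .obs_matrix(x, transform)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(m)) stop("k exceeds the number of observations")
  if (!is.null(seed)) set.seed(seed)
  scores <- .pca_scores(m, var_explained)
  hc <- hclust(dist(scores), method = "ward.D2")
  part <- cutree(hc, k = k)
  if (length(unique(part)) < k || nrow(unique(scores)) < k)
    stop("observations too similar to form ", k, " groups")
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(scores)), part),
                                     function(i) colMeans(scores[i, ,
                                                                 drop = FALSE])))
  wss <- function(g) sum(vapply(split(seq_len(nrow(scores)), g), function(i)
    sum(scale(scores[i, , drop = FALSE], scale = FALSE)^2), numeric(1)))
  km <- if (k == 1L) list(cluster = rep(1L, nrow(scores)),
                          withinss = wss(part))
        else suppressWarnings(kmeans(scores, centers = centroids,
                                     iter.max = 100))
  raw <- if (inherits(x, "bait_survey")) counts_matrix(x) else NULL
  gm <- if (!is.null(raw))
    do.call(rbind, lapply(split(seq_len(nrow(raw)), km$cluster),
                          function(i) colMeans(raw[i, , drop = FALSE])))
  structure(list(group = unname(km$cluster), k = k,
                 group_means = gm, scores = scores, ward = hc,
                 withinss_ward = wss(part),
                 withinss_kmeans = sum(km$withinss)),
            class = "group_assignment")
}

#' Choose the number of momentary-community groups by mean silhouette
#'
#' Clusters over `k_min..k_max` and returns the `k` with the highest mean
#' silhouette width on the PCA projection; ties go to the smallest `k`. A
#' best silhouette below 0.45 indicates structure too weak to justify the
#' partition: `k_min` is returned with a warning.
#'
#' @inheritParams cluster_observations
#' @param k_min,k_max inclusive search range.
#' @return the selected `k`, with the silhouette profile in attribute
#'   `silhouette`.
#' @export
choose_k <- function(x, k_min = 2, k_max = 8, transform = c("log1p", "none"),
                     var_explained = 0.9, seed = NULL) {
  if (k_min > k_max) stop("empty k range")
  if (k_min == k_max) return(k_min)
  m <- .obs_matrix(x, transform)
  if (k_max > nrow(m) - 1) stop("k_max exceeds n - 1")
  ks <- seq(k_min, k_max)
  d <- NULL
  sil <- vapply(ks, function(k) {
    a <- cluster_observations(x, k, transform = transform,
                              var_explained = var_explained, seed = seed)
    if (is.null(d)) d <<- dist(a$scores)
    mean(cluster::silhouette(a$group, d)[, "sil_width"])
  }, numeric(1))
  best <- ks[which.max(sil)]
  if (max(sil) < 0.45) {
    warning("weak cluster structure (best mean silhouette ",
            round(max(sil), 2), "); returning the smallest k")
    best <- k_min
  }
  structure(best, silhouette = setNames(sil, ks))
}

#' Name groups by their numerically dominant species
#'
#' Within each group, species are ranked by mean abundance. The label is the
#' top species if it is at least `ratio` times as abundant as the runner-up;
#' a co-dominance pair "A+B" if the top two are within `ratio` of each other
#' but both at least `ratio` times the third; otherwise "ND" (no numerical
#' dominant). The ratio mirrors the 2x margin of the bait-control rule.
#'
#' @param assignment a `group_assignment` from [cluster_observations()].
#' @param survey the [bait_survey()] that was clustered (used for raw mean
#'   abundances when the assignment lacks them).
#' @param ratio dominance margin.
#' @return character vector of unique labels, one per group index.
#' @export
name_groups <- function(assignment, survey = NULL, ratio = 2) {
  gm <- assignment$group_means
  if (is.null(gm)) {
    if (is.null(survey)) stop("need a survey to compute group means")
    raw <- counts_matrix(survey)
    gm <- do.call(rbind, lapply(split(seq_len(nrow(raw)), assignment$group),
                                function(i) colMeans(raw[i, , drop = FALSE])))
  }
  labels <- apply(gm, 1, function(mu) {
    if (all(mu <= 0)) return("ND")
    o <- order(-mu, names(mu))  # abundance desc, alphabetical tie-break
    top <- mu[o[1]]; second <- if (length(mu) > 1) mu[o[2]] else 0
    third <- if (length(mu) > 2) mu[o[3]] else 0
    if (top >= ratio * second) return(names(mu)[o[1]])
    if (second > 0 && second >= ratio * third)
      return(paste(names(mu)[o[1:2]], collapse = "+"))
    "ND"
  })
  if (anyDuplicated(labels)) {
    warning("duplicate group labels made unique")
    labels <- make.unique(labels, sep = ".")
  }
  unname(labels)
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Momentary-community assignment: k =", x$k, "groups over",
      length(x$group), "observations\n")
  print(table(group = x$group))
  invisible(x)
}
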