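# Local/neighborhood abundance-correlation modeling: design construction,
# variance-inflation screening, backward likelihood-ratio selection over
# log-link count models, random-structure comparison, and the pairwise
# sign summary. The mixed-model optimizer itself is delegated to lme4.

#' Build the model frame for one focal species
#'
#' One row per bait observation. The response is the focal species' local
#' count; the fixed covariates are the local abundances of the other focal
#' species (`local_*`), the neighborhood mean abundances of every focal
#' species at its own autocorrelation radius (`nbr_*`), and the sampling
#' time (numeric 1..3). Grouping labels for the random structure are the
#' session (date x sampling time) and the momentary-community group of the
#' subplot at sampling time 1 on that date (`group1`). Rows whose
#' neighborhood is undefined are dropped, with a message; they are never
#' imputed.
#'
#' @param survey a [bait_survey()].
#' @param focal focal (response) species code.
#' @param radii named vector of neighborhood radii in metres; its names
#'   define the focal species set.
#' @param groups_t1 data.frame `subplot`, `date`, `group`: the time-1
#'   momentary-community group of every (subplot, date).
#' @return data.frame of class `ant_model_frame` with attributes
#'   `response`, `covariates`, `focal_set`, `radii`.
#' @export
build_model_frame <- function(survey, focal, radii, groups_t1) {
  focal_set <- names(radii)
  if (is.null(focal_set) || !all(focal_set %in% survey$species))
    stop("radii must be named by focal species present in the survey")
  if (!focal %in% focal_set) stop("focal species must be in names(radii)")
  obs <- survey$observations
  fr <- obs[c("subplot", "date", "time", "period")]
  fr$response <- obs[[focal]]
  locals <- paste0("local_", setdiff(focal_set, focal))
  for (j in setdiff(focal_set, focal)) fr[[paste0("local_", j)]] <- obs[[j]]
  nbrs <- paste0("nbr_", focal_set)
  for (s in focal_set)
    fr[[paste0("nbr_", s)]] <-
      neighborhood_abundance(survey, s, radii[[s]])$neighborhood
  fr$time <- as.numeric(obs$time)
  fr$session <- factor(paste(obs$date, obs$time, sep = "."))
  gi <- match(paste(obs$subplot, obs$date),
              paste(groups_t1$subplot, groups_t1$date))
  if (anyNA(gi)) stop("missing time-1 group for some (subplot, date)")
  fr$group1 <- factor(groups_t1$group[gi])
  bad <- rowSums(is.na(fr[nbrs])) > 0
  if (any(bad)) {
    message("build_model_frame(", focal, "): dropping ", sum(bad),
            " row(s) with undefined neighborhoods")
    fr <- fr[!bad, ]
  }
  if (!nrow(fr))
    stop("all rows dropped: no neighborhoods defined (radius below the ",
         "minimum subplot spacing?)")
  structure(fr, response = focal, covariates = c(locals, nbrs, "time"),
            focal_set = focal_set, radii = radii,
            class = c("ant_model_frame", "data.frame"))
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` comes from regressing covariate
#' `k` on all the others. Exactly collinear covariates get `Inf`.
#'
#' @param design numeric data.frame or matrix of covariates (>= 2 columns,
#'   more rows than columns).
#' @return named vector of VIFs (always >= 1).
#' @export
vif <- function(design) {
  X <- as.data.frame(design)
  if (ncol(X) < 2) stop("need >= 2 covariates")
  if (nrow(X) <= ncol(X)) stop("need more observations than covariates")
  vapply(seq_along(X), function(k) {
    r2 <- suppressWarnings(
      summary(lm(X[[k]] ~ ., data = X[-k]))$r.squared)
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(names(X))
}

#' Iterative VIF screening
#'
#' Repeatedly removes the covariate with the largest VIF above `threshold`
#' (exact collinearity first) until all remaining VIFs are acceptable, or
#' one covariate is left.
#'
#' @inheritParams vif
#' @param threshold maximum acceptable VIF (default 3).
#' @return list `keep` (retained covariate names), `removed`, `trace` (VIF
#'   vector at each round).
#' @export
vif_screen <- function(design, threshold = 3) {
  X <- as.data.frame(design)
  removed <- character(0)
  trace <- list()
  while (ncol(X) >= 2) {
    v <- vif(X)
    trace[[length(trace) + 1]] <- v
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    X <- X[setdiff(names(X), worst)]
  }
  list(keep = names(X), removed = removed, trace = trace)
}

# fit a log-link count model with the given fixed terms and random structure
.fit_count_model <- function(frame, terms, engine, random) {
  fixed <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (engine == "glm") {
    f <- as.formula(paste("response ~", fixed))
    glm(f, family = poisson(), data = frame)
  } else {
    re <- switch(random,
                 none = stop("use engine 'glm' for a model without random effects"),
                 intercept = "(1 | session)",
                 slope = "(1 | session) + (0 + time | group1)")
    f <- as.formula(paste("response ~", fixed, "+", re))
    lme4::glmer(f, family = poisson(), data = frame,
                control = lme4::glmerControl(calc.derivs = FALSE))
  }
}

.loglik <- function(fit) as.numeric(logLik(fit))

.fixed_coefs <- function(fit) {
  if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
}

#' Backward likelihood-ratio selection of fixed effects
#'
#' Starting from the full fixed-effect set, repeatedly drops the term whose
#' single-term deletion gives the largest likelihood-ratio p-value above
#' `alpha` (`chi2 = 2 (l_full - l_reduced)`, 1 df per dropped term), until
#' every remaining term is significant. A term whose reduced fit fails is
#' retained with a warning. The full deletion path is returned.
#'
#' @param frame an `ant_model_frame`, or any data.frame with a `response`
#'   column (then pass `covariates`).
#' @param covariates candidate fixed-effect terms; defaults to the frame's
#'   `covariates` attribute.
#' @param engine "glm" (Poisson GLM) or "glmer" (Poisson GLMM via lme4).
#' @param random random structure for the glmer engine: "intercept"
#'   (session intercept) or "slope" (session intercept + random slope of
#'   sampling time by time-1 group).
#' @param alpha retention level; `alpha = 1` returns the full model
#'   unchanged.
#' @return list of class `ant_model`: `fit`, `terms` (retained), `path`
#'   (data.frame of drops with p-values), `engine`, `random`, `alpha`,
#'   `response`.
#' @export
backward_select <- function(frame, covariates = attr(frame, "covariates"),
                            engine = c("glm", "glmer"),
                            random = c("intercept", "slope"),
                            alpha = 0.05) {
  engine <- match.arg(engine)
  random <- match.arg(random)
  if (is.null(covariates)) stop("no covariates given")
  terms <- covariates
  fit <- .fit_count_model(frame, terms, engine, random)
  path <- data.frame(step = integer(0), dropped = character(0),
                     p_value = numeric(0))
  step <- 0L
  while (length(terms) && alpha < 1) {
    ll <- .loglik(fit)
    pv <- vapply(terms, function(tm) {
      red <- tryCatch(.fit_count_model(frame, setdiff(terms, tm), engine,
                                       random),
                      error = function(e) NULL,
                      warning = function(w) NULL)
      if (is.null(red)) return(NA_real_)
      stat <- max(0, 2 * (ll - .loglik(red)))
      pchisq(stat, df = 1, lower.tail = FALSE)
    }, numeric(1))
    if (anyNA(pv)) {
      warning("reduced fit failed for: ",
              paste(terms[is.na(pv)], collapse = ", "), "; term(s) retained")
      pv[is.na(pv)] <- 0
    }
    if (max(pv) <= alpha) break
    worst <- terms[which.max(pv)]
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = worst,
                                   p_value = max(pv)))
    terms <- setdiff(terms, worst)
    fit <- .fit_count_model(frame, terms, engine, random)
  }
  structure(list(fit = fit, terms = terms, path = path, engine = engine,
                 random = if (engine == "glm") "none" else random,
                 alpha = alpha,
                 response = attr(frame, "response") %||% "response",
                 focal_set = attr(frame, "focal_set")),
            class = "ant_model")
}

#' Compare random-effect structures by AIC and LRT
#'
#' Fits the full fixed-effect model under three nested random structures -
#' none (Poisson GLM), a session random intercept, and the session
#' intercept plus a random slope of sampling time by time-1 group - and
#' returns the structure minimizing AIC together with the likelihood-ratio
#' tests between nested neighbors (boundary-of-parameter-space caveat
#' noted: these p-values are conservative).
#'
#' @inheritParams backward_select
#' @return list `structure` ("none"/"intercept"/"slope"), `aic` (named
#'   vector), `lrt` (data.frame), `fits`.
#' @export
random_structure_compare <- function(frame,
                                     covariates = attr(frame, "covariates"),
                                     engine = c("glmer", "glm")) {
  engine <- match.arg(engine)
  if (engine == "glm") {
    message("engine without random-effect support; using fixed effects only")
    fit <- .fit_count_model(frame, covariates, "glm", "none")
    return(list(structure = "none", aic = c(none = AIC(fit)),
                lrt = NULL, fits = list(none = fit)))
  }
  if (nlevels(droplevels(factor(frame$session))) < 2)
    stop("a single session: random intercept inestimable")
  fits <- list(none = .fit_count_model(frame, covariates, "glm", "none"))
  fits$intercept <- tryCatch(
    .fit_count_model(frame, covariates, "glmer", "intercept"),
    error = function(e) NULL)
  fits$slope <- tryCatch(
    .fit_count_model(frame, covariates, "glmer", "slope"),
    error = function(e) NULL)
  fits <- Filter(Negate(is.null), fits)
  aic <- vapply(fits, AIC, numeric(1))
  nm <- names(fits)
  lrt <- NULL
  for (i in seq_len(length(fits) - 1)) {
    stat <- max(0, 2 * (.loglik(fits[[i + 1]]) - .loglik(fits[[i]])))
    lrt <- rbind(lrt, data.frame(comparison = paste(nm[i], "vs", nm[i + 1]),
                                 chisq = stat, df = 1,
                                 p_value = pchisq(stat, 1,
                                                  lower.tail = FALSE)))
  }
  list(structure = nm[which.min(aic)], aic = aic, lrt = lrt, fits = fits)
}

#' Pairwise sign summary of retained abundance correlations
#'
#' Collects the signs of the retained (hence significant) `local_*` and
#' `nbr_*` coefficients of one final model per focal species into two
#' focal-by-focal matrices, and classifies each unordered local pair as
#' symmetrically negative ("-/-"), symmetrically positive ("+/+"), mixed
#' (any other combination with at least one retained term), or "ns".
#'
#' @param models named list of `ant_model` results, one per focal species.
#' @return list of class `sign_summary`: `local` and `neighborhood`
#'   character matrices (rows = response species), `pairs` data.frame.
#' @export
sign_summary <- function(models) {
  focal_set <- models[[1]]$focal_set %||% names(models)
  resp <- names(models)
  local <- matrix("ns", length(resp), length(focal_set),
                  dimnames = list(resp, focal_set))
  nbr <- local
  for (r in resp) {
    cf <- .fixed_coefs(models[[r]]$fit)
    for (tm in models[[r]]$terms) {
      sgn <- if (cf[[tm]] > 0) "+" else "-"
      if (startsWith(tm, "local_"))
        local[r, sub("^local_", "", tm)] <- sgn
      else if (startsWith(tm, "nbr_"))
        nbr[r, sub("^nbr_", "", tm)] <- sgn
    }
  }
  pairs <- NULL
  for (i in seq_along(resp)) for (j in seq_along(resp)) {
    if (j <= i) next
    a <- local[resp[i], resp[j]]; b <- local[resp[j], resp[i]]
    cls <- if (a == "-" && b == "-") "-/-"
           else if (a == "+" && b == "+") "+/+"
           else if (a == "ns" && b == "ns") "ns"
           else "mixed"
    pairs <- rbind(pairs, data.frame(species_a = resp[i],
                                     species_b = resp[j],
                                     sign_a = a, sign_b = b, class = cls))
  }
  structure(list(local = local, neighborhood = nbr, pairs = pairs),
            class = "sign_summary")
}

#' @export
print.sign_summary <- function(x, ...) {
  cat("Local coefficient signs (rows = response species):\n")
  print(x$local)
  cat("Neighborhood coefficient signs:\n")
  print(x$neighborhood)
  invisible(x)
}

#' @export
print.ant_model <- function(x, ...) {
  cat("Count model for", x$response, "(", x$engine, ", random:", x$random,
      ")\n  retained terms:",
      if (length(x$terms)) paste(x$terms, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
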