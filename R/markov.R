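# Markov analysis of momentary-community dynamics: transition counting and
# row-normalized estimation between sampling times, and the probability of
# maintaining numerical dominance from time 1 to time 3, by Monte-Carlo
# simulation and in closed form.

#' Per-(subplot, date) group-label sequences
#'
#' Reshapes a per-observation group labelling of a bait survey into one
#' label sequence per (subplot, date), ordered by sampling time.
#'
#' @param survey a [bait_survey()].
#' @param labels character vector of group labels aligned with
#'   `survey$observations` rows.
#' @return character matrix, one row per (subplot, date), one column per
#'   sampling time.
#' @export
group_sequences <- function(survey, labels) {
  obs <- survey$observations
  if (length(labels) != nrow(obs))
    stop("labels must align with survey observations")
  key <- paste(obs$subplot, obs$date, sep = ".")
  seqs <- matrix(NA_character_, length(unique(key)), survey$n_times,
                 dimnames = list(unique(key),
                                 paste0("t", seq_len(survey$n_times))))
  seqs[cbind(match(key, rownames(seqs)), obs$time)] <- labels
  if (anyNA(seqs)) {
    drop <- unique(which(is.na(seqs), arr.ind = TRUE)[, 1])
    warning("dropping ", length(drop), " incomplete sequences")
    seqs <- seqs[-drop, , drop = FALSE]
  }
  seqs
}

#' Count state transitions at one step
#'
#' `n[i, j]` is the number of sequences in state `i` at the step's origin
#' time and state `j` at its destination.
#'
#' @param sequences matrix of state labels, one row per sequence, columns in
#'   time order (e.g. from [group_sequences()]).
#' @param step step index: origin column `step`, destination `step + 1`.
#' @param states state labels fixing the matrix dimensions; default: all
#'   labels observed in `sequences`.
#' @return integer count matrix (states x states).
#' @export
count_transitions <- function(sequences, step = 1, states = NULL) {
  sequences <- as.matrix(sequences)
  if (nrow(sequences) && ncol(sequences) < step + 1)
    stop("sequences need at least ", step + 1, " entries")
  if (is.null(states))
    states <- sort(unique(as.vector(sequences)))
  if (nrow(sequences)) {
    unknown <- setdiff(unique(as.vector(sequences[, c(step, step + 1)])),
                       states)
    if (length(unknown))
      stop("unknown state labels: ", paste(unknown, collapse = ", "))
  }
  from <- factor(sequences[, step], levels = states)
  to <- factor(sequences[, step + 1], levels = states)
  unclass(table(from, to, dnn = NULL))
}

#' Estimate a transition probability matrix from counts
#'
#' Row-normalizes a transition count matrix. Rows with zero total are
#' unobserved origin states: they are returned as `NA` (never imputed) and
#' listed in the `unobserved` attribute.
#'
#' @param counts non-negative count matrix (states x states).
#' @return row-stochastic matrix with `NA` rows for unobserved states.
#' @export
estimate_transition_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  tot <- rowSums(counts)
  P <- counts / ifelse(tot > 0, tot, NA_real_)
  attr(P, "unobserved") <- rownames(counts)[tot == 0]
  P
}

#' Transition model over consecutive sampling times
#'
#' Convenience wrapper building, for each consecutive pair of sampling
#' times, the transition count matrix and its row-normalized probability
#' matrix.
#'
#' @inheritParams count_transitions
#' @return list of class `transition_model`: `states`, `counts` (list per
#'   step), `probs` (list per step), `n_sequences`.
#' @export
transition_model <- function(sequences, states = NULL) {
  sequences <- as.matrix(sequences)
  if (is.null(states)) states <- sort(unique(as.vector(sequences)))
  steps <- seq_len(ncol(sequences) - 1)
  counts <- lapply(steps, count_transitions, sequences = sequences,
                   states = states)
  names(counts) <- paste0("t", steps, steps + 1)
  structure(list(states = states, counts = counts,
                 probs = lapply(counts, estimate_transition_matrix),
                 n_sequences = nrow(sequences)),
            class = "transition_model")
}

.check_stochastic <- function(Tm, name) {
  ok <- !apply(is.na(Tm), 1, any)
  if (any(Tm[ok, ] < -1e-12) || any(Tm[ok, ] > 1 + 1e-12))
    stop(name, " entries must lie in [0, 1]")
  if (any(abs(rowSums(Tm[ok, , drop = FALSE]) - 1) > 1e-8))
    stop(name, " rows must sum to 1")
  ok
}

#' Simulate the maintenance of numerical dominance across two steps
#'
#' For each state `i`, simulates `iterations` two-step chains started in
#' `i`: a destination is drawn from `T12[i, ]`, then from `T23` at that
#' state. Maintenance from time 1 to time 3 is the fraction of chains that
#' remain in `i` at BOTH steps, i.e. the Monte-Carlo counterpart of the
#' diagonal product `T12[i,i] * T23[i,i]`; `return_inclusive = TRUE`
#' instead counts chains occupying `i` at time 3 regardless of the time-2
#' state (adding leave-and-return paths). Unobserved (`NA`) origin rows are
#' skipped with a warning. Per-state simulations use independent RNG
#' streams derived from `seed`.
#'
#' @param T12,T23 row-stochastic matrices on a common state space.
#' @param iterations number of chains per state (>= 1).
#' @param seed master RNG seed.
#' @param return_inclusive count leave-and-return paths as maintained.
#' @return data.frame of class `maintenance_result` with columns `state`,
#'   `p12`, `p23` (per-step retention, the diagonals), `maintain_13`
#'   (simulated), `closed_form`, `se` (binomial Monte-Carlo standard
#'   error), `iterations`.
#' @export
simulate_maintenance <- function(T12, T23, iterations = 10000, seed = NULL,
                                 return_inclusive = FALSE) {
  T12 <- as.matrix(T12); T23 <- as.matrix(T23)
  .check_state_space(T12, T23)
  if (iterations < 1) stop("iterations must be >= 1")
  ok12 <- .check_stochastic(T12, "T12")
  ok23 <- .check_stochastic(T23, "T23")
  states <- rownames(T12)
  if (is.null(states)) states <- as.character(seq_len(nrow(T12)))
  closed <- maintenance_closed_form(T12, T23)
  res <- lapply(seq_along(states), function(i) {
    if (!ok12[i]) {
      warning("origin state ", states[i], " unobserved; skipped")
      return(NULL)
    }
    if (!is.null(seed)) set.seed(seed + i - 1)
    s2 <- sample.int(length(states), iterations, replace = TRUE,
                     prob = T12[i, ])
    s3 <- integer(iterations)
    for (j in unique(s2)) {
      if (!ok23[j]) {
        warning("time-2 state ", states[j],
                " has an unobserved transition row; chains stopped there")
        s3[s2 == j] <- NA_integer_
        next
      }
      idx <- s2 == j
      s3[idx] <- sample.int(length(states), sum(idx), replace = TRUE,
                            prob = T23[j, ])
    }
    kept <- if (return_inclusive) !is.na(s3) & s3 == i
            else s2 == i & !is.na(s3) & s3 == i
    p <- mean(kept)
    data.frame(state = states[i], p12 = T12[i, i], p23 = T23[i, i],
               maintain_13 = p, closed_form = closed[i],
               se = sqrt(p * (1 - p) / iterations),
               iterations = iterations)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("maintenance_result", class(out))
  out
}

#' Closed-form maintenance probability
#'
#' Probability of staying in state `i` across both steps: the product of
#' the per-step diagonal retention probabilities.
#'
#' @inheritParams simulate_maintenance
#' @return named vector `diag(T12) * diag(T23)`.
#' @export
maintenance_closed_form <- function(T12, T23) {
  T12 <- as.matrix(T12); T23 <- as.matrix(T23)
  .check_state_space(T12, T23)
  setNames(diag(T12) * diag(T23),
           rownames(T12) %||% as.character(seq_len(nrow(T12))))
}

.check_state_space <- function(T12, T23) {
  if (!identical(dim(T12), dim(T23)) || nrow(T12) != ncol(T12) ||
      !identical(dimnames(T12), dimnames(T23)))
    stop("T12 and T23 must share a common square state space")
  if (!is.null(dimnames(T12)) && !identical(rownames(T12), colnames(T12)))
    stop("T12 and T23 must share a common square state space")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transition_model <- function(x, ...) {
  cat("Transition model:", length(x$states), "states,",
      x$n_sequences, "sequences,", length(x$counts), "steps\n")
  for (s in names(x$probs)) {
    cat("step", s, ":\n")
    print(round(x$probs[[s]], 3))
  }
  invisible(x)
}
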