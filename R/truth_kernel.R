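# Ground-truth semi-Markov succession kernel. Stands in for the detailed
# process-based simulator whose output would normally train the
# transition classifier; every coefficient is explicit so that closed
# forms and stationary distributions are available as oracles.

#' Create a ground-truth transition kernel
#'
#' The kernel defines, for every registered state, the annual hazard of
#' leaving the state and the distribution over successor states.
#'
#' Hazard: `h(S, R, T) = base_S * plogis(steepness_S * (R - midpoint_S))
#' + temp_effect_S * (T - temp_ref)`, clamped to `[0, 1]`, where `R` is
#' residence time in years and `T` the annual mean temperature. At
#' `R = midpoint` and `T = temp_ref` the hazard equals `base / 2`.
#'
#' Successor support: any registered state other than the current one
#' whose height class is at most `max_height_step` above the current
#' height class (growth is gradual; collapse to any lower structure is
#' allowed). Target log-weights over the support are
#' `base_logit + neigh_coef * seed_pressure + (-therm_sel * |T - opt|)`,
#' where `seed_pressure` is the mean neighbourhood share (tiers averaged)
#' of the successor's member species and `opt` the mean thermal optimum
#' of its members (bare successors take neither bonus).
#'
#' @param state_table A populated [state_table].
#' @param seed Integer seed for the random base log-weights.
#' @param base,midpoint,steepness,temp_effect Hazard coefficients,
#'   recycled over states. `base` in `[0, 1]`, `midpoint` in years,
#'   `temp_effect` per degree C.
#' @param temp_ref Reference temperature (degrees C).
#' @param neigh_coef Logit bonus per unit neighbourhood share.
#' @param therm_sel Logit penalty per degree C of mismatch between
#'   temperature and a successor's thermal optimum (needs
#'   `thermal_optimum` on the pool when positive).
#' @param logit_sd Standard deviation of the random base log-weights.
#' @param max_height_step Maximum upward height-class step per
#'   transition (default 1).
#' @return An object of class `truth_kernel`.
#' @export
make_truth_kernel <- function(state_table, seed = 1L,
                              base = 0.15, midpoint = 20, steepness = 0.15,
                              temp_effect = 0, temp_ref = 8,
                              neigh_coef = 0, therm_sel = 0,
                              logit_sd = 1, max_height_step = 1L) {
  stopifnot(inherits(state_table, "state_table"))
  n <- n_states(state_table)
  if (n < 1L) stop("state table has no registered states")
  base <- rep_len(base, n); midpoint <- rep_len(midpoint, n)
  steepness <- rep_len(steepness, n); temp_effect <- rep_len(temp_effect, n)
  if (any(base < 0 | base > 1)) stop("base hazard must be in [0, 1]")
  hts <- vapply(state_table$states, `[[`, integer(1), "height_class")
  support <- lapply(seq_len(n), function(i) {
    ok <- which(hts <= hts[i] + max_height_step)
    setdiff(ok - 1L, i - 1L)  # 0-based ids, self excluded
  })
  if (any(vapply(support, length, integer(1)) == 0L))
    stop("every state needs at least one possible successor")
  set.seed(as.integer(seed))
  base_logits <- matrix(stats::rnorm(n * n, 0, logit_sd), n, n)
  W <- state_species_weights(state_table)
  opt <- rep(NA_real_, n)
  if (!is.null(state_table$pool$thermal_optimum)) {
    to <- state_table$pool$thermal_optimum
    for (i in seq_len(n)) {
      m <- state_table$states[[i]]$composition$members
      if (length(m)) opt[i] <- mean(to[m])
    }
  } else if (therm_sel > 0) {
    stop("therm_sel > 0 requires thermal_optimum on the species pool")
  }
  structure(list(n_states = n, base = base, midpoint = midpoint,
                 steepness = steepness, temp_effect = temp_effect,
                 temp_ref = temp_ref, neigh_coef = neigh_coef,
                 therm_sel = therm_sel, base_logits = base_logits,
                 support = support, weights = W, opt = opt,
                 max_height_step = as.integer(max_height_step),
                 pool = state_table$pool, seed = as.integer(seed)),
            class = "truth_kernel")
}

#' @export
print.truth_kernel <- function(x, ...) {
  cat("<truth_kernel>", x$n_states, "states; base hazard",
      paste(range(x$base), collapse = "-"),
      "; neigh_coef", x$neigh_coef, "; therm_sel", x$therm_sel, "\n")
  invisible(x)
}

#' Annual leaving hazard of the truth kernel
#'
#' Vectorized over cells; see [make_truth_kernel()] for the closed form.
#'
#' @param kernel A [make_truth_kernel()] object.
#' @param state_id Integer vector of current state ids.
#' @param R Integer vector of residence times (years).
#' @param temp Numeric vector of annual mean temperatures (degrees C).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
kernel_hazard <- function(kernel, state_id, R, temp) {
  i <- state_id + 1L
  h <- kernel$base[i] * stats::plogis(kernel$steepness[i] *
                                        (R - kernel$midpoint[i])) +
    kernel$temp_effect[i] * (temp - kernel$temp_ref)
  pmin(1, pmax(0, h))
}

#' Target-state distributions of the truth kernel
#'
#' @param kernel A truth kernel.
#' @param state_id Integer vector of current state ids (length n).
#' @param t1,t2 Matrices `n x pool` of tier-1 and tier-2 neighbourhood
#'   species shares (zero matrices when the kernel has no neighbourhood
#'   term may be passed as `NULL`).
#' @param temp Numeric vector of annual mean temperatures.
#' @return Matrix `n x n_states` of successor probabilities; each row
#'   sums to 1 and is zero outside the current state's support.
#' @export
kernel_target_distribution <- function(kernel, state_id, t1 = NULL,
                                       t2 = NULL, temp = NULL) {
  n <- length(state_id)
  P <- ncol(kernel$weights)
  if (is.null(t1)) t1 <- matrix(0, n, P)
  if (is.null(t2)) t2 <- matrix(0, n, P)
  if (is.null(temp)) temp <- rep(kernel$temp_ref, n)
  out <- matrix(0, n, kernel$n_states)
  for (s in unique(state_id)) {
    rows <- which(state_id == s)
    sup <- kernel$support[[s + 1L]] + 1L
    logit <- matrix(kernel$base_logits[s + 1L, sup], length(rows),
                    length(sup), byrow = TRUE)
    if (kernel$neigh_coef != 0) {
      press <- (0.5 * t1[rows, , drop = FALSE] +
                  0.5 * t2[rows, , drop = FALSE]) %*%
        t(kernel$weights[sup, , drop = FALSE])
      logit <- logit + kernel$neigh_coef * press
    }
    if (kernel$therm_sel != 0) {
      mismatch <- abs(outer(temp[rows], kernel$opt[sup], "-"))
      mismatch[is.na(mismatch)] <- 0  # bare successor: no thermal term
      logit <- logit - kernel$therm_sel * mismatch
    }
    logit <- logit - apply(logit, 1, max)
    w <- exp(logit)
    out[rows, sup] <- w / rowSums(w)
  }
  out
}

#' Exact time-to-transition distribution under the kernel
#'
#' Probability that a cell currently at residence time `R` leaves its
#' state in exactly `k` years (`k = 1..horizon`), plus the censored
#' probability of surviving the whole horizon, at constant temperature:
#' `P(k) = prod_{j<k-1}(1 - h(R+j)) * h(R+k-1)`.
#'
#' @param kernel A truth kernel.
#' @param state_id Integer vector of state ids.
#' @param R Integer vector of residence times.
#' @param temp Numeric vector of annual mean temperatures.
#' @param horizon Prediction horizon in years (default 10).
#' @return Matrix `n x (horizon+1)`; column 1 is the censored class, and
#'   column `k+1` the probability of a transition in year `k`.
#' @export
kernel_dR_distribution <- function(kernel, state_id, R, temp, horizon = 10L) {
  n <- length(state_id)
  out <- matrix(0, n, horizon + 1L)
  surv <- rep(1, n)
  for (k in seq_len(horizon)) {
    h <- kernel_hazard(kernel, state_id, R + k - 1L, temp)
    out[, k + 1L] <- surv * h
    surv <- surv * (1 - h)
  }
  out[, 1L] <- surv
  out
}
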