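# Empirical (tabulated) transition models. Conditional class frequencies
# over discretized key predictors; with the keys set to the truth
# kernel's true inputs this converges to the Bayes classifier on
# synthetic data and serves as the oracle the neural model is judged
# against. All models in the package share one prediction contract:
# predict(model, context, climate) returns
#   p_dR    n x (horizon+1) matrix (column 1 = censored class 0),
#   p_state n x n_states matrix over the full state space,
# both rows summing to 1.

tab_keys <- function(context, keys, bins, R_cap) {
  vals <- lapply(keys, function(k) {
    v <- context[[k]]
    if (is.null(v)) stop("context lacks key column '", k, "'")
    if (k == "R" && !is.null(R_cap)) v <- pmin(v, R_cap)
    if (!is.null(bins[[k]]))
      v <- as.integer(cut(v, bins[[k]], include.lowest = TRUE))
    v
  })
  do.call(paste, vals)
}

#' Fit a tabulated transition model
#'
#' Estimates the timing and target-state distributions as exact
#' empirical conditionals over discretized key predictors, with optional
#' Laplace smoothing. Keys unseen at prediction time back off to the
#' marginal distributions.
#'
#' @param examples An `example_set`.
#' @param keys Context column names to condition on (default state and
#'   residence time).
#' @param alpha Laplace smoothing pseudo-count (default 0 = exact
#'   empirical frequencies).
#' @param bins Named list of break vectors for continuous keys (passed
#'   to `cut`), e.g. `list(tmean_annual = seq(0, 20, 2))`.
#' @param R_cap Optional cap applied to the `R` key.
#' @return An object of class `tabulated_model`.
#' @export
fit_tabulated <- function(examples, keys = c("state", "R"), alpha = 0,
                          bins = list(), R_cap = NULL) {
  stopifnot(inherits(examples, "example_set"))
  horizon <- examples$horizon
  nS <- examples$n_states
  key <- tab_keys(examples$context, keys, bins, R_cap)
  ukey <- sort(unique(key))
  ki <- match(key, ukey)
  ndr <- horizon + 1L
  p_dR <- matrix(alpha, length(ukey), ndr,
                 dimnames = list(ukey, NULL))
  cnt <- table(factor(ki, seq_along(ukey)), factor(examples$dR, 0:horizon))
  p_dR <- p_dR + unclass(cnt)
  p_dR <- p_dR / rowSums(p_dR)
  has <- !is.na(examples$S_star)
  p_state <- matrix(alpha, length(ukey), nS, dimnames = list(ukey, NULL))
  cnt2 <- table(factor(ki[has], seq_along(ukey)),
                factor(examples$S_star[has], 0:(nS - 1L)))
  p_state <- p_state + unclass(cnt2)
  marg_state <- colSums(p_state) + 1e-12
  marg_state <- marg_state / sum(marg_state)
  empty <- rowSums(p_state) == 0
  if (any(empty))  # keys with only censored rows back off to the marginal
    p_state[empty, ] <- matrix(marg_state, sum(empty), nS, byrow = TRUE)
  p_state <- p_state / rowSums(p_state)
  marg_dR <- colSums(cnt) + 1e-12
  structure(list(keys = keys, bins = bins, R_cap = R_cap,
                 p_dR = p_dR, p_state = p_state,
                 marg_dR = marg_dR / sum(marg_dR), marg_state = marg_state,
                 n_states = nS, horizon = horizon, alpha = alpha),
            class = "tabulated_model")
}

#' @export
print.tabulated_model <- function(x, ...) {
  cat("<tabulated_model> keyed on", paste(x$keys, collapse = " x "),
      "-", nrow(x$p_dR), "key combinations\n")
  invisible(x)
}

#' @export
predict.tabulated_model <- function(object, context, climate = NULL, ...) {
  key <- tab_keys(context, object$keys, object$bins, object$R_cap)
  i <- match(key, rownames(object$p_dR))
  n <- length(key)
  p_dR <- matrix(object$marg_dR, n, object$horizon + 1L, byrow = TRUE)
  p_state <- matrix(object$marg_state, n, object$n_states, byrow = TRUE)
  hit <- !is.na(i)
  p_dR[hit, ] <- object$p_dR[i[hit], , drop = FALSE]
  p_state[hit, ] <- object$p_state[i[hit], , drop = FALSE]
  list(p_dR = p_dR, p_state = p_state)
}

#' Tabulate the truth kernel into an exact transition model
#'
#' Builds a `tabulated_model` whose tables are the kernel's exact
#' probabilities over (state, residence time) at a fixed temperature and
#' fixed neighbourhood shares — the idealized Bayes model used in
#' oracle-equivalence tests of the simulation engine.
#'
#' @param kernel A truth kernel.
#' @param temp Fixed annual mean temperature.
#' @param R_max Residence cap of the table (hazards must have saturated
#'   by then).
#' @param horizon Prediction horizon (default 10).
#' @param t1,t2 Fixed share vectors (default zero).
#' @return A `tabulated_model` keyed on `c("state", "R")`.
#' @export
tabulate_kernel <- function(kernel, temp, R_max = 150L, horizon = 10L,
                            t1 = NULL, t2 = NULL) {
  nS <- kernel$n_states
  P <- ncol(kernel$weights)
  if (is.null(t1)) t1 <- numeric(P)
  if (is.null(t2)) t2 <- numeric(P)
  grid <- expand.grid(R = 0:R_max, state = 0:(nS - 1L))
  p_dR <- kernel_dR_distribution(kernel, grid$state, grid$R,
                                 rep(temp, nrow(grid)), horizon)
  tg <- kernel_target_distribution(kernel, 0:(nS - 1L),
                                   matrix(t1, nS, P, byrow = TRUE),
                                   matrix(t2, nS, P, byrow = TRUE),
                                   rep(temp, nS))
  p_state <- tg[grid$state + 1L, , drop = FALSE]
  keys <- paste(grid$state, grid$R)
  rownames(p_dR) <- keys; rownames(p_state) <- keys
  structure(list(keys = c("state", "R"), bins = list(), R_cap = R_max,
                 p_dR = p_dR, p_state = p_state,
                 marg_dR = colMeans(p_dR), marg_state = colMeans(p_state),
                 n_states = nS, horizon = as.integer(horizon), alpha = 0),
            class = "tabulated_model")
}

#' Exact kernel-backed transition model
#'
#' Computes the truth kernel's timing and target distributions directly
#' from each cell's context (state, residence time, annual temperature
#' and tier shares). Unlike [tabulate_kernel()] this honours
#' temperature- and neighbourhood-dependence, assuming the current
#' annual temperature persists over the prediction horizon.
#'
#' @param kernel A truth kernel.
#' @param horizon Prediction horizon (default 10).
#' @return An object of class `kernel_model`.
#' @export
kernel_model <- function(kernel, horizon = 10L) {
  structure(list(kernel = kernel, horizon = as.integer(horizon),
                 n_states = kernel$n_states),
            class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat("<kernel_model> exact truth-kernel probabilities,",
      x$n_states, "states\n")
  invisible(x)
}

#' @export
predict.kernel_model <- function(object, context, climate = NULL, ...) {
  k <- object$kernel
  pool <- colnames(k$weights)
  t1 <- as.matrix(context[, paste0("t1_", pool), drop = FALSE])
  t2 <- as.matrix(context[, paste0("t2_", pool), drop = FALSE])
  list(p_dR = kernel_dR_distribution(k, context$state, context$R,
                                     context$tmean_annual, object$horizon),
       p_state = kernel_target_distribution(k, context$state, t1, t2,
                                            context$tmean_annual))
}

#' Evaluate a transition model on a test set
#'
#' Top-1 accuracy of the timing head (all rows, censored class
#' included), top-1 and top-3 accuracy of the target-state head
#' (non-censored rows only), and, when a reference model is supplied,
#' the mean total-variation distance between the two models'
#' target-state distributions.
#'
#' @param model A model obeying the prediction contract.
#' @param test An `example_set`.
#' @param climate Climate table (needed by feature-based models).
#' @param reference Optional reference model (e.g. [kernel_model()]).
#' @return A list of metrics, each in `[0, 1]`.
#' @export
evaluate_model <- function(model, test, climate = NULL, reference = NULL) {
  stopifnot(inherits(test, "example_set"), length(test$dR) > 0L)
  pred <- stats::predict(model, test$context, climate)
  stopifnot(all(abs(rowSums(pred$p_dR) - 1) < 1e-6),
            all(abs(rowSums(pred$p_state) - 1) < 1e-6))
  top1_dR <- mean(row_argmax(pred$p_dR) - 1L == test$dR)
  has <- !is.na(test$S_star)
  truth <- test$S_star[has] + 1L
  ps <- pred$p_state[has, , drop = FALSE]
  top1_state <- mean(row_argmax(ps) == truth)
  top3_state <- mean(row_topk_hit(ps, truth, 3L))
  out <- list(top1_dR = top1_dR, top1_state = top1_state,
              top3_state = top3_state, n = length(test$dR),
              n_uncensored = sum(has))
  if (!is.null(reference)) {
    ref <- stats::predict(reference, test$context, climate)
    out$mean_tv_state <- mean(0.5 * rowSums(abs(pred$p_state - ref$p_state)))
    out$mean_tv_dR <- mean(0.5 * rowSums(abs(pred$p_dR - ref$p_dR)))
  }
  out
}
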