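# Two-headed multilayer perceptron for transition prediction: a shared
# ReLU trunk feeding a softmax over transition timing (censored class +
# years 1..horizon) and a softmax over target states (support = states
# realized in training). Written directly on BLAS matrix ops: training
# sets here are desk-scale (1e5-1e6 rows) and a dependency-free,
# seed-reproducible implementation is worth more than raw speed.

#' Configuration of the neural transition model
#'
#' @param hidden Integer vector of hidden-layer widths. The default
#'   (four layers of 256) suits large synthetic spaces; tests use
#'   smaller nets.
#' @param dropout Dropout probability on hidden activations (default
#'   0.2; inverted dropout, disabled at prediction time).
#' @param learning_rate Adam step size.
#' @param lr_decay Multiplicative learning-rate decay per epoch
#'   (default 1 = constant).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param l2 L2 penalty on weights (default 0).
#' @param climate_encoding Passed to [feature_schema()].
#' @param use_shares Include the tier-1/tier-2 neighbourhood share
#'   features (set `FALSE` for spatial-context ablations).
#' @param two_networks Train separate trunks for the timing and
#'   target-state heads instead of one shared trunk (default `FALSE`).
#'   A dedicated target-state trunk ignores predictors irrelevant to
#'   that head more readily, at twice the training cost.
#' @param verbose Print per-epoch losses.
#' @return A config list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(256, 256, 256, 256), dropout = 0.2,
                       learning_rate = 1e-3, lr_decay = 1,
                       batch_size = 512L, epochs = 30L, l2 = 0,
                       climate_encoding = "monthly",
                       use_shares = TRUE, two_networks = FALSE,
                       verbose = FALSE) {
  stopifnot(all(hidden >= 1), dropout >= 0, dropout < 1,
            learning_rate > 0, lr_decay > 0, lr_decay <= 1,
            batch_size >= 1, epochs >= 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2 = l2,
                 climate_encoding = climate_encoding,
                 use_shares = isTRUE(use_shares),
                 two_networks = isTRUE(two_networks),
                 verbose = isTRUE(verbose)),
            class = "mlp_config")
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Parameters live in one flat named list (W1..WL, b1..bL, Wd, bd, Ws,
# bs) so the Adam update can walk them uniformly.
mlp_init <- function(p, hidden, n_dR, n_state) {
  dims <- c(p, hidden)
  params <- list(n_layers = length(hidden))
  for (l in seq_along(hidden)) {
    params[[paste0("W", l)]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                                    sd = sqrt(2 / dims[l])),
                                       dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  h <- dims[length(dims)]
  params$Wd <- matrix(stats::rnorm(h * n_dR, sd = sqrt(2 / h)), h, n_dR)
  params$bd <- numeric(n_dR)
  params$Ws <- matrix(stats::rnorm(h * n_state, sd = sqrt(2 / h)), h, n_state)
  params$bs <- numeric(n_state)
  params
}

mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  L <- params$n_layers
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    h <- relu(sweep(acts[[l]] %*% params[[paste0("W", l)]], 2,
                    params[[paste0("b", l)]], "+"))
    if (training && dropout > 0) {
      m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
      h <- h * m / (1 - dropout)
      masks[[l]] <- m
    }
    acts[[l + 1L]] <- h
  }
  top <- acts[[L + 1L]]
  list(acts = acts, masks = masks,
       logits_dR = sweep(top %*% params$Wd, 2, params$bd, "+"),
       logits_state = sweep(top %*% params$Ws, 2, params$bs, "+"))
}

#' Train the neural transition model
#'
#' Fits the two-headed MLP by minibatch Adam on the joint loss
#' (cross-entropy of the timing head plus cross-entropy of the
#' target-state head, the latter masked on censored rows). Training is
#' seeded and single-threaded-reproducible. Diverging training (NaN
#' loss) raises an error with diagnostics.
#'
#' @param train Training `example_set`.
#' @param climate Climate table covering all example windows.
#' @param state_table The [state_table].
#' @param val Optional validation `example_set`; per-epoch top-1
#'   accuracies are logged.
#' @param config An [mlp_config()].
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @return An object of class `dnn_model` with the weights, feature
#'   scaler, schema hash, realized-state support and a per-epoch
#'   training log.
#' @export
fit_dnn <- function(train, climate, state_table, val = NULL,
                    config = mlp_config(), seed = 1L) {
  stopifnot(inherits(train, "example_set"), length(train$dR) > 0L)
  schema <- feature_schema(state_table, config$climate_encoding,
                           horizon = train$horizon)
  Xraw <- build_features(train$context, climate, schema)
  if (!config$use_shares) {
    drop_cols <- grep("^t[12]_", colnames(Xraw))
    keep <- setdiff(seq_len(ncol(Xraw)), drop_cols)
  } else keep <- seq_len(ncol(Xraw))
  scaler <- fit_scaler(Xraw, schema)
  X <- build_features(train$context, climate, schema, scaler)[, keep,
                                                              drop = FALSE]
  n <- nrow(X)
  y_dR <- train$dR + 1L                       # classes 1..horizon+1
  realized <- sort(unique(train$S_star[!is.na(train$S_star)]))
  if (length(realized) < 1L)
    stop("training set contains no uncensored transitions")
  y_st <- match(train$S_star, realized)       # NA on censored rows
  n_dR <- train$horizon + 1L
  n_st <- length(realized)
  if (config$two_networks) {
    p1 <- mlp_train_core(X, y_dR, NULL, n_dR, n_st, config, seed)
    p2 <- mlp_train_core(X, NULL, y_st, n_dR, n_st, config, seed + 1L)
    model <- dnn_model_obj(list(dR = p1$params, state = p2$params),
                           schema, scaler, keep, realized, train$horizon,
                           config, seed, rbind(p1$log, p2$log))
    if (!is.null(val)) {
      m <- evaluate_model(model, val, climate)
      model$log$val_top1_dR <- m$top1_dR
      model$log$val_top1_state <- m$top1_state
    }
    return(model)
  }
  core <- mlp_train_core(X, y_dR, y_st, n_dR, n_st, config, seed,
                         val_fn = if (is.null(val)) NULL else function(params) {
                           tmp <- dnn_model_obj(params, schema, scaler, keep,
                                                realized, train$horizon,
                                                config, seed, NULL)
                           evaluate_model(tmp, val, climate)
                         })
  return(dnn_model_obj(core$params, schema, scaler, keep, realized,
                       train$horizon, config, seed, core$log))
}

# Minibatch-Adam training loop. y_dR / y_st may be NULL to train a
# single-head network; y_st may contain NA (censored rows are masked
# out of the state loss).
mlp_train_core <- function(X, y_dR, y_st, n_dR, n_st, config, seed,
                           val_fn = NULL) {
  n <- nrow(X)
  set.seed(as.integer(seed))
  params <- mlp_init(ncol(X), config$hidden, n_dR, n_st)
  pnames <- setdiff(names(params), "n_layers")
  adam_m <- lapply(params[pnames], function(x) x * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  lr <- config$learning_rate
  L <- params$n_layers
  log_rows <- list()
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate * config$lr_decay^(epoch - 1)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot_loss <- 0
    for (bi in batches) {
      B <- length(bi)
      fw <- mlp_forward(params, X[bi, , drop = FALSE],
                        dropout = config$dropout, training = TRUE)
      p_d <- softmax_rows(fw$logits_dR)
      p_s <- softmax_rows(fw$logits_state)
      yd <- if (is.null(y_dR)) NULL else y_dR[bi]
      ys <- if (is.null(y_st)) rep(NA_integer_, B) else y_st[bi]
      msk <- !is.na(ys)
      nmask <- max(1L, sum(msk))
      loss <- 0
      if (!is.null(y_dR))
        loss <- loss - mean(log(pmax(p_d[cbind(seq_len(B), yd)], 1e-12)))
      if (!is.null(y_st))
        loss <- loss -
          sum(log(pmax(p_s[cbind(which(msk), ys[msk])], 1e-12))) / nmask
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate or check the feature scaling")
      tot_loss <- tot_loss + loss * B
      if (is.null(y_dR)) gd <- p_d * 0 else {
        gd <- p_d
        gd[cbind(seq_len(B), yd)] <- gd[cbind(seq_len(B), yd)] - 1
        gd <- gd / B
      }
      gs <- p_s
      if (any(msk))
        gs[cbind(which(msk), ys[msk])] <- gs[cbind(which(msk), ys[msk])] - 1
      gs[!msk, ] <- 0
      gs <- gs / nmask
      if (is.null(y_st)) gs <- gs * 0
      top <- fw$acts[[L + 1L]]
      grads <- list()
      grads$Wd <- crossprod(top, gd); grads$bd <- colSums(gd)
      grads$Ws <- crossprod(top, gs); grads$bs <- colSums(gs)
      delta <- gd %*% t(params$Wd) + gs %*% t(params$Ws)
      for (l in L:1) {
        h <- fw$acts[[l + 1L]]
        delta <- delta * (h > 0)
        if (config$dropout > 0 && !is.null(fw$masks[[l]]))
          delta <- delta * fw$masks[[l]] / (1 - config$dropout)
        grads[[paste0("W", l)]] <- crossprod(fw$acts[[l]], delta)
        grads[[paste0("b", l)]] <- colSums(delta)
        if (l > 1L) delta <- delta %*% t(params[[paste0("W", l)]])
      }
      t_step <- t_step + 1
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (nm in pnames) {
        g <- grads[[nm]]
        if (config$l2 > 0 && startsWith(nm, "W"))
          g <- g + config$l2 * params[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        params[[nm]] <- params[[nm]] -
          lr * corr * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
      }
    }
    row <- data.frame(epoch = epoch, train_loss = tot_loss / n)
    if (!is.null(val_fn)) {
      m <- val_fn(params)
      row$val_top1_dR <- m$top1_dR
      row$val_top1_state <- m$top1_state
    }
    log_rows[[epoch]] <- row
    if (config$verbose)
      message(sprintf("epoch %d: loss %.4f", epoch, tot_loss / n))
  }
  list(params = params, log = do.call(rbind, log_rows))
}

dnn_model_obj <- function(params, schema, scaler, keep, realized, horizon,
                          config, seed, log) {
  structure(list(params = params, schema = schema, scaler = scaler,
                 keep_columns = keep, realized_states = realized,
                 n_states = schema$n_states, horizon = horizon,
                 config = config, seed = seed, log = log),
            class = "dnn_model")
}

#' @export
print.dnn_model <- function(x, ...) {
  cat("<dnn_model> trunk", paste(x$config$hidden, collapse = "-"),
      "|", length(x$keep_columns), "features |",
      length(x$realized_states), "realized target states\n")
  invisible(x)
}

#' @export
predict.dnn_model <- function(object, context, climate, ...) {
  X <- build_features(context, climate, object$schema,
                      object$scaler)[, object$keep_columns, drop = FALSE]
  if (object$config$two_networks) {
    p_dR <- softmax_rows(mlp_forward(object$params$dR, X)$logits_dR)
    p_sub <- softmax_rows(mlp_forward(object$params$state, X)$logits_state)
  } else {
    fw <- mlp_forward(object$params, X)
    p_dR <- softmax_rows(fw$logits_dR)
    p_sub <- softmax_rows(fw$logits_state)
  }
  p_state <- matrix(0, nrow(X), object$n_states)
  p_state[, object$realized_states + 1L] <- p_sub
  list(p_dR = p_dR, p_state = p_state)
}
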