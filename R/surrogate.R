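# ---- cross-validation report -----------------------------------------------

r2_score <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Cross-validation report
#'
#' Per-target coefficient of determination, predictive squared correlation
#' Q^2 = 1 - PRESS/TSS computed from held-out (e.g. leave-one-out)
#' predictions, and relative RMSE (RMSE divided by the observed range, in
#' percent).
#'
#' @param predictions,observations Matrices (or vectors) of equal shape;
#'   predictions must come from held-out folds for `q2` to be predictive.
#' @return List with per-target metrics (`r2_per_target`,
#'   `rmse_relative_per_target` in %, and their means) and the pooled
#'   headline numbers `q2` and `rmse_relative`: residuals pooled over all
#'   targets after per-target centring, so one predictive-performance number
#'   summarises a multi-output model without letting a narrow-range target
#'   dominate the average.
#' @export
cv_report <- function(predictions, observations) {
  pred <- as.matrix(predictions); obs <- as.matrix(observations)
  if (!all(dim(pred) == dim(obs))) stop("prediction/observation shape mismatch")
  tgt <- colnames(obs)
  if (is.null(tgt)) tgt <- paste0("target", seq_len(ncol(obs)))
  per <- function(fun) stats::setNames(vapply(seq_len(ncol(obs)), function(j) {
    if (diff(range(obs[, j])) == 0) stop("zero observed range in target ", j)
    fun(obs[, j], pred[, j])
  }, numeric(1)), tgt)
  q2_t <- per(r2_score)
  rmse_rel_t <- per(function(o, p)
    100 * sqrt(mean((o - p)^2)) / diff(range(o)))
  cobs <- sweep(obs, 2, colMeans(obs))
  resid <- obs - pred
  q2_pool <- 1 - sum(resid^2) / sum(cobs^2)
  rmse_pool <- 100 * sqrt(mean(resid^2)) / diff(range(obs))
  list(r2_per_target = q2_t, q2_mean = mean(q2_t),
       rmse_relative_per_target = rmse_rel_t,
       rmse_relative_mean = mean(rmse_rel_t),
       q2 = q2_pool, rmse_relative = rmse_pool)
}

# ---- growth surrogate (support-vector regression) ---------------------------

svm_loo <- function(x, y, kernel, cost) {
  vapply(seq_len(nrow(x)), function(i) {
    fit <- e1071::svm(x = x[-i, , drop = FALSE], y = y[-i], kernel = kernel,
                      cost = cost, scale = FALSE)
    as.numeric(stats::predict(fit, x[i, , drop = FALSE]))
  }, numeric(1))
}

#' Train the growth-parameter surrogate
#'
#' One support-vector regressor per growth target (by default log a1 and
#' log t1), mapping the standardized context encoding to the fitted growth
#' parameters. The kernel family (linear or radial basis) and the
#' regularisation constant C are selected by leave-one-out R^2 on the
#' training set; the report carries the per-target LOO R^2 under the chosen
#' hyperparameters.
#'
#' @param x Encoded (unstandardized) context matrix, one row per training
#'   context.
#' @param targets Matrix of targets (one column per growth parameter).
#' @param seed Integer seed.
#' @param kernels,costs Hyperparameter grid.
#' @return List with `models`, `scaler`, `hyper`, `report` (a [cv_report()])
#'   and `loo_predictions`.
#' @export
train_growth_surrogate <- function(x, targets, seed = 1,
                                   kernels = c("linear", "radial"),
                                   costs = c(0.1, 1, 10, 100)) {
  targets <- as.matrix(targets)
  if (nrow(x) < 14) stop("need >= 14 training rows")
  if (any(apply(targets, 2, function(t) diff(range(t)) == 0)))
    stop("degenerate (constant) target")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  with_seed(seed, {
    models <- list(); hyper <- list()
    loo_pred <- matrix(NA_real_, nrow(xs), ncol(targets),
                       dimnames = dimnames(targets))
    for (j in seq_len(ncol(targets))) {
      y <- targets[, j]
      grid <- expand.grid(kernel = kernels, cost = costs,
                          stringsAsFactors = FALSE)
      scores <- vapply(seq_len(nrow(grid)), function(g) {
        r2_score(y, svm_loo(xs, y, grid$kernel[g], grid$cost[g]))
      }, numeric(1))
      bestg <- which.max(scores)
      loo_pred[, j] <- svm_loo(xs, y, grid$kernel[bestg], grid$cost[bestg])
      models[[j]] <- e1071::svm(x = xs, y = y, kernel = grid$kernel[bestg],
                                cost = grid$cost[bestg], scale = FALSE)
      hyper[[j]] <- grid[bestg, ]
    }
    names(models) <- colnames(targets)
    list(models = models, scaler = scaler, hyper = hyper,
         report = cv_report(loo_pred, targets), loo_predictions = loo_pred)
  })
}

#' @rdname train_growth_surrogate
#' @param surrogate A trained growth surrogate.
#' @param x_new Encoded context matrix to predict.
#' @export
predict_growth_surrogate <- function(surrogate, x_new) {
  xs <- apply_scaler(x_new, surrogate$scaler)
  out <- vapply(surrogate$models, function(m)
    as.numeric(stats::predict(m, xs)), numeric(nrow(xs)))
  matrix(out, nrow = nrow(xs), dimnames = list(NULL, names(surrogate$models)))
}

# ---- reporter surrogate (feed-forward network) ------------------------------

#' Assemble the reporter-surrogate training set from bagged ensembles
#'
#' Each bagging member of each context contributes one training sample:
#' input = the context encoding, output = the member's context-scoped
#' kinetic parameters on the log scale. Global parameters are taken from the
#' calibration stage, not predicted.
#'
#' @param ensembles Named list (by context_id) of member matrices
#'   (iterations x parameters) or `ensemble_fit` objects.
#' @param design Data.frame of the corresponding contexts, with
#'   `context_id`.
#' @param pe Promoter encoding.
#' @param space A [factor_space()].
#' @return List with `x` (features) and `y` (log-parameter targets), plus
#'   `context_of_row`.
#' @export
reporter_training_set <- function(ensembles, design, pe, space = factor_space()) {
  xs <- list(); ys <- list(); ctx_rows <- list()
  for (cid in names(ensembles)) {
    ens <- ensembles[[cid]]
    mat <- if (inherits(ens, "ensemble_fit")) ens$matrix else as.matrix(ens)
    row <- design[design$context_id == cid, , drop = FALSE]
    if (nrow(row) < 1L) stop("context ", cid, " not in design")
    row <- row[1, , drop = FALSE]       # replicated runs share one encoding
    enc <- encode_contexts(row, pe, space)
    xs[[cid]] <- enc[rep(1, nrow(mat)), , drop = FALSE]
    ys[[cid]] <- log(mat)
    ctx_rows[[cid]] <- rep(cid, nrow(mat))
  }
  list(x = do.call(rbind, xs), y = do.call(rbind, ys),
       context_of_row = unlist(ctx_rows, use.names = FALSE))
}

#' Train the reporter-parameter surrogate network
#'
#' A feed-forward network with four hidden layers (default widths
#' 64-64-32-16), batch normalization, rectified activations and dropout,
#' mapping the standardized context encoding to the context-scoped reporter
#' parameters (log scale). Each bagging member is one training sample, so
#' the network sees the calibration uncertainty directly. Training is by
#' Adam on mean-squared error with a seeded initialisation and batch order,
#' hence reproducible.
#'
#' @param x Encoded (unstandardized) feature matrix, one row per sample.
#' @param y Target matrix (log parameters), one row per sample.
#' @param seed Integer seed.
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout probability.
#' @param epochs,batch,lr Training schedule.
#' @param n_networks Number of independently initialised networks whose
#'   predictions are averaged (a small deep ensemble; reduces the variance
#'   of the fit at linear cost in training time).
#' @return List with the fitted `nets`, `x_scaler`, `y_scaler`, `targets`.
#' @export
train_reporter_surrogate <- function(x, y, seed = 1,
                                     hidden = c(64, 64, 32, 16),
                                     dropout = 0.03, epochs = 500,
                                     batch = 64, lr = 3e-3, n_networks = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("feature/target row mismatch")
  x_scaler <- fit_scaler(x); y_scaler <- fit_scaler(y)
  xs <- apply_scaler(x, x_scaler); ys <- apply_scaler(y, y_scaler)
  nets <- lapply(seq_len(n_networks), function(j)
    mlp_train(xs, ys, hidden = hidden, dropout = dropout, epochs = epochs,
              batch = batch, lr = lr, seed = child_seed(seed, j)))
  list(net = nets[[1]], nets = nets, x_scaler = x_scaler,
       y_scaler = y_scaler, targets = colnames(y))
}

#' @rdname train_reporter_surrogate
#' @param surrogate A trained reporter surrogate.
#' @param x_new Encoded context matrix.
#' @return Matrix of predicted log parameters (original target scale).
#' @export
predict_reporter_surrogate <- function(surrogate, x_new) {
  xs <- apply_scaler(as.matrix(x_new), surrogate$x_scaler)
  nets <- if (is.null(surrogate$nets)) list(surrogate$net) else surrogate$nets
  zs <- Reduce(`+`, lapply(nets, mlp_predict, x = xs)) / length(nets)
  out <- sweep(sweep(zs, 2, surrogate$y_scaler$sd, "*"), 2,
               surrogate$y_scaler$mean, "+")
  colnames(out) <- surrogate$targets
  out
}

# ---- end-to-end prediction --------------------------------------------------

#' Predict the dynamic response of an arbitrary context
#'
#' Composes the two surrogates with the mechanistic model: the growth
#' surrogate supplies (a1, t1) — the remaining growth parameters come from
#' the calibration stage aggregates carried in `growth_aux` — the reporter
#' surrogate supplies the context-scoped kinetic parameters, and the ODE
#' model turns them into a trajectory. This is the prediction used for
#' design selection; it works for every key of the factor space, trained or
#' not.
#'
#' @param ctx Context (named vector) or one-row data.frame.
#' @param growth_model Trained [train_growth_surrogate()] bundle.
#' @param reporter_model Trained [train_reporter_surrogate()] bundle.
#' @param pe Promoter encoding used at training time.
#' @param growth_aux Named list with `L1`, `k1`, `k2` (training aggregates).
#' @param globals Named list/vector of the global kinetic parameters from
#'   calibration.
#' @param times Sampling grid (h).
#' @param space A [factor_space()].
#' @return A `biosensor_trajectory`.
#' @export
predict_response <- function(ctx, growth_model, reporter_model, pe,
                             growth_aux, globals, times = default_grid(),
                             space = factor_space()) {
  if (is.data.frame(ctx)) ctx <- unlist(ctx[1, c("medium", "supplement",
                                                 "promoter", "rbs")])
  enc <- encode_contexts(as.data.frame(as.list(ctx)), pe, space)
  gpred <- predict_growth_surrogate(growth_model, enc)
  gp <- growth_params(L1 = growth_aux$L1, a1 = exp(gpred[1, "log_a1"]),
                      t1 = exp(gpred[1, "log_t1"]),
                      k1 = growth_aux$k1, k2 = growth_aux$k2)
  kpred <- exp(predict_reporter_surrogate(reporter_model, enc))[1, ]
  kp <- kinetic_params(
    vmax_PROM = globals$vmax_PROM,
    K_Pk = kpred[["K_Pk"]], K_mRNAp = kpred[["K_mRNAp"]],
    k_deg = globals$k_deg, K_mRNAdeg = kpred[["K_mRNAdeg"]],
    K_P = kpred[["K_P"]], K_lysis = kpred[["K_lysis"]],
    RBS_strength = kpred[["RBS_strength"]],
    k_FDER = globals$k_FDER, K_NFDER = globals$K_NFDER,
    k_deg_FDER = globals$k_deg_FDER, vmax_NAR = globals$vmax_NAR,
    k_deg_GFP = globals$k_deg_GFP, R_basal = globals$R_basal)
  simulate_biosensor(gp, kp, times = times, ctx = ctx)
}
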