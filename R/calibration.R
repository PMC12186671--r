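# ---- weights ----------------------------------------------------------------

#' Inverse-variance weights for heteroscedastic residuals
#'
#' Diagonal weights `1 / max(s_t^2, floor)` per output and time point, with
#' `s_t` the replicate standard deviation and the floor set to
#' `(1e-3 x signal range)^2` so that identical replicates (or noise-free
#' synthetic data) yield finite uniform weights.
#'
#' @param exp An `experiment_time_course`.
#' @param smooth With few replicates the raw per-point variance has only
#'   `n - 1` degrees of freedom and its reciprocal is wildly unstable, which
#'   degrades the fit it is meant to help; `smooth = TRUE` instead pools
#'   information across time points by regressing the replicate variance on
#'   the squared mean signal (an additive + proportional error model) and
#'   weighting by the fitted variance. The raw per-point form is the
#'   default.
#' @return List with numeric weight vectors `od` and `gfp` (one per time
#'   point).
#' @export
estimate_weights <- function(exp, smooth = FALSE) {
  if (ncol(exp$od) < 2L || ncol(exp$gfp) < 2L)
    warning("single replicate: using uniform weights")
  one <- function(m) {
    if (ncol(m) < 2L) return(rep(1, nrow(m)))
    s2 <- apply(m, 1, stats::var)
    ym <- rowMeans(m)
    floor_ <- (1e-3 * diff(range(ym)))^2
    if (smooth) {
      cf <- stats::coef(stats::lm(s2 ~ I(ym^2)))
      s2 <- pmax(cf[1], floor_) + max(cf[2], 0) * ym^2
      w <- 1 / pmax(s2, floor_)
      # cap the precision: a fitted-variance error at a handful of
      # low-variance points must not dominate the whole fit
      return(pmin(w, 5 * stats::median(w)))
    }
    1 / pmax(s2, floor_)
  }
  list(od = one(exp$od), gfp = one(exp$gfp))
}

# ---- fit problem ------------------------------------------------------------

# Scoped free-parameter names: a bare name ("vmax_NAR") applies to every
# context; "K_mRNAp.M2" only to contexts in medium M2; "K_Pk.P3" only to
# promoter P3; "RBS_strength.M0_S1_P2_R4" only to that exact context.
parse_free_name <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  list(base = parts[1],
       scope = if (length(parts) > 1) paste(parts[-1], collapse = ".") else NA)
}

applies_to <- function(spec, ctx) {
  if (is.na(spec$scope)) return(TRUE)
  spec$scope %in% c(ctx[["medium"]], ctx[["promoter"]], context_id(ctx))
}

#' Define a weighted least-squares calibration problem
#'
#' Bundles one or more replicated experiments with the set of kinetic
#' parameters to estimate, their box bounds, per-experiment growth parameters
#' (fitted beforehand from the OD channel, see [fit_growth()]), baseline
#' kinetic parameter sets holding everything not estimated, and
#' inverse-variance weights. Parameters are named with their scope
#' (`"vmax_NAR"` global, `"K_mRNAp.M2"` medium-scoped, `"K_Pk.P3"`
#' promoter-scoped, `"RBS_strength.<context_id>"` context-scoped), so joint
#' fits share values exactly according to the model's variability structure.
#'
#' @param experiments List of `experiment_time_course` objects.
#' @param free Character vector of scoped parameter names to estimate.
#' @param lower,upper Named (or scalar) bounds for `free`; estimation is
#'   box-constrained and non-negative.
#' @param growth List of [growth_params()], one per experiment.
#' @param kinetics List of [kinetic_params()] baselines, one per experiment;
#'   entries named in `free` are overwritten during fitting.
#' @param weights Optional list of weight lists (default: smoothed
#'   [estimate_weights()] per experiment — the raw 2-df per-point weights
#'   let a handful of low-variance points dominate the cost).
#' @param outputs Which channels enter the cost: `"gfp"` (default; OD does
#'   not depend on the kinetic parameters) or `c("od", "gfp")`.
#' @param start Optional named start vector used to seed the optimiser.
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(experiments, free, lower = 1e-4, upper = 1e3,
                        growth, kinetics, weights = NULL,
                        outputs = "gfp", start = NULL) {
  if (inherits(experiments, "experiment_time_course"))
    experiments <- list(experiments)
  if (inherits(growth, "growth_params")) growth <- list(growth)
  if (inherits(kinetics, "kinetic_params")) kinetics <- list(kinetics)
  stopifnot(length(growth) == length(experiments),
            length(kinetics) == length(experiments))
  expand <- function(b) {
    if (length(b) == 1L) b <- rep(b, length(free))
    stats::setNames(as.numeric(b), free)
  }
  lower <- expand(lower); upper <- expand(upper)
  if (any(lower > upper) || any(lower < 0))
    stop("bounds must satisfy 0 <= lower <= upper")
  if (is.null(weights))
    weights <- lapply(experiments, estimate_weights, smooth = TRUE)
  specs <- lapply(free, parse_free_name)
  names(specs) <- free
  structure(list(experiments = experiments, free = free, specs = specs,
                 lower = lower, upper = upper, growth = growth,
                 kinetics = kinetics, weights = weights, outputs = outputs,
                 start = start),
            class = "fit_problem")
}

# kinetic_params for experiment i under parameter vector k
problem_kinetics <- function(problem, k, i) {
  ctx <- problem$experiments[[i]]$context
  kp <- problem$kinetics[[i]]
  for (nm in names(k)) {
    spec <- problem$specs[[nm]]
    if (applies_to(spec, ctx)) kp[[spec$base]] <- unname(k[[nm]])
  }
  do.call(kinetic_params, unclass(kp))
}

#' Weighted least-squares cost of a parameter vector
#'
#' Discrete-sum approximation of the weighted integral squared error between
#' replicate-mean measurements and the model response: the squared residual
#' at each sampling point, scaled by its inverse-variance weight, summed over
#' time points, outputs and experiments. Measurements sit exactly on the
#' 10-min grid, so the sum is taken over the grid itself.
#'
#' @param k Named parameter vector (natural scale) within the problem bounds.
#' @param problem A [fit_problem()].
#' @return Non-negative cost; `+Inf` if the simulation fails at `k`.
#' @export
weighted_cost <- function(k, problem) {
  k <- stats::setNames(as.numeric(k), problem$free)
  total <- 0
  for (i in seq_along(problem$experiments)) {
    exp_i <- problem$experiments[[i]]
    kp <- problem_kinetics(problem, k, i)
    traj <- tryCatch(
      simulate_biosensor(problem$growth[[i]], kp, times = exp_i$times,
                         ctx = exp_i$context),
      error = function(e) NULL)
    if (is.null(traj)) {
      message("simulation failed during cost evaluation; cost set to +Inf")
      return(Inf)
    }
    if ("gfp" %in% problem$outputs)
      total <- total + sum(problem$weights[[i]]$gfp *
                             (rowMeans(exp_i$gfp) - traj$gfp_per_od)^2)
    if ("od" %in% problem$outputs)
      total <- total + sum(problem$weights[[i]]$od *
                             (rowMeans(exp_i$od) - traj$od)^2)
  }
  total
}

# ---- growth fitting ---------------------------------------------------------

growth_cost <- function(par, tt, y, w) {
  gp <- list(L1 = par[1], a1 = par[2], t1 = par[3], k1 = par[4], k2 = par[5])
  s1 <- plogis(gp$a1 * (tt - gp$t1))
  s2 <- plogis((gp$k1 * gp$a1) * (tt - gp$k2 * gp$t1))
  sum(w * (y - (gp$L1 * s1 + gp$k1 * s2))^2)
}

#' Fit the double-logistic growth law to an OD time course
#'
#' Weighted least squares on the replicate-mean OD with multistart local
#' search: a data-driven heuristic start (asymptote from the maximum OD,
#' midpoint from the half-maximum crossing, rate from the steepest log-slope)
#' plus seeded random perturbations, each polished by box-constrained
#' L-BFGS-B. Fits all five parameters `(L1, a1, t1, k1, k2)` for a single
#' experiment; use [fit_growth_joint()] to share `(k1, k2)` across contexts.
#'
#' @param exp An `experiment_time_course` (only the OD channel is used).
#' @param n_starts Number of multistarts (>= 20 by default).
#' @param seed Integer seed for the start perturbations.
#' @param bounds Optional list with `lower`/`upper` vectors over
#'   `(L1, a1, t1, k1, k2)`.
#' @return List with `growth` (a [growth_params()]) and `fit` (a list with
#'   `k_hat`, `cost`, `converged`, `n_evals`).
#' @export
fit_growth <- function(exp, n_starts = 20, seed = 1, bounds = NULL) {
  tt <- exp$times
  y <- rowMeans(exp$od)
  if (diff(range(y)) < 1e-8 * max(abs(y), 1))
    stop("degenerate growth curve: OD signal is flat")
  w <- estimate_weights(exp, smooth = TRUE)$od

  ymax <- max(y)
  t_half <- tt[which(y >= (min(y) + ymax) / 2)[1]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(tt)
  slope <- max(diff(y) / diff(tt))
  a1_0 <- max(4 * slope / ymax, 0.1)
  start0 <- c(L1 = ymax, a1 = a1_0, t1 = t_half, k1 = 0.05 * ymax, k2 = 1.2)

  if (is.null(bounds))
    bounds <- list(lower = c(0.2 * ymax, 0.02, 0.2, 0, 0.3),
                   upper = c(3 * ymax, 10, 2 * max(tt), ymax, 4))

  with_seed(seed, {
    starts <- list(start0)
    for (s in seq_len(max(n_starts, 1) - 1)) {
      pert <- start0 * exp(rnorm(5, 0, 0.4))
      starts[[s + 1]] <- pmin(pmax(pert, bounds$lower), bounds$upper)
    }
    best <- NULL
    evals <- 0L
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, growth_cost, tt = tt, y = y, w = w,
                     method = "L-BFGS-B", lower = bounds$lower,
                     upper = bounds$upper,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(fit)) next
      evals <- evals + fit$counts[1]
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("growth fit failed from every start")
    gp <- growth_params(best$par[1], best$par[2], best$par[3],
                        k1 = best$par[4], k2 = best$par[5])
    list(growth = gp,
         fit = list(k_hat = stats::setNames(best$par,
                                            c("L1", "a1", "t1", "k1", "k2")),
                    cost = best$value, converged = best$convergence == 0,
                    n_evals = unname(evals)))
  })
}

#' Jointly fit growth curves with shared second-phase coefficients
#'
#' Stage 1 fits every experiment independently; stage 2 pins `(k1, k2)` to
#' their across-context medians and refits the context-dependent
#' `(L1, a1, t1)` per experiment with the shared pair held fixed.
#'
#' @param experiments List of `experiment_time_course` objects.
#' @inheritParams fit_growth
#' @return List with `growth` (list of [growth_params()]), `k1`, `k2`.
#' @export
fit_growth_joint <- function(experiments, n_starts = 20, seed = 1) {
  singles <- lapply(seq_along(experiments), function(i)
    fit_growth(experiments[[i]], n_starts = n_starts,
               seed = child_seed(seed, i)))
  k1 <- stats::median(vapply(singles, function(s) s$fit$k_hat[["k1"]],
                             numeric(1)))
  k2 <- stats::median(vapply(singles, function(s) s$fit$k_hat[["k2"]],
                             numeric(1)))
  refits <- lapply(seq_along(experiments), function(i) {
    exp_i <- experiments[[i]]
    tt <- exp_i$times; y <- rowMeans(exp_i$od)
    w <- estimate_weights(exp_i, smooth = TRUE)$od
    st <- singles[[i]]$fit$k_hat[c("L1", "a1", "t1")]
    fit <- stats::optim(st, function(p)
      growth_cost(c(p, k1, k2), tt, y, w),
      method = "L-BFGS-B",
      lower = c(1e-3, 0.02, 0.2), upper = c(3 * max(y), 10, 2 * max(tt)),
      control = list(maxit = 500, factr = 1e4))
    growth_params(fit$par[1], fit$par[2], fit$par[3], k1 = k1, k2 = k2)
  })
  list(growth = refits, k1 = k1, k2 = k2)
}

# ---- hybrid global/local calibration ---------------------------------------

#' Calibrate kinetic parameters by hybrid global/local optimisation
#'
#' Minimises [weighted_cost()] over the problem's free parameters with a
#' seeded differential-evolution global stage (rand/1/bin, log-scale
#' parameterisation because the rates span orders of magnitude) followed by
#' Nelder-Mead and L-BFGS-B polishing of the best member. Deterministic
#' given the seed.
#'
#' @param problem A [fit_problem()].
#' @param seed Integer seed.
#' @param budget Approximate cap on objective evaluations in the global
#'   stage.
#' @param pop_size Differential-evolution population size.
#' @return A `fit_result` list: `k_hat` (named, natural scale, within
#'   bounds), `cost`, `converged`, `n_evals`.
#' @export
calibrate <- function(problem, seed = 1, budget = 3000, pop_size = 20) {
  free <- problem$free
  d <- length(free)
  lo <- log(pmax(problem$lower, 1e-12))
  hi <- log(pmax(problem$upper, 1e-12))
  point_bounds <- all(problem$upper - problem$lower <= 0)

  if (point_bounds) {
    k <- problem$lower
    return(list(k_hat = k, cost = weighted_cost(k, problem),
                converged = TRUE, n_evals = 1L))
  }

  counter <- new.env()
  counter$evals <- 0L
  obj <- function(logk) {
    counter$evals <- counter$evals + 1L
    weighted_cost(exp(logk), problem)
  }

  with_seed(seed, {
    # initial population: uniform in log space, plus the start point
    pop <- t(vapply(seq_len(pop_size), function(i)
      lo + runif(d) * (hi - lo), numeric(d)))
    if (!is.null(problem$start)) {
      st <- log(pmin(pmax(problem$start[free], problem$lower), problem$upper))
      pop[1, ] <- st
    }
    cost <- apply(pop, 1, obj)
    n_gen <- max(1L, floor((budget - pop_size) / pop_size))
    f_w <- 0.8; cr <- 0.9
    for (g in seq_len(n_gen)) {
      for (i in seq_len(pop_size)) {
        idx <- sample(setdiff(seq_len(pop_size), i), 3)
        trial <- pop[idx[1], ] + f_w * (pop[idx[2], ] - pop[idx[3], ])
        mask <- runif(d) < cr
        mask[sample.int(d, 1)] <- TRUE
        cand <- ifelse(mask, trial, pop[i, ])
        cand <- pmin(pmax(cand, lo), hi)
        cc <- obj(cand)
        if (cc <= cost[i]) { pop[i, ] <- cand; cost[i] <- cc }
      }
    }
    best <- which.min(cost)
    # local polish: simplex to escape DE's terminal plateau, then
    # quasi-Newton; the simplex objective penalises leaving the box so the
    # polish cannot escape along a compensation ridge and be clipped back
    # onto a bad boundary point
    obj_box <- function(p) {
      viol <- sum(pmax(p - hi, 0)^2 + pmax(lo - p, 0)^2)
      obj(pmin(pmax(p, lo), hi)) * (1 + viol) + 1e3 * viol
    }
    p1 <- stats::optim(pop[best, ], obj_box, method = "Nelder-Mead",
                       control = list(maxit = 400 * d,
                                      reltol = 1e-14))
    p2 <- tryCatch(
      stats::optim(pmin(pmax(p1$par, lo), hi), obj, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    # best feasible candidate wins; never worse than the global-stage best
    cands <- list(list(par = pop[best, ], value = cost[best]),
                  list(par = pmin(pmax(p1$par, lo), hi), value = NA))
    cands[[2]]$value <- obj(cands[[2]]$par)
    if (!is.null(p2))
      cands[[3]] <- list(par = pmin(pmax(p2$par, lo), hi), value = p2$value)
    final <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
    logk <- final$par
    fcost <- final$value
    if (!is.finite(fcost))
      stop("calibration budget exhausted without a finite-cost evaluation")
    list(k_hat = stats::setNames(exp(logk), free), cost = fcost,
         converged = TRUE, n_evals = counter$evals)
  })
}

# ---- bootstrap / bagging ----------------------------------------------------

#' Bootstrap-resample the replicates of an experiment
#'
#' For each time point and each output channel independently, draws replicate
#' values uniformly with replacement, rebuilding a dataset of the same shape
#' as the original. Deterministic given the seed.
#'
#' @param exp An `experiment_time_course` with >= 2 replicates.
#' @param seed Integer seed.
#' @return A resampled `experiment_time_course`.
#' @export
bootstrap_resample <- function(exp, seed = 1) {
  nrep <- ncol(exp$od)
  if (nrep < 2L) stop("bootstrap_resample() needs >= 2 replicates")
  nt <- nrow(exp$od)
  with_seed(seed, {
    res <- exp
    pick <- function(m) {
      idx <- matrix(sample.int(nrep, nt * nrep, replace = TRUE), nt, nrep)
      out <- matrix(m[cbind(rep(seq_len(nt), nrep), as.vector(idx))], nt, nrep)
      colnames(out) <- colnames(m)
      out
    }
    res$od <- pick(exp$od)
    res$gfp <- pick(exp$gfp)
    res
  })
}

#' Bagged ensemble calibration
#'
#' Bootstrap aggregation: repeats (resample replicates -> recalibrate) for
#' `n_iterations` independent realisations of the dataset and collects every
#' fitted parameter vector. The member matrix is the training set for the
#' reporter surrogate. Members whose calibration fails are dropped with a
#' message; more than 20% failures is an error.
#'
#' @param problem A [fit_problem()].
#' @param n_iterations Number of bootstrap refits (300 in the full profile;
#'   scaled-down runs use 50).
#' @param seed Master integer seed.
#' @param budget,pop_size Per-member optimiser budget (members start from the
#'   full-data fit, so a reduced budget suffices).
#' @param start Optional named start vector (defaults to a full-data
#'   [calibrate()] run).
#' @return An `ensemble_fit`: list with `members` (list of fit results),
#'   `matrix` (iterations x parameters), `n_iterations`.
#' @export
bagging_ensemble <- function(problem, n_iterations = 300, seed = 1,
                             budget = 600, pop_size = 10, start = NULL) {
  if (is.null(start)) {
    full <- calibrate(problem, seed = child_seed(seed, 0), budget = budget * 2)
    start <- full$k_hat
  }
  members <- vector("list", n_iterations)
  failed <- 0L
  for (b in seq_len(n_iterations)) {
    s <- child_seed(seed, b)
    res_exps <- lapply(seq_along(problem$experiments), function(i)
      bootstrap_resample(problem$experiments[[i]], seed = child_seed(s, i)))
    pb <- problem
    pb$experiments <- res_exps
    pb$start <- start
    fit <- tryCatch(calibrate(pb, seed = s, budget = budget,
                              pop_size = pop_size),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      message("bagging member ", b, " failed and was dropped")
    }
    members[[b]] <- fit
  }
  if (failed > 0.2 * n_iterations)
    stop("more than 20% of bagging members failed (", failed, "/",
         n_iterations, ")")
  members <- Filter(Negate(is.null), members)
  mat <- do.call(rbind, lapply(members, function(m) m$k_hat))
  structure(list(members = members, matrix = mat,
                 n_iterations = n_iterations),
            class = "ensemble_fit")
}
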