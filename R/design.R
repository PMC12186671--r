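# ---- model matrix -----------------------------------------------------------

#' Reference-coded model matrix for a categorical design
#'
#' The assumed response model for design construction is a linear combination
#' of one-hot encoded factor levels. Reference coding (the first level of
#' each factor dropped) keeps the information matrix invertible: intercept +
#' 3 promoter + 4 RBS + 3 medium + 3 supplement columns = 14 for the default
#' space.
#'
#' @param design Data.frame of runs with columns medium, supplement,
#'   promoter, rbs.
#' @param space A [factor_space()].
#' @return Numeric 0/1 matrix, `nrow(design)` x 14.
#' @export
model_matrix <- function(design, space = factor_space()) {
  n <- nrow(design)
  cols <- list(`(Intercept)` = rep(1, n))
  for (f in names(space)) {
    levels <- space[[f]]
    vals <- design[[f]]
    bad <- which(!vals %in% levels)
    if (length(bad))
      stop("run ", bad[1], ": unknown ", f, " level '", vals[bad[1]], "'")
    for (lv in levels[-1]) cols[[paste0(f, lv)]] <- as.numeric(vals == lv)
  }
  do.call(cbind, cols)
}

#' Log-determinant of a design's information matrix
#'
#' @inheritParams model_matrix
#' @return `log det(X'X)`; `-Inf` if singular.
#' @export
design_log_det <- function(design, space = factor_space()) {
  x <- model_matrix(design, space)
  d <- determinant(crossprod(x), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

# regularised log-det used during the search so that coordinate exchange can
# climb out of singular (rank-deficient) starting designs
log_det_reg <- function(xtx, eps = 1e-8) {
  d <- determinant(xtx + diag(eps, nrow(xtx)), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

# one coordinate-exchange pass over the mutable rows; returns improved design
exchange_sweep <- function(design, space, cand, cand_x, fixed_rows = 0L) {
  x <- model_matrix(design, space)
  xtx <- crossprod(x)
  best <- log_det_reg(xtx)
  for (i in seq(fixed_rows + 1L, nrow(design))) {
    xi <- x[i, ]
    base <- xtx - tcrossprod(xi)
    # try every candidate row in place of run i
    scores <- vapply(seq_len(nrow(cand)), function(j)
      log_det_reg(base + tcrossprod(cand_x[j, ])), numeric(1))
    j <- which.max(scores)
    if (scores[j] > best + 1e-10) {
      design[i, c("medium", "supplement", "promoter", "rbs")] <-
        cand[j, c("medium", "supplement", "promoter", "rbs")]
      x[i, ] <- cand_x[j, ]
      xtx <- base + tcrossprod(cand_x[j, ])
      best <- scores[j]
    }
  }
  list(design = design, log_det = best)
}

run_exchange <- function(design, space, fixed_rows = 0L, max_sweeps = 20L) {
  cand <- full_factorial(space)
  cand_x <- model_matrix(cand, space)
  prev <- -Inf
  for (s in seq_len(max_sweeps)) {
    res <- exchange_sweep(design, space, cand, cand_x, fixed_rows)
    design <- res$design
    if (res$log_det <= prev + 1e-10) break
    prev <- res$log_det
  }
  design$context_id <- context_id(design)
  list(design = design, log_det = design_log_det(design, space))
}

#' D-optimal design over the categorical factor space
#'
#' Selects `n_runs` contexts maximising `det(X'X)` of the reference-coded
#' model matrix — the D-optimality criterion, which minimises the covariance
#' of the parameter estimates of the assumed linear model. The search is a
#' seeded coordinate exchange over the full factorial candidate set, restarted
#' from several random initial designs; the best restart is returned.
#'
#' @param space A [factor_space()].
#' @param n_runs Number of runs (>= 14, the number of model-matrix columns).
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts.
#' @param start Optional starting design (data.frame of runs); used as the
#'   first restart. When `n_runs` equals the candidate-set size the full
#'   factorial itself is the default start — exchange cannot improve on the
#'   whole candidate set.
#' @return A list with `design` (data.frame of runs with `run_id`),
#'   `log_det`, and `n_runs`.
#' @export
d_optimal <- function(space = factor_space(), n_runs = 32, seed = 1,
                      n_restarts = 4, start = NULL) {
  cand <- full_factorial(space)
  p <- ncol(model_matrix(cand[1, , drop = FALSE], space))
  if (n_runs < p)
    stop("n_runs must be >= ", p, " for estimability of the one-hot model")
  if (is.null(start) && n_runs == nrow(cand)) {
    start <- cand
    n_restarts <- 0                 # the whole candidate set is optimal
  }
  with_seed(seed, {
    best <- NULL
    starts <- c(if (!is.null(start)) list(start),
                lapply(seq_len(n_restarts), function(r) {
                  s <- cand[sample.int(nrow(cand), n_runs, replace = TRUE), ]
                  rownames(s) <- NULL
                  s
                }))
    for (st in starts) {
      res <- run_exchange(st, space)
      if (is.null(best) || res$log_det > best$log_det) best <- res
    }
    best$design$run_id <- seq_len(nrow(best$design))
    list(design = best$design, log_det = best$log_det, n_runs = n_runs)
  })
}

#' Augment an existing design with additional D-optimal runs
#'
#' Adds `n_additional` runs chosen to maximise the determinant of the
#' combined information matrix; the existing runs are immutable. Information
#' is monotone: the combined log-det never falls below the existing one.
#'
#' @param existing Design data.frame (e.g. `d_optimal()$design`).
#' @param space A [factor_space()].
#' @param n_additional Number of new runs.
#' @param seed Integer seed.
#' @return As [d_optimal()], with the first `nrow(existing)` rows unchanged.
#' @export
augment_design <- function(existing, space = factor_space(), n_additional = 32,
                           seed = 1) {
  if (n_additional == 0)
    return(list(design = existing, log_det = design_log_det(existing, space),
                n_runs = nrow(existing)))
  cand <- full_factorial(space)
  keep <- c("medium", "supplement", "promoter", "rbs")
  with_seed(seed, {
    new <- cand[sample.int(nrow(cand), n_additional, replace = TRUE), keep]
    combined <- rbind(existing[, keep], new)
    rownames(combined) <- NULL
    res <- run_exchange(combined, space, fixed_rows = nrow(existing))
    res$design$run_id <- seq_len(nrow(res$design))
    list(design = res$design, log_det = res$log_det,
         n_runs = nrow(res$design))
  })
}
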