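# ---- context encoding -------------------------------------------------------

#' Encode contexts for the surrogate models
#'
#' Each context becomes an 11-dimensional feature vector: one quantitative
#' promoter value (a learned scalar strength per promoter, see
#' [optimize_promoter_encoding()]) followed by one-hot blocks for RBS,
#' medium and supplement under reference coding (first level dropped for
#' medium and supplement; all RBS levels kept minus the reference gives 4
#' columns). Distinct contexts always map to distinct vectors.
#'
#' @param design Data.frame of contexts (columns medium, supplement,
#'   promoter, rbs) or a single named context vector.
#' @param pe Named numeric promoter encoding (one scalar per promoter
#'   level).
#' @param space A [factor_space()].
#' @return Numeric matrix, one row per context, 11 columns.
#' @export
encode_contexts <- function(design, pe = default_promoter_encoding(),
                            space = factor_space()) {
  if (!is.data.frame(design))
    design <- as.data.frame(as.list(design), stringsAsFactors = FALSE)
  if (any(!design$promoter %in% names(pe)))
    stop("unknown promoter level in encoding")
  onehot <- function(vals, levels, prefix) {
    bad <- which(!vals %in% levels)
    if (length(bad))
      stop("unknown ", prefix, " level '", vals[bad[1]], "'")
    m <- vapply(levels[-1], function(lv) as.numeric(vals == lv),
                numeric(length(vals)))
    m <- matrix(m, nrow = length(vals),
                dimnames = list(NULL, paste0(prefix, levels[-1])))
    m
  }
  cbind(promoter_value = unname(pe[design$promoter]),
        onehot(design$rbs, space$rbs, "rbs"),
        onehot(design$medium, space$medium, "medium"),
        onehot(design$supplement, space$supplement, "supplement"))
}

#' @rdname encode_contexts
#' @export
default_promoter_encoding <- function(space = factor_space()) {
  stats::setNames(seq(0, 1, length.out = length(space$promoter)),
                  space$promoter)
}

#' Feature standardisation
#'
#' Zero-mean unit-variance scaling fitted on the training matrix only; the
#' fitted means and standard deviations travel with the model so unseen
#' contexts are scaled identically. Constant columns (a level absent from
#' the training set) keep unit scale.
#'
#' @param x Training feature matrix.
#' @return A `feature_scaler` (list with `mean`, `sd`).
#' @export
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

# ---- promoter-encoding optimisation -----------------------------------------

# LOO R^2 of a fixed-hyperparameter kernel regressor; the inner score used
# while searching over promoter encodings. A linear kernel is used here on
# purpose: a flexible kernel can fit any assignment of distinct scalars to
# promoters, which leaves the ordering of the encoding unidentified, whereas
# a linear response rewards encodings monotone in the promoter effect.
loo_score <- function(x, y, cost = 10) {
  n <- nrow(x)
  preds <- vapply(seq_len(n), function(i) {
    fit <- e1071::svm(x = x[-i, , drop = FALSE], y = y[-i], cost = cost,
                      kernel = "linear", scale = FALSE)
    as.numeric(stats::predict(fit, x[i, , drop = FALSE]))
  }, numeric(1))
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

#' Learn quantitative promoter values by model-based optimisation
#'
#' Searches the four promoter scalars over `[0, 1]^4` for the encoding that
#' maximises the leave-one-out R^2 of the growth-parameter regressor, using
#' sequential model-based (Bayesian) optimisation: a Latin-hypercube initial
#' design, a Gaussian-process surrogate of the score surface
#' ([kernlab::gausspr()]), and an upper-confidence acquisition over sampled
#' candidates. Because any order-reversing relabelling of the scalars leaves
#' the regressor's performance unchanged, the returned encoding is
#' canonicalised to correlate positively with the per-promoter mean of the
#' first target, which makes the learned ordering identifiable.
#'
#' @param design Training contexts (data.frame).
#' @param targets Numeric matrix of regression targets (e.g. log a1, log t1),
#'   one row per context.
#' @param seed Integer seed.
#' @param budget Total score evaluations (>= 10).
#' @param space A [factor_space()].
#' @return List with `encoding` (named scalar per promoter), `score` (best
#'   LOO R^2 found) and `history` (evaluated encodings and scores).
#' @export
optimize_promoter_encoding <- function(design, targets, seed = 1, budget = 40,
                                       space = factor_space()) {
  if (budget < 10) stop("budget must allow at least 10 evaluations")
  targets <- as.matrix(targets)
  if (length(unique(design$promoter)) < 2)
    stop("need >= 2 promoter levels in the training data")
  np <- length(space$promoter)

  score_of <- function(pe_vec) {
    pe <- stats::setNames(pe_vec, space$promoter)
    x <- encode_contexts(design, pe, space)
    x <- apply_scaler(x, fit_scaler(x))
    mean(vapply(seq_len(ncol(targets)), function(j)
      loo_score(x, targets[, j]), numeric(1)))
  }

  with_seed(seed, {
    n0 <- min(max(10, budget %/% 3), budget)
    pts <- lhs::maximinLHS(n0, np)
    # data-driven candidates: each target's per-promoter mean rescaled to
    # [0,1] is an encoding that separates promoters by their average effect
    for (j in seq_len(min(ncol(targets), np))) {
      pm <- tapply(targets[, j], factor(design$promoter, space$promoter),
                   mean)
      if (any(is.na(pm)) || diff(range(pm)) == 0) next
      pts <- rbind(pts, (pm - min(pm)) / diff(range(pm)))
    }
    pts <- pts[seq_len(min(nrow(pts), budget)), , drop = FALSE]
    scores <- apply(pts, 1, score_of)
    while (nrow(pts) < budget) {
      gp_fit <- tryCatch({
        fit <- NULL
        utils::capture.output(
          fit <- kernlab::gausspr(x = pts, y = scores,
                                  variance.model = TRUE))
        fit
      }, error = function(e) NULL)
      cand <- matrix(runif(500 * np), ncol = np)
      if (is.null(gp_fit)) {
        nxt <- cand[1, ]
      } else {
        mu <- as.numeric(kernlab::predict(gp_fit, cand, type = "response"))
        sdv <- tryCatch(
          as.numeric(kernlab::predict(gp_fit, cand, type = "sdeviation")),
          error = function(e) rep(0, nrow(cand)))
        nxt <- cand[which.max(mu + 0.5 * sdv), ]
      }
      pts <- rbind(pts, nxt)
      scores <- c(scores, score_of(nxt))
    }
    best <- which.max(scores)
    pe <- stats::setNames(pts[best, ], space$promoter)
    # canonical orientation: align with the per-promoter mean response
    pm <- tapply(targets[, 1], design$promoter, mean)
    common <- intersect(names(pe), names(pm))
    if (length(common) >= 2 &&
        stats::cor(pe[common], pm[common]) < 0)
      pe <- max(pe) + min(pe) - pe
    list(encoding = pe, score = scores[best],
         history = list(points = pts, scores = scores))
  })
}
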