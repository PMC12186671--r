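# ---- ranking ----------------------------------------------------------------

#' Rank candidate designs by predicted response
#'
#' Computes the chosen response summary for every predicted trajectory and
#' returns the top-k table: gain ([steady_state_gain()], ranked descending)
#' or half-time ([half_time()], ranked ascending). Candidates whose summary
#' cannot be computed (e.g. no response) are excluded with a message. Ties
#' share the minimum rank of their group; the row order within ties is the
#' lexicographic context order.
#'
#' @param predictions Named list of trajectories (names are context ids), or
#'   a named numeric vector of precomputed criterion values.
#' @param criterion `"gain"` or `"half_time"`.
#' @param k Number of rows to keep (the full ranking is returned if `k`
#'   exceeds the candidate count).
#' @param observed Optional named numeric vector of observed criterion
#'   values over the full comparison set; adds observed values and observed
#'   ranks (computed within the full set, so they may exceed `k`).
#' @return A `ranked_table` data.frame with columns `context_id`,
#'   `predicted`, `predicted_rank` and, when `observed` is given, `observed`
#'   and `observed_rank`.
#' @export
rank_candidates <- function(predictions, criterion = c("gain", "half_time"),
                            k = 10, observed = NULL) {
  criterion <- match.arg(criterion)
  fun <- if (criterion == "gain") steady_state_gain else half_time
  if (is.numeric(predictions)) {
    vals <- predictions
  } else {
    vals <- vapply(names(predictions), function(cid) {
      tryCatch(fun(predictions[[cid]]), error = function(e) {
        message("candidate ", cid, " excluded: ", conditionMessage(e))
        NA_real_
      })
    }, numeric(1))
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) stop("no rankable candidates")
  sgn <- if (criterion == "gain") -1 else 1
  ord <- order(sgn * vals, names(vals))        # lexicographic tie-break
  vals <- vals[ord]
  tab <- data.frame(context_id = names(vals), predicted = unname(vals),
                    predicted_rank = rank(sgn * vals, ties.method = "min"),
                    stringsAsFactors = FALSE)
  if (!is.null(observed)) {
    if (any(!tab$context_id %in% names(observed)))
      stop("missing observed value for ",
           setdiff(tab$context_id, names(observed))[1])
    obs_rank <- rank(sgn * observed, ties.method = "min")
    tab$observed <- unname(observed[tab$context_id])
    tab$observed_rank <- unname(obs_rank[tab$context_id])
  }
  tab <- utils::head(tab, k)
  class(tab) <- c("ranked_table", "data.frame")
  tab
}

#' Top-k overlap between predicted and observed rankings
#'
#' The number of designs among the predicted top-k whose observed rank in
#' the full comparison set is also at most k — the headline figure of merit
#' for a screening model.
#'
#' @param ranked A `ranked_table` (or data.frame) with an `observed_rank`
#'   column.
#' @param k Cutoff.
#' @return Integer in `[0, k]`.
#' @export
top_k_overlap <- function(ranked, k = 10) {
  top <- utils::head(ranked, k)
  if (is.null(top$observed_rank) || any(is.na(top$observed_rank)))
    stop("observed ranks missing")
  sum(top$observed_rank <= k)
}

# ---- Kendall rank correlation, one-tailed -----------------------------------

# concordant-discordant statistic S = C - D and tie counts via pairwise scan
kendall_counts <- function(x, y) {
  n <- length(x)
  s <- 0; tx_pairs <- 0; ty_pairs <- 0
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    s <- s + sum(sign(dx) * sign(dy))
    tx_pairs <- tx_pairs + sum(dx == 0)
    ty_pairs <- ty_pairs + sum(dy == 0)
  }
  list(S = s, n0 = n * (n - 1) / 2, tx = tx_pairs, ty = ty_pairs)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' One-tailed Kendall rank correlation test
#'
#' Tau-b with tie corrections, and a one-tailed p-value for positive
#' association. For n <= 8 the p-value is exact: every permutation of `y`
#' against the fixed `x` is enumerated and the proportion with a
#' concordance statistic at least as large as the observed one is reported
#' (tie structures are preserved under permutation, so comparing S is
#' equivalent to comparing tau-b). For n > 8 a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors (values or ranks) of equal length >= 3.
#' @param method `"auto"` (exact up to n = 8), `"exact"`, or `"normal"`.
#' @return List with `tau` (tau-b), `p` (one-tailed, positive association),
#'   `S`, `n`, `method`.
#' @export
kendall_one_tailed <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n <- length(x)
  if (n != length(y) || n < 3) stop("need equal-length inputs of length >= 3")
  kc <- kendall_counts(x, y)
  denom <- sqrt((kc$n0 - kc$tx) * (kc$n0 - kc$ty))
  if (denom == 0) stop("tau undefined: all values tied in x or y")
  tau <- kc$S / denom
  if (method == "auto") method <- if (n <= 8) "exact" else "normal"

  if (method == "exact") {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    pairs <- utils::combn(n, 2)
    sx <- sign(x[pairs[2, ]] - x[pairs[1, ]])
    s_all <- rep(0, nrow(perms))
    for (pp in seq_len(ncol(pairs))) {
      yi <- y[perms[, pairs[1, pp]]]
      yj <- y[perms[, pairs[2, pp]]]
      s_all <- s_all + sx[pp] * sign(yj - yi)
    }
    p <- mean(s_all >= kc$S - 1e-9)
  } else {
    # tie-corrected variance of S under the null (standard tau-b test)
    tab_x <- table(x); tab_y <- table(y)
    tie_term <- function(tt, f) sum(f(as.numeric(tt)))
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- tie_term(tab_x, function(t) t * (t - 1) * (2 * t + 5))
    vu <- tie_term(tab_y, function(t) t * (t - 1) * (2 * t + 5))
    v1 <- tie_term(tab_x, function(t) t * (t - 1)) *
      tie_term(tab_y, function(t) t * (t - 1)) / (2 * n * (n - 1))
    v2 <- tie_term(tab_x, function(t) t * (t - 1) * (t - 2)) *
      tie_term(tab_y, function(t) t * (t - 1) * (t - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    # upper-tail continuity correction: P(S >= s) evaluated at s - 1
    z <- (kc$S - 1) / sqrt(v)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(tau = tau, p = p, S = kc$S, n = n, method = method)
}
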