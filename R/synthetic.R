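# ---- seeded RNG plumbing ----------------------------------------------------

# evaluate code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic child seed below 2^31, never 0
child_seed <- function(seed, i) {
  s <- (as.double(seed) * 48271 + i * 104729) %% 2147483647
  as.integer(s) + 1L
}

log_uniform <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# ---- noise specification ----------------------------------------------------

#' Measurement-noise specification for synthetic plate-reader data
#'
#' Replicate noise is heteroscedastic: each observation is
#' `y (1 + eps_p) + eps_a` with `eps_p ~ N(0, proportional_sd)` and
#' `eps_a ~ N(0, additive_sd x signal range)`, then clipped at zero. The
#' proportional term dominates at high signal, emulating the
#' variance-increases-with-signal behaviour of plate-reader fluorescence.
#'
#' @param proportional_sd Fraction of the signal (default 0.05).
#' @param additive_sd Fraction of the signal range (default 0.01).
#' @param replicates Number of biological replicates (default 3).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(proportional_sd = 0.05, additive_sd = 0.01,
                       replicates = 3L) {
  if (proportional_sd < 0 || additive_sd < 0 || replicates < 1)
    stop("noise sds must be >= 0 and replicates >= 1")
  structure(list(proportional_sd = proportional_sd, additive_sd = additive_sd,
                 replicates = as.integer(replicates)),
            class = "noise_spec")
}

# ---- ground truth ------------------------------------------------------------

# default generator ranges/effect scales; documented in the methods vignette.
# Chosen once so that OD curves are sigmoids saturating within the 16-h run
# (OD(0) near 0.05) and GFP/OD rises over a span of hours, and so that the
# context -> growth-parameter map has paper-scale predictability (substantial
# medium/supplement effects over a non-trivial per-context residual).
synthetic_defaults <- function() {
  list(
    globals = list(vmax_PROM = c(0.3, 1), k_deg = c(0.2, 0.5),
                   k_FDER = c(0.8, 2), K_NFDER = c(0.5, 2),
                   k_deg_FDER = c(0.05, 0.2), vmax_NAR = c(1, 4),
                   k_deg_GFP = c(0.05, 0.2), R_basal = c(0.2, 0.5),
                   k1 = c(0.1, 0.3), k2 = c(1.1, 1.5)),
    K_Pk_range = c(0.3, 3),
    medium_range = c(0.5, 2),
    rbs_base_range = c(0.3, 3),
    rbs_context_sd = 0.15,           # log-scale context perturbation
    growth = list(
      a1 = list(base = 0.6, medium = 0.20, supplement = 0.10,
                promoter = 0.05, rbs = 0.05, noise = 0.12),
      t1 = list(base = 6.0, medium = 0.12, supplement = 0.08,
                promoter = 0.03, rbs = 0.03, noise = 0.08),
      L1 = list(base = 1.1, medium = 0.15, supplement = 0.08,
                promoter = 0.02, rbs = 0.02, noise = 0.05))
  )
}

#' Draw a ground-truth parameter universe
#'
#' Generates a complete synthetic parameterisation of the biosensor library
#' with the documented variability structure: global kinetic constants shared
#' everywhere; promoter-scoped transcriptional strengths `K_Pk` (P1 is the
#' reference, `K_P1 = 1`); medium-scoped `K_mRNAp`, `K_mRNAdeg` (M0
#' reference), `K_P`, `K_lysis`; fully context-scoped `RBS_strength`; and
#' per-context growth parameters `(L1, a1, t1)` with globally shared
#' `(k1, k2)`. Scoped rates are drawn log-uniformly; growth parameters are
#' log-normal around a base value with additive factor-level effects on the
#' log scale plus a per-context residual, so two contexts sharing a medium
#' share all medium-scoped kinetics exactly.
#'
#' `RBS_strength` is an intrinsic per-RBS base strength times a log-normal
#' context perturbation: every context gets its own value (full
#' context-dependence) but the map from context to parameter retains
#' learnable structure, as a surrogate model presumes of the real system.
#'
#' @param space A [factor_space()].
#' @param seed Integer seed; the ground truth is reproducible from it.
#' @param defaults Generator ranges (see `synthetic_defaults()`).
#' @return An object of class `ground_truth` with elements `globals`,
#'   `promoter` (K_Pk table), `medium` (medium-scoped rate table), `contexts`
#'   (per-context growth + RBS_strength table) and `space`.
#' @export
draw_ground_truth <- function(space = factor_space(), seed = 1,
                              defaults = synthetic_defaults()) {
  with_seed(seed, {
    gl <- lapply(defaults$globals, function(r) log_uniform(1, r[1], r[2]))
    gl$R_basal <- runif(1, defaults$globals$R_basal[1],
                        defaults$globals$R_basal[2])

    K_Pk <- c(1, log_uniform(length(space$promoter) - 1,
                             defaults$K_Pk_range[1], defaults$K_Pk_range[2]))
    names(K_Pk) <- space$promoter

    med <- defaults$medium_range
    medium <- data.frame(
      medium = space$medium,
      K_mRNAp = log_uniform(length(space$medium), med[1], med[2]),
      K_mRNAdeg = c(1, log_uniform(length(space$medium) - 1, med[1], med[2])),
      K_P = log_uniform(length(space$medium), med[1], med[2]),
      K_lysis = log_uniform(length(space$medium), med[1], med[2]))

    rbs_base <- log_uniform(length(space$rbs), defaults$rbs_base_range[1],
                            defaults$rbs_base_range[2])
    names(rbs_base) <- space$rbs

    # per-level log-scale effects for the growth parameters
    eff <- lapply(defaults$growth, function(g) {
      list(medium = stats::setNames(rnorm(length(space$medium), 0, g$medium),
                                    space$medium),
           supplement = stats::setNames(
             rnorm(length(space$supplement), 0, g$supplement),
             space$supplement),
           promoter = stats::setNames(
             rnorm(length(space$promoter), 0, g$promoter), space$promoter),
           rbs = stats::setNames(rnorm(length(space$rbs), 0, g$rbs),
                                 space$rbs))
    })

    ctxs <- full_factorial(space)
    n <- nrow(ctxs)
    gpar <- function(par) {
      g <- defaults$growth[[par]]
      e <- eff[[par]]
      exp(log(g$base) + e$medium[ctxs$medium] + e$supplement[ctxs$supplement] +
            e$promoter[ctxs$promoter] + e$rbs[ctxs$rbs] +
            rnorm(n, 0, g$noise))
    }
    ctxs$L1 <- gpar("L1")
    ctxs$a1 <- gpar("a1")
    ctxs$t1 <- gpar("t1")
    ctxs$RBS_strength <- unname(rbs_base[ctxs$rbs]) *
      exp(rnorm(n, 0, defaults$rbs_context_sd))

    structure(list(globals = gl, promoter = K_Pk, medium = medium,
                   rbs_base = rbs_base, contexts = ctxs, space = space,
                   seed = seed),
              class = "ground_truth")
  })
}

#' Resolve the growth parameters of one context
#'
#' @param gt A [draw_ground_truth()] object.
#' @param ctx A context (named vector with medium/supplement/promoter/rbs).
#' @return A [growth_params()] object.
#' @export
resolve_growth <- function(gt, ctx) {
  row <- gt$contexts[gt$contexts$context_id == context_id(ctx), ]
  if (nrow(row) != 1L) stop("context not in ground truth: ", context_id(ctx))
  growth_params(L1 = row$L1, a1 = row$a1, t1 = row$t1,
                k1 = gt$globals$k1, k2 = gt$globals$k2)
}

#' Resolve the kinetic parameters of one context
#'
#' @inheritParams resolve_growth
#' @return A [kinetic_params()] object.
#' @export
resolve_kinetics <- function(gt, ctx) {
  row <- gt$contexts[gt$contexts$context_id == context_id(ctx), ]
  if (nrow(row) != 1L) stop("context not in ground truth: ", context_id(ctx))
  med <- gt$medium[gt$medium$medium == row$medium, ]
  gl <- gt$globals
  kinetic_params(
    vmax_PROM = gl$vmax_PROM, K_Pk = unname(gt$promoter[row$promoter]),
    K_mRNAp = med$K_mRNAp, k_deg = gl$k_deg, K_mRNAdeg = med$K_mRNAdeg,
    K_P = med$K_P, K_lysis = med$K_lysis, RBS_strength = row$RBS_strength,
    k_FDER = gl$k_FDER, K_NFDER = gl$K_NFDER, k_deg_FDER = gl$k_deg_FDER,
    vmax_NAR = gl$vmax_NAR, k_deg_GFP = gl$k_deg_GFP, R_basal = gl$R_basal)
}

# ---- experiment generation ---------------------------------------------------

#' Generate one replicated synthetic experiment
#'
#' Simulates the noiseless OD and GFP/OD trajectories of a context on the
#' default 16-h / 10-min grid and overlays independent heteroscedastic
#' replicate noise (see [noise_spec()]); values are clipped at zero.
#'
#' @param ctx Context (named vector or `context_key`).
#' @param gt A [draw_ground_truth()] object.
#' @param noise A [noise_spec()].
#' @param seed Integer seed for the noise draws.
#' @param times Sampling grid (h).
#' @return An `experiment_time_course`: list with `context`, `times`,
#'   `od` and `gfp` replicate matrices (time x replicate), and the noiseless
#'   `truth` trajectory.
#' @export
generate_experiment <- function(ctx, gt, noise = noise_spec(), seed = 1,
                                times = default_grid()) {
  gp <- resolve_growth(gt, ctx)
  kp <- resolve_kinetics(gt, ctx)
  truth <- simulate_biosensor(gp, kp, times = times, ctx = ctx)
  with_seed(seed, {
    noisy <- function(y) {
      rng <- diff(range(y))
      m <- vapply(seq_len(noise$replicates), function(r) {
        pmax(y * (1 + rnorm(length(y), 0, noise$proportional_sd)) +
               rnorm(length(y), 0, noise$additive_sd * rng), 0)
      }, numeric(length(y)))
      colnames(m) <- paste0("rep", seq_len(noise$replicates))
      m
    }
    structure(list(context = ctx, times = times, od = noisy(truth$od),
                   gfp = noisy(truth$gfp_per_od), truth = truth),
              class = "experiment_time_course")
  })
}

#' Generate a synthetic experimental library
#'
#' One replicated experiment per design run, with per-run child seeds derived
#' deterministically from the master seed.
#'
#' @param design A design data.frame with columns medium, supplement,
#'   promoter, rbs (e.g. from [d_optimal()]).
#' @param gt A [draw_ground_truth()] object.
#' @param noise A [noise_spec()].
#' @param seed Master integer seed.
#' @param times Sampling grid (h).
#' @return A named list of `experiment_time_course` objects keyed by
#'   `context_id`.
#' @export
generate_library <- function(design, gt, noise = noise_spec(), seed = 1,
                             times = default_grid()) {
  out <- lapply(seq_len(nrow(design)), function(i) {
    ctx <- c(medium = design$medium[i], supplement = design$supplement[i],
             promoter = design$promoter[i], rbs = design$rbs[i])
    generate_experiment(ctx, gt, noise = noise, seed = child_seed(seed, i),
                        times = times)
  })
  names(out) <- context_id(design)
  out
}
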