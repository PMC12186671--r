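# ---- configuration ----------------------------------------------------------

#' Run configuration for the DBTL workflow
#'
#' Collects every knob of a reproducible run: factor space, seeds per stage,
#' design sizes, noise specification, optimiser budgets, bagging iterations
#' and train/validation splits. The `desk` profile scales the bagging count
#' down from 300 to 50 for interactive work; everything else is shared.
#'
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param profile `"full"` (300 bagging iterations) or `"desk"` (50).
#' @param n_initial,n_augment Design sizes of the two experimental rounds.
#' @param n_train,n_validation Train/validation split of the combined design
#'   (defaults 48/16).
#' @param nn_validation Held-out contexts for the reporter network (8 of
#'   64).
#' @param noise A [noise_spec()].
#' @param budget Calibration budget (objective evaluations).
#' @param space A [factor_space()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, profile = c("desk", "full"),
                       n_initial = 32, n_augment = 32, n_train = 48,
                       n_validation = 16, nn_validation = 8,
                       noise = noise_spec(), budget = 3000,
                       space = factor_space()) {
  profile <- match.arg(profile)
  if (n_train + n_validation > n_initial + n_augment)
    stop("train/validation split exceeds the design size")
  structure(list(
    seed = seed, profile = profile,
    bagging_iterations = if (profile == "full") 300L else 50L,
    n_initial = n_initial, n_augment = n_augment, n_train = n_train,
    n_validation = n_validation, nn_validation = nn_validation,
    noise = noise, budget = budget, space = space,
    stage_seeds = stats::setNames(
      vapply(1:8, function(i) child_seed(seed, i), integer(1)),
      c("doe", "generate", "fit", "bag", "train", "predict", "rank",
        "validate"))),
    class = "run_config")
}

# order-insensitive-free deterministic hash of a configuration (FNV-1a over
# its deparsed form); good enough for manifest identity checks
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(stage, config, outdir, extra = list()) {
  manifest <- c(list(stage = stage, seed = config$stage_seeds[[stage]],
                     profile = config$profile,
                     config_hash = config_hash(unclass(config))),
                extra)
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Run one workflow stage
#'
#' Dispatches one step of the pipeline — `doe` (D-optimal + augmented
#' design), `generate` (synthetic library), `fit` (growth calibration),
#' `bag` (kinetic calibration with bootstrap bagging over a configured
#' context subset), `train` (surrogates), `predict` (response prediction
#' over the design), `rank` (ranked table), `validate` (top-k overlap and
#' Kendall test against a reference or held-out observations) — writing its
#' artifacts and a seed-stamped manifest under `outdir` and returning the
#' updated in-memory state.
#'
#' @param name Stage id.
#' @param config A [run_config()].
#' @param state Named list of upstream artifacts (returned enriched).
#' @param outdir Output directory (created if needed).
#' @return The updated state (invisibly carries `manifest`).
#' @export
run_stage <- function(name, config, state = list(), outdir = tempdir()) {
  if (!name %in% names(config$stage_seeds)) stop("unknown stage '", name, "'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$stage_seeds[[name]]
  need <- function(what) {
    if (is.null(state[[what]]))
      stop("stage '", name, "' needs missing upstream artifact '", what,
           "' (produced by an earlier stage)")
    state[[what]]
  }
  state$manifest <- switch(
    name,
    doe = {
      r1 <- d_optimal(config$space, n_runs = config$n_initial, seed = seed)
      r2 <- augment_design(r1$design, config$space,
                           n_additional = config$n_augment, seed = seed)
      state$design_initial <- r1$design
      state$design <- r2$design
      write_design_csv(r1$design, file.path(outdir, "design_round1.csv"))
      write_design_csv(r2$design, file.path(outdir, "design_combined.csv"))
      write_manifest("doe", config, outdir,
                     list(log_det_round1 = r1$log_det,
                          log_det_combined = r2$log_det))
    },
    generate = {
      design <- need("design")
      state$ground_truth <- draw_ground_truth(config$space, seed = seed)
      state$experiments <- generate_library(design, state$ground_truth,
                                            noise = config$noise, seed = seed)
      utils::write.csv(experiments_to_long(state$experiments),
                       file.path(outdir, "experiments_long.csv"),
                       row.names = FALSE)
      write_manifest("generate", config, outdir,
                     list(n_experiments = length(state$experiments)))
    },
    fit = {
      exps <- need("experiments")
      jf <- fit_growth_joint(exps, seed = seed)
      names(jf$growth) <- names(exps)
      state$growth_fits <- jf
      gtab <- do.call(rbind, lapply(names(jf$growth), function(cid)
        data.frame(context_id = cid, as.list(unclass(jf$growth[[cid]])))))
      utils::write.csv(gtab, file.path(outdir, "growth_fits.csv"),
                       row.names = FALSE)
      write_manifest("fit", config, outdir,
                     list(k1 = jf$k1, k2 = jf$k2))
    },
    bag = {
      exps <- need("experiments")
      jf <- need("growth_fits")
      ids <- state$bag_contexts
      if (is.null(ids)) ids <- names(exps)
      ensembles <- list()
      for (cid in ids) {
        problem <- context_fit_problem(exps[[cid]], jf$growth[[cid]],
                                       baseline = state$kinetic_baseline)
        ensembles[[cid]] <- bagging_ensemble(
          problem, n_iterations = config$bagging_iterations,
          seed = child_seed(seed, match(cid, ids)),
          budget = config$budget %/% 5)
      }
      state$ensembles <- ensembles
      mat <- do.call(rbind, lapply(names(ensembles), function(cid)
        data.frame(context_id = cid, iteration =
                     seq_len(nrow(ensembles[[cid]]$matrix)),
                   ensembles[[cid]]$matrix, check.names = FALSE)))
      utils::write.csv(mat, file.path(outdir, "ensemble_parameters.csv"),
                       row.names = FALSE)
      write_manifest("bag", config, outdir,
                     list(n_contexts = length(ensembles),
                          n_iterations = config$bagging_iterations))
    },
    rank = {
      preds <- need("predictions")     # named vector or trajectory list
      ranked <- rank_candidates(preds, criterion = state$criterion %||% "gain",
                                k = state$k %||% 10,
                                observed = state$observed)
      state$ranked <- ranked
      write_ranked_csv(ranked, file.path(outdir, "ranked_table.csv"))
      write_manifest("rank", config, outdir, list(n_rows = nrow(ranked)))
    },
    validate = {
      ranked <- state$ranked
      if (is.null(ranked)) ranked <- reference_ranking(
        state$reference %||% "high_gain")
      overlap <- top_k_overlap(ranked, k = state$k %||% 10)
      kt <- kendall_one_tailed(ranked$predicted, ranked$observed)
      state$validation <- list(top_k_overlap = overlap, kendall = kt)
      jsonlite::write_json(list(top_k_overlap = overlap, tau = kt$tau,
                                p = kt$p, method = kt$method),
                           file.path(outdir, "validation.json"),
                           auto_unbox = TRUE, digits = NA)
      write_manifest("validate", config, outdir,
                     list(top_k_overlap = overlap, tau = kt$tau, p = kt$p))
    },
    stop("unknown stage '", name, "'")
  )
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default single-context kinetic calibration problem
#'
#' Builds the [fit_problem()] used by the bagging stage: the context's
#' RBS-scoped translation strength, the medium-scoped protein production
#' rate, the promoter-scoped transcription strength and the global GFP
#' degradation constant are estimated against the GFP/OD channel, with
#' everything else held at the supplied baseline kinetics (or documented
#' defaults). This is deliberately flexible enough that single fits can
#' chase noise along compensating directions — the regime in which bagged
#' ensembles earn their keep.
#'
#' @param exp An `experiment_time_course`.
#' @param growth Fitted [growth_params()] for the context.
#' @param baseline Optional [kinetic_params()] baseline.
#' @param free Scoped names to estimate (defaults to the context-, medium-
#'   and promoter-scoped strengths of this context).
#' @param lower,upper Bounds.
#' @return A [fit_problem()].
#' @export
context_fit_problem <- function(exp, growth, baseline = NULL, free = NULL,
                                lower = 1e-2, upper = 1e2) {
  ctx <- exp$context
  if (is.null(baseline))
    baseline <- kinetic_params(vmax_PROM = 0.5, k_deg = 0.3, k_FDER = 1.2,
                               K_NFDER = 1, k_deg_FDER = 0.1, vmax_NAR = 2,
                               k_deg_GFP = 0.1, R_basal = 0.3)
  if (is.null(free))
    free <- c(paste0("RBS_strength.", context_id(ctx)),
              paste0("K_P.", ctx[["medium"]]),
              paste0("K_Pk.", ctx[["promoter"]]),
              "k_deg_GFP")
  fit_problem(exp, free = free, lower = lower, upper = upper,
              growth = growth, kinetics = baseline)
}
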