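# ---- long-format trajectory CSV ---------------------------------------------

#' Convert experiments to / from the long trajectory format
#'
#' The interchange format for replicated time courses: one row per context,
#' replicate and time point, with columns `context_id, medium, supplement,
#' promoter, rbs, replicate, time_h, od, gfp_per_od`.
#'
#' @param experiments Named list of `experiment_time_course` objects.
#' @return A long-format data.frame.
#' @export
experiments_to_long <- function(experiments) {
  seen <- new.env()   # replicate offset per context: a design may repeat a
  do.call(rbind, lapply(experiments, function(e) {  # run, adding replicates
    ctx <- e$context
    cid <- context_id(ctx)
    nrep <- ncol(e$od)
    offset <- if (is.null(seen[[cid]])) 0L else seen[[cid]]
    seen[[cid]] <- offset + nrep
    do.call(rbind, lapply(seq_len(nrep), function(r)
      data.frame(context_id = cid, medium = ctx[["medium"]],
                 supplement = ctx[["supplement"]],
                 promoter = ctx[["promoter"]], rbs = ctx[["rbs"]],
                 replicate = r + offset, time_h = e$times, od = e$od[, r],
                 gfp_per_od = e$gfp[, r], stringsAsFactors = FALSE)))
  }))
}

#' @rdname experiments_to_long
#' @param long A long-format data.frame as written by
#'   [experiments_to_long()].
#' @export
long_to_experiments <- function(long) {
  out <- lapply(split(long, long$context_id), function(d) {
    reps <- sort(unique(d$replicate))
    times <- sort(unique(d$time_h))
    d <- d[order(d$replicate, d$time_h), ]
    od <- matrix(d$od, ncol = length(reps),
                 dimnames = list(NULL, paste0("rep", reps)))
    gfp <- matrix(d$gfp_per_od, ncol = length(reps),
                  dimnames = list(NULL, paste0("rep", reps)))
    structure(list(context = c(medium = d$medium[1],
                               supplement = d$supplement[1],
                               promoter = d$promoter[1], rbs = d$rbs[1]),
                   times = times, od = od, gfp = gfp),
              class = "experiment_time_course")
  })
  out[unique(long$context_id)]
}

#' Read / write design tables
#'
#' Designs are CSV files with columns `run_id, promoter, rbs, medium,
#' supplement`.
#'
#' @param design Design data.frame.
#' @param path File path.
#' @export
write_design_csv <- function(design, path) {
  if (is.null(design$run_id)) design$run_id <- seq_len(nrow(design))
  utils::write.csv(design[, c("run_id", "promoter", "rbs", "medium",
                              "supplement")],
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$context_id <- context_id(d)
  d
}

# ---- reference validation fixtures ------------------------------------------

#' Reference predicted-vs-observed biosensor rankings
#'
#' Published benchmark rankings for a 64-experiment naringenin biosensor
#' library: the predicted top-10 high-gain designs (relative GFP/OD gain, %)
#' and the predicted top fast-response designs (half-times, s x 10^3),
#' each with the observed value and the rank of the design within the full
#' experimental comparison set. Used to validate the selection machinery.
#'
#' @param which `"high_gain"` or `"fast_response"`.
#' @return A `ranked_table` data.frame with columns `predicted`, `observed`,
#'   `observed_rank`, `experiment`, `medium`, `supplement`, `promoter`,
#'   `rbs`.
#' @export
reference_ranking <- function(which = c("high_gain", "fast_response")) {
  which <- match.arg(which)
  file <- if (which == "high_gain") "reference_highgain_ranking.csv"
          else "reference_fastresponse_ranking.csv"
  path <- system.file("extdata", file, package = "biosensordbtl")
  if (!nzchar(path)) stop("fixture not found: ", file)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("ranked_table", "data.frame")
  tab
}

#' Write a ranked table in the reporting layout
#'
#' @param ranked A `ranked_table`.
#' @param path File path.
#' @export
write_ranked_csv <- function(ranked, path) {
  utils::write.csv(as.data.frame(ranked), path, row.names = FALSE,
                   quote = FALSE)
}
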