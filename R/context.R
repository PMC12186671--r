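#' Factor space of the biosensor library
#'
#' The combinatorial design space of the biosensor library: two genetic
#' regulatory factors (constitutive promoter driving the transcription factor
#' FdeR, and its ribosome binding site) and two environmental context factors
#' (growth medium and supplemented carbon source). All factors are categorical.
#'
#' @param promoter,rbs,medium,supplement Character vectors of level labels.
#' @return An object of class `factor_space`: a named list of level vectors in
#'   the canonical order promoter, rbs, medium, supplement.
#' @examples
#' sp <- factor_space()
#' prod(lengths(sp))  # 320 combinations
#' @export
factor_space <- function(promoter = paste0("P", 1:4),
                         rbs = paste0("R", 1:5),
                         medium = paste0("M", 0:3),
                         supplement = paste0("S", 0:3)) {
  sp <- list(promoter = promoter, rbs = rbs, medium = medium,
             supplement = supplement)
  for (nm in names(sp)) {
    lv <- sp[[nm]]
    if (length(lv) < 1L || anyDuplicated(lv) || any(!nzchar(lv)))
      stop("factor '", nm, "' needs a non-empty duplicate-free level set")
  }
  structure(sp, class = "factor_space")
}

#' One experimental context
#'
#' A context is one cell of the factorial space: a (medium, supplement,
#' promoter, RBS) combination. Levels are validated against the space.
#'
#' @param medium,supplement,promoter,rbs Single level labels.
#' @param space A [factor_space()].
#' @return An object of class `context_key` (named character vector).
#' @export
context_key <- function(medium, supplement, promoter, rbs,
                        space = factor_space()) {
  ctx <- c(medium = medium, supplement = supplement,
           promoter = promoter, rbs = rbs)
  check_context(ctx, space)
  structure(ctx, class = "context_key")
}

check_context <- function(ctx, space = factor_space()) {
  stopifnot(all(c("medium", "supplement", "promoter", "rbs") %in% names(ctx)))
  for (nm in names(space)) {
    if (!ctx[[nm]] %in% space[[nm]])
      stop("unknown ", nm, " level '", ctx[[nm]], "'")
  }
  invisible(ctx)
}

#' Enumerate the full factorial context set
#'
#' @param space A [factor_space()].
#' @return A data.frame with columns medium, supplement, promoter, rbs and one
#'   row per combination (320 for the default space), plus a `context_id`
#'   label of the form `M0_S0_P1_R1`.
#' @export
full_factorial <- function(space = factor_space()) {
  grid <- expand.grid(rbs = space$rbs, promoter = space$promoter,
                      supplement = space$supplement, medium = space$medium,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("medium", "supplement", "promoter", "rbs")]
  grid$context_id <- context_id(grid)
  rownames(grid) <- NULL
  grid
}

#' @rdname full_factorial
#' @param ctx A context (named vector or data.frame of level columns).
#' @export
context_id <- function(ctx) {
  if (is.data.frame(ctx)) {
    paste(ctx$medium, ctx$supplement, ctx$promoter, ctx$rbs, sep = "_")
  } else {
    paste(ctx[["medium"]], ctx[["supplement"]], ctx[["promoter"]],
          ctx[["rbs"]], sep = "_")
  }
}

# row of a design data.frame -> context_key
row_context <- function(row, space = factor_space()) {
  context_key(row$medium, row$supplement, row$promoter, row$rbs, space = space)
}
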