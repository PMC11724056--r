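# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic stages route their seed through this so that the pipeline
# is a pure function of (inputs, config).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Check that a numeric vector lies on the probability simplex.
check_simplex <- function(p, what = "proportions", tol = 1e-9) {
  if (any(p < -tol)) stop(what, " contain negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Stable renaming of cluster labels by descending cluster size; ties broken
# by the smallest original label so the result is deterministic.
rename_by_size <- function(labels, prefix = "C") {
  tab <- table(labels)
  ord <- order(-as.integer(tab), names(tab))
  map <- setNames(paste0(prefix, seq_along(ord)), names(tab)[ord])
  unname(map[as.character(labels)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log2 with a small pseudocount on both sides.
log2_ratio <- function(a, b, pseudo = 1e-9) log2((a + pseudo) / (b + pseudo))
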