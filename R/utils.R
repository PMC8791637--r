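#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without disturbing the
#' session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministic and collision-resistant enough for a handful of stages;
#' keeps results below 2^31 so they remain valid R integers.
#'
#' @param seed master integer seed.
#' @param offset stage index (small non-negative integer).
#' @return integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647L)
}

#' Compact parameter digest for provenance columns
#'
#' Serializes a named list of scalar parameters into a stable
#' `name=value;...` string that quantification stages embed in their
#' output tables, so a result row can be traced back to its settings.
#'
#' @param params named list of scalar parameters.
#' @return single character string.
#' @export
param_digest <- function(params) {
  if (length(params) == 0L) return("")
  nm <- sort(names(params))
  vals <- vapply(params[nm], function(v) {
    paste(format(v, digits = 10, trim = TRUE, scientific = FALSE), collapse = ",")
  }, character(1))
  paste(paste0(nm, "=", vals), collapse = ";")
}

#' Structured log line to stderr
#'
#' @param stage stage name.
#' @param ... message parts pasted together.
#' @keywords internal
cq_log <- function(stage, ...) {
  message(sprintf("[condquant:%s] %s", stage, paste0(...)))
}

## shift a matrix by (dy, dx), padding with `fill`
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ys) == 0L || length(xs) == 0L) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
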