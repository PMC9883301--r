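# Internal helpers shared across modules.

# Run an expression with a locally seeded RNG, restoring the caller's
# .Random.seed afterwards so simulation helpers do not perturb global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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

#' Derive a reproducible per-stage seed from a global seed
#'
#' Hashes the stage name together with the global seed so pipeline stages can
#' be re-run in isolation with the same random stream they would see inside
#' [run_pipeline()]. The result is always a positive 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single positive integer.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- digest::digest2int(paste0(stage, ":", format(seed)))
  (abs(h) %% (.Machine$integer.max - 1L)) + 1L
}

stop_if_negative <- function(x, what = "counts") {
  if (any(x < 0, na.rm = TRUE)) {
    abort(paste0("negative ", what, " are not allowed"))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
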