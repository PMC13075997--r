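# Internal helpers shared across modules.

#' Evaluate an expression with a fixed RNG state
#'
#' Seeds R's Mersenne-Twister generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards so seeded operations do not perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and a stream label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Round a percentage to the nearest integer, halves away from zero
#'
#' The rounding rule used for all printed count/total percentages in the
#' splicing-error summaries (e.g. 811 of 1,510 gives 54).
#'
#' @param count Numerator count(s), non-negative.
#' @param total Denominator total, positive.
#' @return Integer percent(s).
#' @examples
#' percent_round(811, 1510)
#' @export
percent_round <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0), all(count >= 0))
  as.integer(floor(100 * count / total + 0.5))
}

# Stop with a prefixed, formatted message.
sc_stop <- function(...) stop(sprintf(...), call. = FALSE)

# md5 of an in-memory object via its JSON serialization (for manifests).
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
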