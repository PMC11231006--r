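#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded package functions never disturb the
#' global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  expr
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to seed
# per-object pseudo-random feature draws so fixtures are pure functions of
# their inputs.
string_hash <- function(s, mod = 2147483647L) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% mod
  as.integer(h)
}

# Derive a child seed from a base seed and a label, staying below 2^31.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + string_hash(label)) %% 2147483647)
}

abort_surgvqa <- function(msg, class) {
  stop(structure(class = c(class, "surgvqa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)
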