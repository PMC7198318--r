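# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Canonicalise an author set: unique, sorted, non-empty strings.
as_author_set <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  sort(unique(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_citesum <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "citesum_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
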