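# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Natural (numeric-aware) ordering of file names: "frame_2" < "frame_10".
natural_order <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", x)))
  num[is.na(num)] <- Inf
  order(num, x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0L, 1L, 0, 1, TRUE, FALSE))
}

as_mask <- function(m) {
  storage.mode(m) <- "integer"
  m
}
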