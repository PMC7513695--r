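# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this, so no
# function leaks global RNG state.
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}

# Derive a stage-level sub-seed from a global seed so that stage reruns are
# stable. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647L)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s).",
                  name, min, paste(x, collapse = ",")))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1] (got %s).",
                  name, paste(x, collapse = ",")))
  }
  invisible(as.numeric(x))
}

assert_number <- function(x, name) {
  if (length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(as.numeric(x))
}

# rank 1 = highest score; deterministic tie-break on gene id
score_ranks <- function(score, gene) {
  ord <- order(-score, gene)
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  rank
}

# decile 1 holds the ceiling(n/10) top-ranked genes
rank_decile <- function(rank, n) {
  pmin(10L, as.integer(ceiling(rank / ceiling(n / 10))))
}
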