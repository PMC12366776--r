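# Seed plumbing: every stochastic operation runs in its own RNG scope derived
# deterministically from (config seed, identifiers), so datasets are
# reproducible element-wise regardless of generation order, and user RNG
# state is never disturbed.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mix a base seed with identifiers (integers or strings) into one 31-bit seed.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647)
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p)) * 131
    for (v in as.double(p)) {
      h <- (h * 69069 + (v %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Internal: stop unless all named conditions hold, with a compact message.
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
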