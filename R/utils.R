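# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used for the seeded restarts of the model-reduction search so that
# fits are bit-reproducible no matter where they are called from.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# -sum(p * log(q)) over entries with p > 0; +Inf if any p > 0 meets q == 0.
cross_entropy_sum <- function(p, q) {
  pos <- p > 0
  if (!any(pos)) return(0)
  if (any(q[pos] == 0)) return(Inf)
  -sum(p[pos] * log(q[pos]))
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
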