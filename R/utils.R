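# Internal numeric and RNG helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; lipid apportionment uses the
#' conventional round-half-up rule so that printed one-decimal mole percents
#' are reproduced exactly.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps package randomness reproducible
# without clobbering the user's stream.
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-molecule stream seed derived from a global seed and a
# molecule index. Constants are arbitrary coprime multipliers; result stays
# inside the 32-bit signed range R requires for set.seed().
molecule_seed <- function(seed, mol_index) {
  ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(mol_index) * 15485863) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
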