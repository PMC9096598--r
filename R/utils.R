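# Internal numerical and RNG helpers.

.adaptsim_env <- new.env(parent = emptyenv())

# Gauss-Legendre rule on [-1, 1], cached per node count.
gl_rule <- function(n = 128L) {
  key <- paste0("gl", n)
  r <- .adaptsim_env[[key]]
  if (is.null(r)) {
    r <- pracma::gaussLegendre(n, -1, 1)
    .adaptsim_env[[key]] <- r
  }
  r
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Half-away-from-zero rounding, matching journal-table formatting (base
# round() is round-half-even). The epsilon guards binary representation of
# values that are exact halves in decimal.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  }
  invisible(as.integer(round(x)))
}
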