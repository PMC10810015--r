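# internal validation and RNG plumbing

PARTICLES <- c("electron", "proton", "alpha")
SPECIES <- c("OH", "e_aq", "H", "H2O2")

.check_particle <- function(particle) {
  if (length(particle) != 1L || !particle %in% PARTICLES) {
    abort(paste0(
      "unknown particle '", paste(particle, collapse = ","),
      "'; must be one of ", paste(PARTICLES, collapse = ", ")
    ))
  }
  particle
}

.check_let <- function(let, lower = 0, upper = 300) {
  if (!is.numeric(let) || anyNA(let)) abort("LET must be numeric and non-missing")
  bad <- let < lower | let > upper
  if (any(bad)) {
    abort(sprintf(
      "LET %g keV/um outside supported interval [%g, %g]",
      let[bad][1], lower, upper
    ))
  }
  let
}

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort(paste0(what, " must be non-negative"))
  }
  x
}

# Deterministic per-module substream seed derived from one root seed, so that
# adding draws in one module never perturbs another. Kept below 2^31 - 1.
.stream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.double(seed) %% 65011) * 33013 + h * 97 + 1) %% 2147483647L
}

# Run `expr` under `seed` if given, otherwise in the ambient RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
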