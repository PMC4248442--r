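# Internal helpers shared across modules.

# Run `code` with a temporary RNG seed, restoring the caller's random state
# afterwards so generators never leak global RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic sub-seed for a named component so that each
# generator is reproducible independently of call order. Kept < 2^31.
sub_seed <- function(seed, component) {
  offs <- c(expression = 101L, pathways = 211L, pm = 307L,
            compounds = 401L, proteomes = 503L)
  off <- offs[[component]]
  (as.integer(seed) %% 2146000000L) + off
}

# Locus lists travel inside data frame cells as ";"-joined strings.
join_loci <- function(x) vapply(x, function(v) paste(v, collapse = ";"), character(1))

split_loci <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never falls into the 1:x trap for length-1 vectors
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
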