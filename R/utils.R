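# Internal helpers: seeded substreams, RNG state preservation, step functions.

# Substream seeds: one independent seed per (master, replication, stream).
# Keeps every derived seed strictly below 2^31 - 1.
STREAMS <- c(accidents = 1L, weather = 2L, service = 3L, population = 4L)

substream_seed <- function(master, stream, rep = 0L) {
  idx <- STREAMS[[stream]]
  s <- (as.numeric(master) %% 1e6) * 1021 + as.numeric(rep) * 131 + idx * 7 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Piecewise-constant step function: value[i] holds on [breaks[i], breaks[i+1]).
# breaks[1] must be <= any queried t.
step_fun <- function(breaks, values) {
  stopifnot(length(values) == length(breaks))
  list(breaks = breaks, values = values)
}

step_at <- function(sf, t) {
  sf$values[findInterval(t, sf$breaks)]
}

# Format doubles so that read-back round-trips bit exactly.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    sprintf("%.17g", v)
  }, character(1))
  out
}

ems_abort <- function(msg, class) {
  stop(structure(class = c(class, "ems_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MONTHS3 <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
             "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")
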