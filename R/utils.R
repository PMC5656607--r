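# Internal helpers: error signalling, seeded RNG, interval arithmetic.

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("escapescreen_format_error",
                                             "escapescreen_error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("escapescreen_param_error",
                                             "escapescreen_error")))
}

# Evaluate `expr` under a private RNG stream; the caller's .Random.seed is
# untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_param("`seed` must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# INFO-level pipeline logging; suppress with options(escapescreen.quiet = TRUE)
log_info <- function(...) {
  if (!isTRUE(getOption("escapescreen.quiet", TRUE)))
    message("[escapescreen] ", sprintf(...))
}

# Variant identity used throughout: chrom:pos:ref:alt (sample added where
# voting is per-sample).
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
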