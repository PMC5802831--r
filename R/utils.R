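# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  If `seed` is NULL the current stream is used unchanged, so
# callers can opt out of reproducibility control.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
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

# Draw `n` independent child seeds (31-bit) from a master seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Sequence over a range; a single point sits at the midpoint.
lin_seq <- function(range, n) {
  if (n == 1) mean(range) else seq(range[1], range[2], length.out = n)
}

# Full-precision numeric formatting for text serialization (round-trips
# doubles exactly, which is stronger than the 15 significant digits the
# file contract asks for).
fmt_num <- function(x) sprintf("%.17g", x)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Cheap content fingerprint for provenance records (md5 of the full-precision
# text rendering).
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(fmt_num(as.numeric(x)), f)
  unname(tools::md5sum(f))
}
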