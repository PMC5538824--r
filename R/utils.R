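# Internal helpers shared across modules.

.assert <- function(cond, msg, class = "cabuffer_validation_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Centered k-point moving average; shrinks the window at the edges so the
# output has the same length and no NA padding.
moving_average <- function(x, k = 5L) {
  k <- as.integer(k)
  .assert(k >= 1L, "smoothing window must be >= 1 sample")
  if (k == 1L || length(x) < 2L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Significance stars: *p<0.05, **p<0.01, ***p<0.001, ns otherwise.
sig_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

# Small provenance hash of an R object (config fingerprinting for outputs).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
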