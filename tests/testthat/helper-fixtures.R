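# Shared fixtures: everything is generated in code at test time.

# A small configuration for fast pipeline tests: 30 s of usable signal
# (10 segments of 3 s), tiny training budget.
tiny_config <- function(...) {
  default_config(record_seconds_used = 30, epochs = 2L, batch_size = 8L, ...)
}

# Short clean synthetic record (default 60 s) for detector tests.
short_record <- function(duration_s = 60, noise_sd = 0, seed = 11, ...) {
  gen_record(synth_params(duration_s = duration_s, noise_sd = noise_sd,
                          seed = seed, ...))
}

# Exhaustive-coupling discrete Frechet oracle for short sequences: recursion
# over the three monotone moves, memoized.  Independent of the package DP.
frechet_brute <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    d <- abs(a[i] - b[j])
    v <- if (i == 1 && j == 1) d
    else if (i == 1) max(rec(1, j - 1), d)
    else if (j == 1) max(rec(i - 1, 1), d)
    else max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), d)
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}
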