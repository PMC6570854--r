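# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from the user seed so the environment,
# pairing and trait streams are independently reproducible. Kept inside
# the 32-bit integer range.
stage_seed <- function(seed, stage) {
  offset <- c(environment = 0L, pairing = 1L, traits = 2L, generic = 3L)[[stage]]
  as.integer((as.numeric(seed) + offset * 1000003) %% 2147483629)
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", what),
          class = "leafspectra_domain_error")
  }
  invisible(x)
}

# Format a numeric data frame to 12 significant digits so written CSVs are
# byte-stable across runs.
format_signif <- function(df, digits = 12) {
  as_tibble(lapply(df, function(col) {
    if (is.double(col)) signif(col, digits) else col
  }))
}

write_csv_stable <- function(df, path, digits = 12) {
  readr::write_csv(format_signif(df, digits), path, progress = FALSE)
  invisible(path)
}
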