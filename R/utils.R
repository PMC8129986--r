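# Internal helpers shared across the package.

# Validation failures get their own condition class so callers (and the CLI)
# can distinguish bad inputs (exit 1) from runtime faults (exit 2).
stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("debtprior_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Coerce a column read from CSV to numeric; any value that fails to parse is
# a validation error, never a silent NA.
coerce_numeric <- function(x, column, context = "table") {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "" & !(x %in% c("NA")))
  if (length(bad) > 0L) {
    stop_validation("%s: column '%s' has unparseable numeric value '%s' (row %d)",
                    context, column, x[bad[1L]], bad[1L])
  }
  out
}

# Deterministic, locale-independent ordering for character keys.
order_c <- function(...) order(..., method = "radix")

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# Mersenne-Twister + inversion, pinned so outputs are portable.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
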