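# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-run seed from a campaign seed and a run index, kept inside
# the 32-bit integer range so set.seed() accepts it.
run_seed <- function(seed, run_index) {
  as.integer((as.numeric(seed) + 100003 * as.numeric(run_index)) %%
               .Machine$integer.max)
}

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_positive <- function(..., .allow_zero = FALSE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) || any(!is.finite(x)) ||
        (if (.allow_zero) any(x < 0) else any(x <= 0))) {
      stop_domain(sprintf("'%s' must be %s and finite", nms[i],
                          if (.allow_zero) "non-negative" else "positive"))
    }
  }
  invisible(TRUE)
}

trapz_int <- function(x, y) pracma::trapz(x, y)

cum_trapz <- function(x, y) as.numeric(pracma::cumtrapz(x, y))

# Centered moving average with odd window; ends use shrinking windows.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}
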