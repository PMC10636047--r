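# Internal helpers shared across modules.

# Half-up integer rounding (round(2.5) in base R is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + sign(x) * 0.5) / m
}

# Largest-remainder apportionment of n items over probabilities `probs`.
# Deterministic: ties on the fractional remainder go to the lower index.
# Guarantees sum(result) == n and result >= 0.
apportion <- function(n, probs) {
  stopifnot(n >= 0, all(probs >= 0), abs(sum(probs) - 1) < 1e-9)
  q <- n * probs
  cnt <- floor(q)
  left <- n - sum(cnt)
  if (left > 0) {
    # primary key: fractional remainder descending; ties to the lower index
    ord <- order(-(q - cnt), seq_along(q))
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

# Maximal runs of TRUE in a logical vector indexed by `idx` (sorted integer
# positions, e.g. slice indices): returns data.frame(start, end, length) of
# runs of *consecutive* indices.
consecutive_runs <- function(idx) {
  if (length(idx) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  idx <- sort(unique(idx))
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  data.frame(
    start = idx[brk[-length(brk)] + 1L],
    end = idx[brk[-1L]],
    length = diff(brk)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit-normalize a vector, erroring on degenerate input.
unitize <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate ", what, " (zero length)")
  v / n
}
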