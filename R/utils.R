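# Internal helpers: classed error conditions and small numeric utilities.

sp_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "selfpred_error", "error", "condition")))
}

config_error <- function(field, msg) {
  sp_stop(sprintf("invalid configuration: field '%s' %s", field, msg),
          "selfpred_config_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-stage 32-bit seed from a global seed without collisions.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, qc = 23L, relmat = 37L, fit = 53L, cv = 71L,
               rank = 89L, ld = 101L, paternity = 127L, mcmc = 151L)
  off <- offsets[[stage]] %||% 997L
  as.integer((as.numeric(seed) * 2654435.0 + off * 97.0) %% 2147483629)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

# Symmetrize a matrix that is symmetric up to round-off.
symmetrize <- function(m) (m + t(m)) / 2

# Effective sample size of an MCMC chain from the initial positive sequence
# of autocorrelations (single chain).
ess <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(as.numeric(n))
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  max(1, n / (1 + 2 * s))
}
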