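# internal validation helpers

.check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be probabilities in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", what, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

.check_mix <- function(p, what) {
  if (is.null(names(p)) || any(names(p) == "")) {
    stop(sprintf("`%s` must be a named vector of proportions", what),
         call. = FALSE)
  }
  .check_prob(p, what)
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("`%s` must sum to 1", what), call. = FALSE)
  }
  invisible(p)
}

# Fisher-z confidence interval for a Pearson correlation
.fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

# derive a sub-seed stream from one master seed (kept below .Machine 32-bit)
.spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
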