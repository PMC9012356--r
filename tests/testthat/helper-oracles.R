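# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Clopper-Pearson by bisection on exact binomial tail sums
cp_bisect <- function(x, n, alpha = 0.05, tol = 1e-10) {
  upper_tail <- function(p) sum(dbinom(x:n, n, p))   # P(X >= x)
  lower_tail <- function(p) sum(dbinom(0:x, n, p))   # P(X <= x)
  bis <- function(f, target) {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (x == 0) 0 else bis(upper_tail, alpha / 2)
  hi <- if (x == n) 1 else bis(function(p) 1 - lower_tail(p), 1 - alpha / 2)
  c(lo, hi)
}

# AUC as the explicit tie-corrected pairwise comparison probability
auc_pairwise <- function(scores, labels, lower_is_diseased = TRUE) {
  x <- if (lower_is_diseased) -scores else scores
  xp <- x[as.logical(labels)]; xn <- x[!as.logical(labels)]
  tot <- 0
  for (a in xp) for (b in xn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xp) * length(xn))
}

# brute-force median over a logical ROI via full sort
median_bruteforce <- function(values, roi) {
  v <- sort(values[roi])
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# phantom cache: heavy fixtures built once per test run
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- make_phantom(spec)
  .phantom_cache[[key]]
}

default_noisy_phantom <- function() {
  cached_phantom("noisy_07",
                 phantom_spec(mcp_target_ratio = 0.07, seed = 421))
}

noiseless_phantom <- function() {
  cached_phantom("clean_07",
                 phantom_spec(mcp_target_ratio = 0.07, noise_sigma = 0,
                              bias_amplitude = 0, seed = 1))
}
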