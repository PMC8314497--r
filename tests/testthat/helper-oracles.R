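# Independent oracles, coded as literal loops / textbook formulas so they
# share no code path with the package internals.

# Literal position-by-position running-sum walk: increment |score|^p / N_R
# at hits, decrement 1/(N - N_hit) at misses; ES = value of maximal |running|
# (first occurrence on ties).
oracle_es_walk <- function(scores, is_hit, weight_p) {
  n <- length(scores)
  n_hit <- sum(is_hit)
  n_r <- sum(abs(scores[is_hit])^weight_p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      cur <- cur + if (n_r > 0) abs(scores[i])^weight_p / n_r else 1 / n_hit
    } else {
      cur <- cur - 1 / (n - n_hit)
    }
    running[i] <- cur
  }
  best <- 1L
  for (i in seq_len(n)) {
    if (abs(running[i]) > abs(running[best])) best <- i
  }
  le <- if (running[best] >= 0) {
    which(is_hit & seq_len(n) <= best)
  } else {
    which(is_hit & seq_len(n) >= best)
  }
  list(es = running[best], peak_index = best, leading_idx = le)
}

# Sum-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Midrank transform by explicit counting, then the Pearson oracle.
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Literal depth-by-depth weighted top/bottom overlap.
oracle_overlap <- function(a, b, alpha, n_top) {
  common <- intersect(a, b)
  a <- a[a %in% common]
  b <- b[b %in% common]
  s <- 0
  for (n in seq_len(n_top)) {
    s <- s + exp(-alpha * n) *
      (length(intersect(head(a, n), head(b, n))) +
         length(intersect(tail(a, n), tail(b, n))))
  }
  s
}

# Chi-square upper tail for even df = 2k, via the closed-form Poisson sum
# P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!.
oracle_chisq_tail_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Small deterministic ranked list for fixtures.
toy_ranking <- function(n = 10, seed = 1) {
  set.seed(seed)
  ranked_genes(setNames(sort(rnorm(n), decreasing = TRUE),
                        sprintf("g%02d", seq_len(n))),
               metric = "pearson", target_id = "LNC")
}

# Tiny cohort for fast end-to-end tests.
small_cohort <- function(seed = 7, n_samples = 60, n_genes = 300,
                         planted_size = 20, n_null_sets = 10) {
  generate_cohort(synthetic_config(
    n_samples = n_samples, n_genes = n_genes,
    planted_sets = list(list(name = "PLANTED", size = planted_size,
                             effect_beta = 1, fraction_responsive = 1)),
    n_null_sets = n_null_sets, null_set_size_range = c(5, 20),
    noise_sd = 0.5, seed = seed))
}
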