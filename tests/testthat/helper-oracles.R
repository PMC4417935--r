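# Independent brute-force oracles used to validate the optimized
# implementations, plus small fixture builders.

# Poly(A) trimming by exhaustive enumeration: for every candidate number of
# kept bases i, score the removed suffix with explicit sums, then apply the
# same keep-more tie break and minimum-trim rule.
oracle_trim <- function(bases, qualities, min_trim = 3) {
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(b)
  scores <- vapply(0:n, function(i) {
    if (i == n) return(0)
    suffix <- (i + 1):n
    a <- suffix[b[suffix] == "A"]
    not_a <- suffix[b[suffix] != "A"]
    sum(qualities[a]) - 3 * sum(qualities[not_a])
  }, numeric(1))
  keep <- max(which(scores == max(scores))) - 1L
  if (n - keep >= min_trim) substr(bases, 1, keep) else bases
}

random_read <- function(max_len = 100, polya_prob = 0.5) {
  n <- sample(5:max_len, 1)
  b <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
              prob = c(0.3, 0.22, 0.22, 0.22, 0.04))
  if (runif(1) < polya_prob) {
    tail_len <- sample(0:min(n - 1, 30), 1)
    if (tail_len > 0) {
      tail_bases <- sample(c("A", "C", "G", "T"), tail_len, replace = TRUE,
                           prob = c(0.85, 0.05, 0.05, 0.05))
      b[(n - tail_len + 1):n] <- tail_bases
    }
  }
  list(bases = paste(b, collapse = ""),
       qualities = sample(2:40, n, replace = TRUE))
}

# Exhaustive two-state path decoding: enumerates all 2^n genotype paths in
# chunks (bit arithmetic, no path matrix held in memory) and returns the
# maximum joint log-likelihood. Independent of the Viterbi recursion.
oracle_best_path_loglik <- function(obs, epsilon = 0.02, transition = 1e-4) {
  n <- length(obs)
  le <- matrix(log(0.5), nrow = 2, ncol = n) # state x gene emission
  known <- !is.na(obs)
  le[1, known] <- ifelse(obs[known] == 0L, log(1 - epsilon), log(epsilon))
  le[2, known] <- ifelse(obs[known] == 1L, log(1 - epsilon), log(epsilon))
  lt <- c(log(1 - transition), log(transition))
  best <- -Inf
  total <- 2^n
  chunk <- 2^min(n, 14)
  for (start in seq(0, total - 1, by = chunk)) {
    codes <- start:(min(start + chunk, total) - 1)
    ll <- rep(log(0.5), length(codes))
    prev <- codes %% 2
    ll <- ll + le[cbind(prev + 1, 1)]
    code <- codes %/% 2
    for (i in seq_len(n - 1)) {
      s <- code %% 2
      ll <- ll + le[cbind(s + 1, i + 1)] + lt[1 + (s != prev)]
      prev <- s
      code <- code %/% 2
    }
    best <- max(best, max(ll))
  }
  best
}

# log-likelihood of the path the package decoded, via the package's own
# scorer (tested separately against manual arithmetic)
path_loglik <- function(path, obs, epsilon = 0.02, transition = 1e-4) {
  aseqtl:::genotype_path_loglik(path, obs, epsilon, transition)
}

# small backcross configuration for fast unit tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_f1_per_direction = 4L, n_n2_f1xb6 = 20L, n_n2_b6xf1 = 26L,
         n_autosomes = 3L, genes_per_chromosome = 30L, seed = seed),
    list(...))
  do.call(simulation_config, args)
}
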