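# Vectorized statistics shared by the testing modules. Both helpers use the
# classical large-sample forms so that genome x marker scans and permutation
# rounds stay cheap; the rank-sum z matches wilcox.test(exact = FALSE,
# correct = TRUE) and the t-test is the ordinary one-sample t.

# One-sample t-test of each row of `d` against 0, NA entries excluded.
row_t_test <- function(d) {
  n <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums(d^2, na.rm = TRUE) - n * m^2
  s2 <- ss / pmax(n - 1, 1)
  tstat <- m / sqrt(s2 / n)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[n < 2 | s2 <= 0] <- NA_real_
  tstat[n < 2 | s2 <= 0] <- NA_real_
  list(t = tstat, p = p, n = n, mean = m)
}

# Row ranks of Y over the columns `cols` (average ranks for ties), plus the
# per-row tie correction term sum(t^3 - t). Vectorized with a single
# order() pass so genome x marker scans stay cheap.
row_ranks <- function(Y, cols) {
  sub <- Y[, cols, drop = FALSE]
  k <- nrow(sub)
  n <- ncol(sub)
  o <- order(row(sub), sub)
  v <- sub[o]
  row_of_o <- rep(seq_len(k), each = n)
  pos <- rep(seq_len(n), times = k)
  new_run <- c(TRUE, diff(v) != 0) | c(TRUE, diff(row_of_o) != 0)
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  starts <- which(new_run)
  avg_rank <- pos[starts] + (run_len - 1) / 2
  rk <- numeric(k * n)
  rk[o] <- avg_rank[run_id]
  dim(rk) <- c(k, n)
  ties <- as.vector(rowsum(run_len^3 - run_len, row_of_o[starts],
                           reorder = FALSE))
  list(ranks = rk, ties = ties, n = n)
}

# Two-sided Wilcoxon rank-sum p-value for every row of a pre-ranked matrix,
# comparing columns where `group` is TRUE against the rest. `rr` comes from
# row_ranks() on the included columns; `group` is relative to those columns.
ranksum_from_ranks <- function(rr, group) {
  n1 <- sum(group)
  n2 <- rr$n - n1
  if (n1 == 0 || n2 == 0) {
    return(list(p = rep(NA_real_, nrow(rr$ranks)),
                U = rep(NA_real_, nrow(rr$ranks))))
  }
  W <- rr$ranks[, group, drop = FALSE] %*% rep(1, n1)
  U <- as.numeric(W) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- rr$n
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - rr$ties / (n * (n - 1)))
  z <- U - mu
  correction <- sign(z) * 0.5
  z <- (z - correction) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 <= 0] <- NA_real_
  p <- pmin(p, 1)
  list(p = p, U = U)
}

# Convenience wrapper: rank-sum test of every row of Y between group TRUE
# and FALSE columns (NA group entries excluded).
row_ranksum_test <- function(Y, group) {
  incl <- which(!is.na(group))
  rr <- row_ranks(Y, incl)
  ranksum_from_ranks(rr, as.logical(group[incl]))
}

# Spearman correlation of each row of Y against x, with the large-sample
# t approximation for the p-value (as cor.test(..., method = "spearman",
# exact = FALSE)). Rows are tested over the columns where both the row and
# x are observed; rows with fewer than `min_n` pairs, or zero variance,
# get NA.
row_spearman <- function(Y, x, min_n = 4) {
  n_genes <- nrow(Y)
  rho <- p <- rep(NA_real_, n_genes)
  n_used <- integer(n_genes)
  for (g in seq_len(n_genes)) {
    ok <- !is.na(Y[g, ]) & !is.na(x)
    n <- sum(ok)
    n_used[g] <- n
    if (n < min_n) next
    yr <- rank(Y[g, ok])
    xr <- rank(x[ok])
    if (stats::sd(yr) == 0 || stats::sd(xr) == 0) next
    r <- stats::cor(yr, xr)
    rho[g] <- r
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p[g] <- if (abs(r) == 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n_used)
}
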