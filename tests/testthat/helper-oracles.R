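# Independent oracles and small fixture builders shared across tests.

# Monte-Carlo oracle for the reversal-class probabilities: brute-force
# sampling of the ratio treat/disease, classified with classify_alpha.
mc_reversal_probs <- function(dd, sd_d, dt, sd_t, n = 1e6, seed = 4242) {
  set.seed(seed)
  alpha <- rnorm(n, dt, sd_t) / rnorm(n, dd, sd_d)
  tab <- table(factor(classify_alpha(alpha), levels = reversal_classes()))
  as.numeric(tab) / n
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# fraction of all size-n signatures drawn from a universe of size N
# whose overlap with a fixed size-K set is >= k.
enum_hyper_tail <- function(N, K, n, k) {
  sigs <- utils::combn(N, n)
  inset <- sigs <= K          # wlog the set is genes 1..K
  mean(colSums(inset) >= k)
}

# Hand step-up BH oracle (independent of bh_adjust's vectorised path).
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) sorted[i] <- min(sorted[i], sorted[i + 1])
  out <- numeric(n)
  out[o] <- pmin(sorted, 1)
  out
}

# A reproducible two-group feature matrix.
make_two_groups <- function(n_per = 30, p = 5, shift = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = shift), n_per))
  list(x = x, groups = factor(rep(c("a", "b"), each = n_per)))
}

# Match detected spots to truth; returns precision and recall at a
# centroid tolerance in px.
match_spots <- function(spots, truth, tol = 4) {
  if (nrow(spots) == 0L)
    return(list(precision = NA_real_, recall = 0))
  d2 <- outer(spots$row, truth$row, "-")^2 + outer(spots$col, truth$col, "-")^2
  list(precision = mean(sqrt(apply(d2, 1L, min)) <= tol),
       recall = mean(sqrt(apply(d2, 2L, min)) <= tol))
}
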