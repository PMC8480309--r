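# Builders and independent oracles shared by the suite.

# expression-set tibble from a genes x (time, replicate) value matrix;
# NA cells become not-detected
toy_expression <- function(values, times, n_rep, layer = "protein",
                           genes = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  tibble::tibble(
    gene = rep(genes, times = length(times) * n_rep),
    time_hai = rep(rep(times, each = n_rep), each = nrow(values)),
    replicate = rep(rep(seq_len(n_rep), length(times)), each = nrow(values)),
    value = as.vector(values)
  ) |> translag::expression_set(layer = layer)
}

# DE-call tibble for delay tests: one row per gene x contrast
toy_calls <- function(calls_by_gene) {
  purrr::imap(calls_by_gene, function(calls, g) {
    tibble::tibble(gene = g, contrast = seq_along(calls), call = calls)
  }) |> purrr::list_rbind()
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# exact rank-sum p by enumeration of all group assignments (no ties)
ranksum_enum_oracle <- function(a, b, alternative = "two_sided") {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(n, length(a))
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- length(a) * (n + 1) / 2
  switch(alternative,
    greater = mean(w_all >= w_obs),
    less = mean(w_all <= w_obs),
    two_sided = min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
  )
}

# exact signed-rank p by enumeration of all 2^n sign assignments
signedrank_enum_oracle <- function(d, alternative = "two_sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  switch(alternative,
    greater = mean(v_all >= v_obs),
    less = mean(v_all <= v_obs),
    two_sided = min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  )
}

# hypergeometric upper tail from first principles (choose products)
hyper_tail_oracle <- function(a, m, n, k) {
  # Pr(X >= a) with X ~ Hypergeom(m annotated, n not, k drawn)
  js <- a:min(m, k)
  js <- js[k - js <= n]
  sum(choose(m, js) * choose(n, k - js)) / choose(m + n, k)
}

# exact pwm window-score tail by enumerating all 4^w words with the same
# per-column integerisation as the scanner
pwm_enum_oracle <- function(p, eps = 1e-3) {
  s_int <- round(log2(p$mat / p$background) / eps)
  w <- p$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- integer(nrow(words))
  probs <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    scores <- scores + s_int[cbind(words[, j], j)]
    probs <- probs * p$background[words[, j]]
  }
  function(score_int) {
    vapply(score_int, function(s) sum(probs[scores >= s]), 1.0)
  }
}

`%||%` <- rlang::`%||%`
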