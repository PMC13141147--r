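# --- independent oracles ----------------------------------------------------

# brute force over all positive-negative pairs, ties half-credited
auroc_oracle <- function(labels, scores) {
  p <- scores[labels == 1]; n <- scores[labels == 0]
  tot <- 0
  for (a in p) for (b in n)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# exhaustive step enumeration over distinct thresholds
aupr_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_tp <- 0; ap <- 0
  for (t in th) {
    tp <- sum(labels == 1 & scores >= t)
    fp <- sum(labels == 0 & scores >= t)
    ap <- ap + (tp - prev_tp) * tp / (tp + fp)
    prev_tp <- tp
  }
  ap / sum(labels == 1)
}

# exact rank-sum p by full enumeration of rank assignments
ranksum_oracle <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  switch(alternative,
         greater = mean(ws >= w_obs),
         less = mean(ws <= w_obs),
         two.sided = min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs))))
}

# exact signed-rank p by enumeration of all sign patterns
signed_rank_oracle <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  switch(alternative,
         greater = mean(vs >= v_obs),
         less = mean(vs <= v_obs),
         two.sided = min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs))))
}
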