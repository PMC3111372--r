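# Independent brute-force oracles used to pin the optimized implementations.
# They share no code with the package internals.

# Exhaustive minimum-variance bipartition over all split positions of the
# sorted array; population variance computed from first principles.
oracle_tdt <- function(samples) {
  L <- sort(samples)
  n <- length(L)
  pvar <- function(x) mean((x - mean(x))^2)
  obj <- vapply(seq_len(n - 1L), function(e)
    pvar(L[1:e]) + pvar(L[(e + 1):n]), numeric(1))
  e <- which.min(obj)
  list(split_index = e, objective = obj[e],
       excluded = e < 2L || e > n - 2L,
       threshold = if (e < 2L || e > n - 2L) NA_real_ else (L[e] + L[e + 1]) / 2)
}

# Weighted class entropy computed through explicit probability tables.
oracle_entropy <- function(reg, tgt, t) {
  side <- ifelse(reg <= t, "do", "up")
  n <- length(reg)
  total <- 0
  for (s in unique(side)) {
    lab <- tgt[side == s]
    p <- table(factor(lab, levels = c(-1, 1))) / length(lab)
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    total <- total + (length(lab) / n) * h
  }
  total
}

# Exhaustive RRT scan over the distinct observed values, skipping
# candidates that leave a side empty; ties -> smallest threshold.
oracle_rrt <- function(reg, tgt) {
  cand <- sort(unique(reg))
  cand <- Filter(function(t) sum(reg <= t) > 0 && sum(reg > t) > 0, cand)
  if (length(cand) == 0) return(NULL)
  ent <- vapply(cand, function(t) oracle_entropy(reg, tgt, t), numeric(1))
  best <- min(ent)
  thr <- min(cand[abs(ent - best) < 1e-12])
  list(threshold = thr, entropy = best)
}

# Six-way enumeration of rule types scored from first principles
# (conditional frequencies), with the documented filters and tie order.
oracle_best_rule <- function(rs, ts, accuracy, scp) {
  n <- length(rs)
  cond <- function(t_val, r_val) {
    idx <- rs == r_val
    if (!any(idx)) return(0)
    mean(ts[idx] == t_val)
  }
  frac <- function(r_val, t_val) sum(rs == r_val & ts == t_val) / n
  cands <- list(
    list(c = 1L,  score = cond(1, 1) * cond(-1, -1), pass = TRUE),
    list(c = -1L, score = cond(-1, 1) * cond(1, -1), pass = TRUE),
    list(c = 2L,  score = cond(1, 1),  pass = frac(1, 1) >= scp - 1e-12),
    list(c = 3L,  score = cond(-1, -1), pass = frac(-1, -1) >= scp - 1e-12),
    list(c = -2L, score = cond(1, -1), pass = frac(-1, 1) >= scp - 1e-12),
    list(c = -3L, score = cond(-1, 1), pass = frac(1, -1) >= scp - 1e-12))
  best <- list(rule_type = 0L, score = 0)
  for (cd in cands) {
    if (!cd$pass || cd$score < accuracy - 1e-12) next
    if (cd$score > best$score + 1e-12) best <- list(rule_type = cd$c, score = cd$score)
  }
  best
}
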