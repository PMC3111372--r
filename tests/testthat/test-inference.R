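p_def <- inference_params(accuracy = 0.75, scp = 0.95, max_delay = 3L)

test_that("lagged alignment pairs regulator sample j with target sample j+w", {
  reg <- 1:6
  tgt <- 11:16
  a0 <- align_lagged(reg, tgt, 0)
  expect_identical(a0$regulator, reg)
  expect_identical(a0$target, tgt)
  a2 <- align_lagged(reg, tgt, 2)
  expect_identical(a2$regulator, 1:4)
  expect_identical(a2$target, 13:16)
  expect_error(align_lagged(reg, tgt, 3), "fewer than 4")
})

test_that("confusion counts follow the rule-type semantics", {
  s <- function(x) ifelse(x == "+", 1L, -1L)
  reg <- s(c("+", "+", "-", "-"))
  tgt_same <- s(c("+", "+", "-", "-"))
  cc <- confusion_counts(reg, tgt_same, 1)
  expect_identical(cc, list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  cc_anti <- confusion_counts(reg, s(c("-", "-", "+", "+")), -1)
  expect_identical(cc_anti, list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  # brute tally over 5 positions
  cc5 <- confusion_counts(s(c("+", "-", "+", "-", "+")),
                          s(c("+", "+", "-", "-", "+")), 1)
  expect_identical(cc5, list(tp = 2L, fp = 1L, tn = 1L, fn = 1L))
  # counts always partition the samples
  set.seed(5)
  for (c in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
    r <- rand_states(9); t <- rand_states(9)
    cc <- confusion_counts(r, t, c)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, 9L)
  }
  expect_error(confusion_counts(reg, tgt_same, 0), "undefined")
  expect_error(confusion_counts(reg, tgt_same[1:3]), "length")
})

test_that("rule scores are predictive values with the SCP filter", {
  perfect <- list(tp = 2L, fp = 0L, tn = 2L, fn = 0L)
  expect_equal(score_rule(perfect, 1, 4, 0.95)$score, 1)
  mixed <- list(tp = 2L, fp = 1L, tn = 1L, fn = 1L)
  expect_equal(score_rule(mixed, 1, 5, 0.95)$score, (2 / 3) * (1 / 2))
  # one-sided: single factor plus coverage requirement
  one <- score_rule(list(tp = 3L, fp = 0L, tn = 1L, fn = 0L), 2, 4, 0.95)
  expect_equal(one$score, 1)
  expect_false(one$passes_scp)    # 3/4 < 0.95
  expect_true(score_rule(list(tp = 4L, fp = 0L, tn = 0L, fn = 0L),
                         2, 4, 1)$passes_scp)
  # 0/0 factors score 0
  expect_equal(score_rule(list(tp = 0L, fp = 0L, tn = 2L, fn = 2L),
                          1, 4, 0.95)$score, 0)
})

test_that("the best rule type is the six-way argmax under both filters", {
  same <- c(1L, 1L, -1L, -1L)
  br <- best_rule_type(same, same, p_def)
  expect_identical(br$rule_type, 1L)   # type 2 is blocked by SCP (2/4 < 0.95)
  expect_equal(br$score, 1)
  br2 <- best_rule_type(same, -same, p_def)
  expect_identical(br2$rule_type, -1L)
  expect_equal(br2$score, 1)
  # nothing above the cut-off -> type 0
  br3 <- best_rule_type(c(1L, -1L, 1L, -1L), c(1L, 1L, -1L, -1L), p_def)
  expect_identical(br3$rule_type, 0L)
  expect_identical(br3$score, 0)
})

test_that("best rule type matches the enumeration oracle on random states", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    rs <- rand_states(n)
    ts <- rand_states(n)
    acc <- sample(c(0.5, 0.75, 0.9), 1)
    scp <- sample(c(0.3, 0.6, 0.95), 1)
    p <- inference_params(accuracy = acc, scp = scp)
    got <- best_rule_type(rs, ts, p)
    want <- oracle_best_rule(rs, ts, acc, scp)
    expect_identical(got$rule_type, want$rule_type)
    expect_equal(got$score, want$score)
  }
})

test_that("label swap symmetry and joint permutation invariance hold", {
  set.seed(29)
  for (i in 1:30) {
    rs <- rand_states(12)
    ts <- rand_states(12)
    a <- best_rule_type(rs, ts, inference_params(accuracy = 0.5, scp = 1))
    b <- best_rule_type(rs, -ts, inference_params(accuracy = 0.5, scp = 1))
    if (abs(a$rule_type) == 1L) {
      expect_identical(b$rule_type, -a$rule_type)
      expect_equal(b$score, a$score)
    }
    perm <- sample(12)
    c_ <- best_rule_type(rs[perm], ts[perm], p_def)
    d <- best_rule_type(rs, ts, p_def)
    expect_identical(c_, d)
  }
})

test_that("scp = 1 never lets a one-sided type through", {
  set.seed(37)
  p1 <- inference_params(accuracy = 0.01, scp = 1)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    br <- best_rule_type(rand_states(n), rand_states(n), p1)
    expect_true(br$rule_type %in% c(-1L, 0L, 1L))
  }
})

test_that("a noiseless planted pair yields a perfect profile assignment", {
  st <- generate_synthetic(3, 10, 1,
                           planted = list(planted_rule("G01", "G02", 2, 1)),
                           seed = 101)
  ds <- st$datasets[[1]]
  prof <- infer_profile(ds, "G02", 2, p_def)
  row <- prof[prof$regulator == "G01", ]
  expect_identical(row$rule_type, 1L)
  expect_equal(row$score, 1)
  expect_identical(nrow(prof), 2L)   # every other gene is a candidate
})

test_that("an excluded target TDT is a precondition violation", {
  v <- matrix(rnorm(25), 5, 5)
  v[1, ] <- c(0, 0, 0, 0, 10)   # optimal split isolates one sample
  ds <- make_ds(v, genes = sprintf("g%d", 1:5))
  expect_error(infer_profile(ds, "g1", 0, inference_params()), "excluded")
})

test_that("constant regulators are assigned type 0", {
  v <- rbind(rep(1, 8), c(0, 0, 0, 0, 1, 1, 1, 1), c(2, 2, 2, 2, 2, 2, 2, 2))
  ds <- make_ds(v, genes = c("flat1", "tgt", "flat2"))
  prof <- infer_profile(ds, "tgt", 0, inference_params())
  expect_true(all(prof$rule_type == 0L))
})

test_that("max_delay 0 emits only simultaneous rules", {
  st <- generate_synthetic(5, 10, 1,
                           planted = list(planted_rule("G01", "G02", 0, 1)),
                           seed = 55)
  rs <- infer_rules(st$datasets[[1]], inference_params(max_delay = 0L))
  expect_true(all(rs$rules$delay == 0L))
})

test_that("a dataset whose every TDT is excluded yields no rules", {
  v <- matrix(0, 4, 5)
  v[, 5] <- 10          # every gene: one isolated high sample
  v <- v + outer(1:4, rep(0, 5))   # keep rows distinct
  ds <- make_ds(v, genes = sprintf("g%d", 1:4))
  rs <- infer_rules(ds, inference_params(max_delay = 0L))
  expect_identical(nrow(rs$rules), 0L)
  expect_identical(nrow(rs$exclusions), 4L)
})

test_that("every ordered gene pair is considered exactly once per delay", {
  st <- generate_synthetic(6, 10, 1, seed = 77)
  prof <- infer_profile(st$datasets[[1]], "G03", 1, p_def)
  expect_identical(sort(prof$regulator), sort(setdiff(st$datasets[[1]]$genes, "G03")))
})
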