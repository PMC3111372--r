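test_that("the generator is deterministic in its seed", {
  a <- generate_synthetic(6, 10, 2, seed = 5)
  b <- generate_synthetic(6, 10, 2, seed = 5)
  expect_identical(a$datasets[[1]]$values, b$datasets[[1]]$values)
  expect_identical(a$datasets[[2]]$values, b$datasets[[2]]$values)
  c_ <- generate_synthetic(6, 10, 2, seed = 6)
  expect_false(identical(a$datasets[[1]]$values, c_$datasets[[1]]$values))
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_synthetic(4, 8, 1, seed = 2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planted thresholds are recovered by the discretization layer", {
  st <- generate_synthetic(4, 12, 1,
                           planted = list(planted_rule("G01", "G02", 0, 1)),
                           seed = 19)
  ds <- st$datasets[[1]]
  for (g in ds$genes) {
    tdt <- compute_tdt(ds$values[g, ])
    expect_false(tdt$excluded)
    # noiseless two-level signal: split midpoint equals the latent threshold
    expect_equal(tdt$threshold, unname(st$thresholds[g]))
  }
})

test_that("noiseless planted rules of each two-sided type are recovered", {
  planted <- list(planted_rule("G01", "G02", 0, 1),
                  planted_rule("G03", "G04", 2, -1),
                  planted_rule("G05", "G06", 3, 1))
  st <- generate_synthetic(8, 14, 1, planted = planted, seed = 23)
  rs <- infer_rules(st$datasets[[1]],
                    inference_params(accuracy = 0.75, scp = 0.95,
                                     max_delay = 3L))
  rec <- recovery_metrics(rs, st)
  expect_equal(rec$sensitivity, 1)
  # each planted statement is present with a perfect score
  for (pr in planted) {
    hit <- rs$rules[rs$rules$regulator == pr$regulator &
                    rs$rules$target == pr$target &
                    rs$rules$delay == pr$delay, ]
    expect_identical(hit$rule_type, pr$rule_type)
    expect_equal(hit$score, 1)
  }
})

test_that("a delay-0 two-sided rule records its implied mirror as truth", {
  st <- generate_synthetic(4, 10, 1,
                           planted = list(planted_rule("G01", "G02", 0, 1)),
                           seed = 29)
  expect_identical(nrow(st$rules), 2L)
  expect_setequal(st$rules$regulator, c("G01", "G02"))
  expect_identical(sum(st$rules$implied), 1L)
})

test_that("low-fidelity rules fall below the accuracy cut-off", {
  st <- generate_synthetic(4, 16, 1,
                           planted = list(planted_rule("G01", "G02", 1, 1,
                                                       fidelity = 0.5)),
                           seed = 31)
  rs <- infer_rules(st$datasets[[1]],
                    inference_params(accuracy = 0.75, scp = 0.95,
                                     max_delay = 1L))
  hit <- rs$rules[rs$rules$regulator == "G01" & rs$rules$target == "G02" &
                  rs$rules$delay == 1L, ]
  expect_identical(nrow(hit), 0L)
})

test_that("consensus requires the rule in enough datasets", {
  planted <- list(planted_rule("G01", "G02", 1, 1))
  with_rule <- generate_synthetic(6, 12, 2, planted = planted, seed = 37)
  without <- generate_synthetic(6, 12, 1, seed = 38)
  p <- inference_params(accuracy = 0.75, scp = 0.95, max_delay = 1L)
  sets <- c(lapply(with_rule$datasets, infer_rules, params = p),
            lapply(without$datasets, infer_rules, params = p))
  key <- function(df) paste(df$regulator, df$target, df$delay, df$rule_type)
  # support 2 of 3 < strict intersection
  strict <- consensus_rules(sets, rca = 1)
  expect_false("G01 G02 1 1" %in% key(strict$rules))
  # but passes at rca = 2/3
  loose <- consensus_rules(sets, rca = 2 / 3)
  expect_true("G01 G02 1 1" %in% key(loose$rules))
})

test_that("recovery sensitivity does not improve as noise grows", {
  planted <- list(planted_rule("G01", "G02", 1, 1),
                  planted_rule("G03", "G04", 0, -1))
  sens_at <- function(noise) {
    mean(vapply(1:4, function(s) {
      st <- generate_synthetic(6, 12, 1, planted = planted,
                               noise_sd = noise, margin = 1, seed = 100 + s)
      rs <- infer_rules(st$datasets[[1]],
                        inference_params(accuracy = 0.75, scp = 0.95,
                                         max_delay = 1L))
      recovery_metrics(rs, st)$sensitivity
    }, numeric(1)))
  }
  s0 <- sens_at(0)
  s_mid <- sens_at(0.6)
  s_hi <- sens_at(1.5)
  expect_equal(s0, 1)
  expect_lte(s_hi, s0)
  expect_lte(s_hi, s_mid + 0.25)   # trend, allowing seed-ensemble noise
})

test_that("generator validates its inputs", {
  expect_error(generate_synthetic(4, 7, 1), "at least 8")
  expect_error(generate_synthetic(4, 8, 1,
                                  planted = list(planted_rule("G01", "G02", 5, 1))),
               "exceeds m - 4")
  expect_error(generate_synthetic(4, 10, 1,
                                  planted = list(planted_rule("G01", "G09", 0, 1))),
               "outside")
  expect_error(
    generate_synthetic(4, 10, 1,
                       planted = list(planted_rule("G01", "G02", 0, 1),
                                      planted_rule("G03", "G02", 1, 1))),
    "at most one")
  expect_error(planted_rule("A", "A", 0, 1))
  expect_error(planted_rule("A", "B", 0, 0))
})

test_that("missing-value injection flows through imputation", {
  st <- generate_synthetic(6, 12, 1, missing_prob = 0.05, seed = 41)
  v <- st$datasets[[1]]$values
  expect_gt(sum(is.na(v)), 0)
  imp <- impute_missing(st$datasets[[1]], "row_mean")
  expect_false(anyNA(imp$values))
})

test_that("synthetic datasets and truth serialize to a directory", {
  st <- generate_synthetic(4, 10, 2,
                           planted = list(planted_rule("G01", "G02", 1, -1)),
                           seed = 43)
  dir <- withr::local_tempdir()
  write_synthetic_truth(st, dir)
  expect_true(file.exists(file.path(dir, "synth01.tsv")))
  expect_true(file.exists(file.path(dir, "synth02.tsv")))
  truth <- read_rules(file.path(dir, "truth_rules.tsv"))
  expect_identical(nrow(truth), 1L)
  expect_identical(truth$rule_string, "+/- G01 1 -> -/+ G02")
  expect_true(truth$planted)
  back <- read_expression(file.path(dir, "synth01.tsv"))
  expect_identical(back$values, st$datasets[[1]]$values)
})
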