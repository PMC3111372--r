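# Small fixture builders (everything is generated in code).

make_ds <- function(values, name = "toy", genes = NULL, interval = NULL) {
  if (!is.null(genes)) rownames(values) <- genes
  expression_dataset(values, name = name, sampling_interval = interval)
}

# Random +1/-1 state vector
rand_states <- function(n) sample(c(-1L, 1L), n, replace = TRUE)

# The 33 rules of a published yeast cell-cycle run, used as a fixed
# projection example: (regulator, delay, target, type sign).
yeast_rules_33 <- function() {
  txt <- c(
    "CLB1 0 CLB2 1",  "CLB1 3 CLB5 1",  "CLB1 3 CLB6 1",  "CLB1 0 CLN2 -1",
    "CLB1 0 SWI5 1",  "CLB2 0 CDC20 1", "CLB2 0 CLB1 1",  "CLB2 3 CLB5 1",
    "CLB2 3 CLB6 1",  "CLB2 0 CLN2 -1", "CLB2 0 SWI5 1",  "CLB5 4 CLB2 1",
    "CLB5 0 CLB6 1",  "CLB5 3 CLB6 -1", "CLB6 0 CLB1 -1", "CLB6 0 CLB5 1",
    "CLB6 3 CLB5 -1", "CLB6 0 CLN2 1",  "CLB6 1 CLN2 1",  "CLN1 0 CLB6 1",
    "CLN1 2 CLB6 -1", "CLN1 0 CLN2 1",  "CLN2 4 CLB2 1",  "CLN2 0 CLB5 1",
    "CLN2 0 CLB6 1",  "CLN2 2 CLB6 -1", "CLN2 3 CLB6 -1", "SIC1 0 CLB5 1",
    "SWI4 0 CLB5 1",  "SWI4 4 CLB5 -1", "SWI5 0 CDC20 1", "SWI5 0 CLB2 1",
    "SWI5 3 CLB6 1")
  parts <- do.call(rbind, strsplit(txt, " ", fixed = TRUE))
  data.frame(regulator = parts[, 1], delay = as.integer(parts[, 2]),
             target = parts[, 3], rule_type = as.integer(parts[, 4]),
             score = 1, stringsAsFactors = FALSE)
}
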