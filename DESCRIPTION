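Package: lagrules
Title: Time-Lagged Gene Regulatory Rule Mining from Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-free inference of time-lagged pairwise regulation rules
    from one or more gene-expression time-series matrices.  Target genes are
    discretized with an adaptive minimum-variance bipartition threshold and
    candidate regulators with per-gene-pair entropy-minimizing thresholds;
    seven qualitative rule types spanning arbitrary time delays are scored
    with a positive/negative predictive value performance function and
    filtered by accuracy and sample-coverage parameters.  Rules inferred
    independently from several datasets are combined by a consensus step
    requiring support in a minimum fraction of datasets.  Includes an
    evaluation layer benchmarking predicted gene pairs against scored
    reference pair sets, and a synthetic time-series generator with planted
    lagged rules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
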