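# Diversity statistics against hand-computed values and brute-force
# oracles, QC/filter boundaries, and the downsampling law.

bf_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n * sum(x))
}

test_that("clonality matches hand-computed entropy values", {
  expect_equal(clonality(rep(0.25, 4)), 0)
  # H = -(0.8 ln 0.8 + 2 * 0.1 ln 0.1) = 0.63903186, Hmax = ln 3
  expect_equal(clonality(c(0.8, 0.1, 0.1)), 1 - 0.639031860/log(3),
               tolerance = 1e-9)
  expect_equal(clonality(1), 1)
  expect_equal(clonality(c(5, 5, 10)), clonality(c(0.25, 0.25, 0.5)))
  expect_error(clonality(numeric(0)), "empty")
})

test_that("gini follows the mean-absolute-difference formula", {
  expect_equal(gini(rep(7, 12)), 0)
  expect_equal(gini(c(9, 1)), 0.4)
  expect_error(gini(c(0, 0)), "zero")
  set.seed(7)
  for (i in 1:20) {
    x <- sample(0:30, sample(2:12, 1), replace = TRUE)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini(x), bf_gini(x), tolerance = 1e-12)
  }
  # appending a zero-count clone increases inequality
  x <- c(4, 3, 2)
  expect_gt(gini(c(x, 0)), gini(x))
})

test_that("production efficiency counts nt variants per productive AA", {
  aa <- c("CASSFSGNTIYF", "CASRGDEQYF")
  r1 <- make_rep(aa, c(5, 5))
  expect_equal(production_efficiency(r1), 1.0)
  r2 <- make_rep(rep(aa, each = 3), counts = rep(1, 6),
                 nt = c(fix_nt(aa[1]), fix_nt(aa[1], alt = TRUE),
                        paste0(substr(fix_nt(aa[1]), 1, 33), "TTC"),
                        fix_nt(aa[2]), fix_nt(aa[2], alt = TRUE),
                        paste0(substr(fix_nt(aa[2]), 1, 27), "TTC")))
  expect_equal(production_efficiency(r2), 3.0)
  # nonproductive rows do not contribute
  r3 <- make_rep(c(aa, "CAS*F"), c(5, 5, 99))
  expect_equal(production_efficiency(r3), 1.0)
  r4 <- make_rep("CAS*F", 3)
  expect_error(production_efficiency(r4), "no productive")
})

test_that("QC threshold is strict: below 5000 excluded, exactly 5000 kept", {
  cfg <- analysis_config()
  r_low <- make_rep("CASSFSGNTIYF", 4999)
  r_ok <- make_rep("CASSFSGNTIYF", 5000)
  qlow <- qc_filter_sample(r_low, cfg)
  expect_false(qlow$kept)
  expect_match(qlow$reason, "4999")
  expect_true(qc_filter_sample(r_ok, cfg)$kept)
})

test_that("CDR3 length filter keeps 7-mers, drops 6-mers, preserves counts", {
  r <- make_rep(c("CASSQF", "CASSAQF", "CASSLGQAYEQYF"), c(10, 20, 30))
  f <- filter_cdr3(r, 7)
  expect_setequal(f$rearrangements$cdr3_aa, c("CASSAQF", "CASSLGQAYEQYF"))
  expect_equal(sum(f$rearrangements$count), 50)
  e <- make_rep(character(0), numeric(0), nt = character(0),
                productive = logical(0), v = character(0), j = character(0))
  expect_equal(nrow(filter_cdr3(e)$rearrangements), 0)
})

test_that("downsampling conserves depth, is identity at full depth, errors below", {
  aa <- rand_cdr3(40)
  set.seed(1)
  r <- make_rep(aa, sample(50:200, length(aa), replace = TRUE))
  expect_identical(downsample(r, total_count(r)), r)
  expect_error(downsample(r, total_count(r) + 1), "less than")
  for (i in 1:10) {
    d <- downsample(r, 500)
    expect_equal(total_count(d), 500)
    expect_true(all(d$rearrangements$cdr3_nt %in% r$rearrangements$cdr3_nt))
  }
})

test_that("downsampled clone counts follow the hypergeometric law", {
  # clone at frequency 0.2 of 2500 reads, depth 500: mean 100,
  # var = 500*.2*.8*(2000/2499)
  aa <- rand_cdr3(21)
  r <- make_rep(aa, c(500, rep(100, 20)))
  target <- aa[1]
  set.seed(99)
  draws <- replicate(600, {
    d <- downsample(r, 500)
    pa <- d$rearrangements
    sum(pa$count[pa$cdr3_aa == target])
  })
  m <- 500 * 0.2
  v <- 500 * 0.2 * 0.8 * (2500 - 500) / (2500 - 1)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 600))
  expect_lt(abs(var(draws) - v), 3 * v * sqrt(2 / 599))
})

test_that("cumulative top-N frequencies are correct and nested", {
  r1 <- make_rep("CASSFSGNTIYF", 100)
  expect_equal(unname(cumulative_top_freq(r1, c(10, 100, 1000))),
               c(1, 1, 1))
  aa <- rand_cdr3(20)
  r2 <- make_rep(aa, rep(5, 20))
  expect_equal(unname(cumulative_top_freq(r2, 10)), 0.5)
  set.seed(3)
  r3 <- make_rep(rand_cdr3(500), sample(1:50, 500, replace = TRUE))
  f <- cumulative_top_freq(r3, c(10, 100, 1000))
  expect_true(all(diff(f) >= 0))
  # oracle: sorted cumulative sums
  pa <- productive_aa_counts(r3)
  expect_equal(unname(f["100"]), sum(sort(pa, decreasing = TRUE)[1:100]) / sum(pa),
               tolerance = 1e-12)
})

test_that("length distribution counts unique sequences, not templates", {
  aa <- c("CASSLGQAYEQYF", "CASSLGQAYEQYF", "CASRGDEQYF")
  r <- make_rep(aa, c(50, 30, 1),
                nt = c(fix_nt(aa[1]), fix_nt(aa[1], alt = TRUE),
                       fix_nt(aa[3])))
  ld <- length_distribution(r)
  expect_equal(ld$counts, c("10" = 1L, "13" = 1L))
  expect_equal(sum(ld$counts), length(productive_aa_counts(r)))
  r15 <- make_rep(rand_cdr3(30, 15), rep(2, 30))
  ld15 <- length_distribution(r15)
  expect_equal(names(ld15$counts), "15")
  expect_equal(ld15$median_length, 15)
})

test_that("summaries of a monoclonal repertoire hit the degenerate values", {
  r <- make_rep("CASSLGQAYEQYF", 6000)
  s <- summarize_repertoire(r, analysis_config(downsample_iterations = 3,
                                               rng_seed = 1))
  expect_equal(s$clonality, 1)
  expect_equal(s$max_clone_freq, 1)
  expect_equal(s$gini, 0)
  expect_equal(s$unique_productive_aa, 1)
})

test_that("summaries are reproducible and invariant to row order and dialect", {
  aa <- rand_cdr3(80)
  set.seed(11)
  counts <- sample(30:150, length(aa), replace = TRUE)
  r <- make_rep(aa, counts)
  cfg <- analysis_config(downsample_depth = 2000, downsample_iterations = 5,
                         rng_seed = 42)
  s1 <- summarize_repertoire(r, cfg)
  s2 <- summarize_repertoire(r, cfg)
  expect_identical(s1, s2)
  # permuted input rows
  perm <- sample(length(aa))
  r_perm <- make_rep(aa[perm], counts[perm])
  expect_identical(summarize_repertoire(r_perm, cfg), s1)
  # read back through a dialect file
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rearrangement_table(r, f, "airr")
  r_io <- read_rearrangement_table(f, "airr", sample_id = r$sample_id)
  expect_identical(summarize_repertoire(r_io, cfg), s1)
})

test_that("iteration averaging agrees with a single draw within Monte-Carlo error", {
  aa <- rand_cdr3(200)
  r <- make_rep(aa, rep(30, length(aa)))
  many <- summarize_repertoire(r, analysis_config(
    downsample_depth = 2000, downsample_iterations = 40, rng_seed = 7))
  set.seed(8)
  singles <- replicate(40, summarize_repertoire(r, analysis_config(
    downsample_depth = 2000, downsample_iterations = 1))$clonality)
  expect_lt(abs(many$clonality - mean(singles)),
            3 * sd(singles) / sqrt(length(singles)) +
              3 * sd(singles) / sqrt(40))
})

test_that("clonality and Gini rank two-clone mixtures identically", {
  doms <- seq(0.5, 0.95, by = 0.05)
  cl <- vapply(doms, function(d) clonality(c(d, 1 - d)), 0)
  gi <- vapply(doms, function(d) gini(c(d, 1 - d)), 0)
  expect_true(all(diff(cl) > 0))
  expect_true(all(diff(gi) > 0))
  expect_equal(order(cl), order(gi))
})

test_that("cohort metrics report exclusions with reasons", {
  cfg_g <- generator_config("plhiv", n_participants = 2, n_clones = 400,
                            samples_per_participant = c(2, 2),
                            art_sample_index = 2,
                            total_count_per_sample = 7000, seed = 21)
  co <- generate_cohort(cfg_g)
  # shrink one sample below the QC threshold
  low_id <- names(co$repertoires)[2]
  set.seed(1)
  co$repertoires[[low_id]] <- downsample(co$repertoires[[low_id]], 4000)
  m <- cohort_metrics(co, analysis_config(downsample_depth = 5000,
                                          downsample_iterations = 2,
                                          rng_seed = 2))
  excl <- attr(m, "excluded")
  expect_equal(excl$sample_id, low_id)
  expect_match(excl$reason, "4000")
  expect_false(low_id %in% m$sample_id)
  expect_equal(nrow(m), 3)
  expect_true(all(m$clonality >= 0 & m$clonality <= 1))
})

test_that("mean clonality orders pre-ART > post-ART > control on synthetic cohorts", {
  plhiv <- generate_cohort(generator_config(
    "plhiv", n_participants = 5, n_clones = 2500,
    samples_per_participant = c(6, 8), art_sample_index = 3,
    total_count_per_sample = 15000, seed = 55))
  ctrl <- generate_cohort(generator_config(
    "control", n_participants = 6, n_clones = 5000,
    total_count_per_sample = 15000, seed = 56))
  m <- cohort_metrics(combine_cohorts(plhiv, ctrl),
                      analysis_config(downsample_iterations = 3,
                                      rng_seed = 4))
  means <- tapply(m$clonality, m$group, mean)
  expect_gt(means["pre"], means["post"])
  expect_gt(means["post"], means["control"])
})
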