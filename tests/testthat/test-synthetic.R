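# Generator behaviour: determinism, clone-size laws, convergent
# recombination, length calibration, persistence, post-ART dynamics,
# spiking.

test_that("the generator is deterministic given a seed", {
  cfg <- generator_config("plhiv", n_participants = 2, n_clones = 500,
                          samples_per_participant = c(3, 4),
                          art_sample_index = 2,
                          total_count_per_sample = 3000, seed = 17)
  r1 <- generate_repertoire(cfg, "1001", 2)
  r2 <- generate_repertoire(cfg, "1001", 2)
  expect_identical(r1, r2)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$repertoires, c2$repertoires)
  expect_identical(c1$clinical, c2$clinical)
  # a cohort member equals its standalone counterpart
  expect_identical(c1$repertoires[["1001_T02"]], r1)
})

test_that("generated sequences are valid CDR3s and translate to their AA", {
  cfg <- generator_config("control", n_participants = 1, n_clones = 300,
                          total_count_per_sample = 5000, seed = 2)
  r <- generate_repertoire(cfg, "C001", 1)
  aa <- r$rearrangements$cdr3_aa
  expect_true(all(grepl("^C.*F$", aa)))
  expect_true(all(nchar(aa) >= 6 & nchar(aa) <= 27))
  expect_true(all(nchar(r$rearrangements$cdr3_nt) == 3 * nchar(aa)))
  # translation oracle over a subset
  idx <- seq_len(min(50, nrow(r$rearrangements)))
  tr <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(r$rearrangements$cdr3_nt[idx])))
  expect_equal(tr, aa[idx])
})

test_that("a uniform clone law yields near-zero clonality", {
  cfg <- generator_config("control", n_clones = 1000, clone_law = "uniform",
                          neighbor_rate = 0, convergence_rate = 1,
                          total_count_per_sample = 50000, seed = 3)
  r <- generate_repertoire(cfg, "C001", 1)
  pa <- productive_aa_counts(r)
  expect_lt(clonality(pa / sum(pa)), 0.05)
})

test_that("the dominant-clone frequency is recovered at depth 50000", {
  cfg <- generator_config("plhiv", n_clones = 2000,
                          clone_law = list(type = "powerlaw", exponent = 2),
                          dominant_clone_freq = 0.25,
                          samples_per_participant = c(1, 1),
                          art_sample_index = NA, freq_log_sd = 0,
                          total_count_per_sample = 50000, seed = 4)
  r <- generate_repertoire(cfg, "1001", 1)
  pa <- productive_aa_counts(r)
  expect_lt(abs(max(pa) / sum(pa) - 0.25), 0.05)
})

test_that("measured production efficiency approaches the configured rate", {
  cfg <- generator_config("control", n_clones = 1000, clone_law = "uniform",
                          convergence_rate = 1.5, neighbor_rate = 0,
                          total_count_per_sample = 50000, seed = 5)
  r <- generate_repertoire(cfg, "C001", 1)
  expect_lt(abs(production_efficiency(r) - 1.5) / 1.5, 0.05)
})

test_that("healthy-like repertoires have median CDR3 length 15", {
  cfg <- generator_config("control", n_clones = 4000,
                          total_count_per_sample = 20000, seed = 6)
  r <- generate_repertoire(cfg, "C001", 1)
  expect_equal(length_distribution(r)$median_length, 15)
})

test_that("clonality increases strictly with generator dominance", {
  settings <- list(
    uniform = list(clone_law = "uniform", dominant_clone_freq = 0),
    mild = list(clone_law = list(type = "powerlaw", exponent = 3),
                dominant_clone_freq = 0),
    dominant = list(clone_law = list(type = "powerlaw", exponent = 2),
                    dominant_clone_freq = 0.15))
  means <- vapply(names(settings), function(nm) {
    s <- settings[[nm]]
    mean(vapply(1:10, function(seed) {
      cfg <- generator_config("plhiv", n_clones = 800,
                              clone_law = s$clone_law,
                              dominant_clone_freq = s$dominant_clone_freq,
                              samples_per_participant = c(1, 1),
                              art_sample_index = NA,
                              total_count_per_sample = 8000, seed = seed)
      r <- generate_repertoire(cfg, "X", 1)
      pa <- productive_aa_counts(r)
      clonality(pa / sum(pa))
    }, 0))
  }, 0)
  expect_lt(means["uniform"], means["mild"])
  expect_lt(means["mild"], means["dominant"])
})

test_that("full persistence without noise keeps the dominant clone fixed", {
  cfg <- generator_config("plhiv", n_participants = 1, n_clones = 400,
                          samples_per_participant = c(4, 4),
                          art_sample_index = 3, persistence = 1,
                          freq_log_sd = 0, post_art_diversification = 0,
                          post_art_contraction = 0,
                          total_count_per_sample = 6000, seed = 7)
  co <- generate_cohort(cfg)
  tops <- vapply(co$repertoires, function(r)
    names(productive_aa_counts(r))[1], "")
  expect_equal(length(unique(tops)), 1L)
  expect_equal(unique(tops), co$truth$participants[["1001"]]$dominant)
})

test_that("without diversification the clone pool never grows after ART", {
  cfg <- generator_config("plhiv", n_participants = 2, n_clones = 300,
                          samples_per_participant = c(5, 5),
                          art_sample_index = 2,
                          post_art_diversification = 0,
                          total_count_per_sample = 4000, seed = 8)
  co <- generate_cohort(cfg)
  for (p in co$truth$participants) {
    expect_true(all(diff(p$n_active) <= 0))
  }
  # and with diversification on, the pool grows post-ART
  cfg2 <- generator_config("plhiv", n_participants = 1, n_clones = 300,
                           samples_per_participant = c(5, 5),
                           art_sample_index = 2,
                           post_art_diversification = 0.1,
                           total_count_per_sample = 4000, seed = 8)
  co2 <- generate_cohort(cfg2)
  expect_true(any(diff(co2$truth$participants[["1001"]]$n_active) > 0))
})

test_that("clinical trajectories step down in viral load and recover CD4", {
  cfg <- generator_config("plhiv", n_participants = 3, n_clones = 200,
                          samples_per_participant = c(6, 6),
                          art_sample_index = 3,
                          total_count_per_sample = 3000, seed = 9)
  co <- generate_cohort(cfg)
  st <- samples_table(co)
  clin <- co$clinical
  clin$group <- st$group[match(paste(clin$participant_id, clin$date),
                               paste(st$participant_id, st$collection_date))]
  pre_vl <- log10(clin$viral_load[clin$group == "pre"])
  post_vl <- log10(clin$viral_load[clin$group == "post"])
  expect_gt(median(pre_vl) - median(post_vl), 2)
  pre_cd4 <- clin$cd4_count[clin$group == "pre"]
  late_cd4 <- clin$cd4_count[clin$group == "post"]
  expect_gt(median(late_cd4), median(pre_cd4))
})

test_that("spiked public clonotypes land in carriers only", {
  cfg <- generator_config("plhiv", n_participants = 6, n_clones = 300,
                          samples_per_participant = c(2, 3),
                          art_sample_index = 2,
                          total_count_per_sample = 4000, seed = 10)
  co <- generate_cohort(cfg)
  rec <- make_db("CASSIVTGPYNEQFF", "CMV", "HLA-B*44")
  carriers <- names(co$mhc)[vapply(co$mhc, function(g)
    hla_match("HLA-B*44", g), TRUE)]
  expect_gt(length(carriers), 0)
  sp <- spike_public_clonotypes(co, rec, spike_freq = 2e-3)
  st <- samples_table(sp)
  for (i in seq_len(nrow(st))) {
    present <- "CASSIVTGPYNEQFF" %in%
      sp$repertoires[[st$sample_id[i]]]$rearrangements$cdr3_aa
    expect_equal(present, st$participant_id[i] %in% carriers)
  }
  expect_error(spike_public_clonotypes(co, make_db("CASSF", "CMV", "junk")),
               "unparseable")
})
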