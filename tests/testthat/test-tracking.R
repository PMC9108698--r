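# Clone tracking, annotation with MHC filtering, specificity propagation,
# public-candidate discovery.

serial_reps <- function() {
  aa <- c("CASSDAMINANTF", "CASSTEADYNNEF", "CASSLATECMMEF")
  list(
    make_rep(aa[1:2], c(80, 20), sample_id = "P1_a", participant_id = "P1",
             date = as.Date("2009-01-01")),
    make_rep(aa[1:2], c(70, 30), sample_id = "P1_b", participant_id = "P1",
             date = as.Date("2010-01-01")),
    make_rep(aa, c(50, 30, 20), sample_id = "P1_c", participant_id = "P1",
             date = as.Date("2011-01-01")))
}

test_that("first_observed splits clones around the ART date", {
  art <- as.Date("2010-06-01")
  tr <- track_top_clones(serial_reps(), art, n = 3)
  by_clone <- tr[!duplicated(tr$cdr3_aa), c("cdr3_aa", "first_observed")]
  expect_equal(by_clone$first_observed[by_clone$cdr3_aa == "CASSDAMINANTF"],
               "pre_art")
  expect_equal(by_clone$first_observed[by_clone$cdr3_aa == "CASSLATECMMEF"],
               "post_art")
  # trajectories carry zeros before a clone appears
  late <- tr[tr$cdr3_aa == "CASSLATECMMEF", ]
  expect_equal(late$frequency[order(late$collection_date)][1:2], c(0, 0))
  # per-timepoint frequencies sum to at most 1
  expect_true(all(tapply(tr$frequency, tr$collection_date, sum) <= 1 + 1e-12))
})

test_that("a monoclonal series yields one trajectory at frequency one", {
  reps <- list(
    make_rep("CASSLGQAYEQYF", 100, sample_id = "M_a", participant_id = "M",
             date = as.Date("2009-01-01")),
    make_rep("CASSLGQAYEQYF", 200, sample_id = "M_b", participant_id = "M",
             date = as.Date("2010-01-01")))
  tr <- track_top_clones(reps, as.Date("2009-06-01"), n = 50)
  expect_equal(unique(tr$cdr3_aa), "CASSLGQAYEQYF")
  expect_equal(tr$frequency, c(1, 1))
})

test_that("tracking refuses a missing ART date but accepts NULL for controls", {
  expect_error(track_top_clones(serial_reps(), as.Date(NA)), "ART start date")
  tr <- track_top_clones(serial_reps(), NULL, n = 2)
  expect_true(all(is.na(tr$first_observed)))
})

test_that("the synthetic dominant clone tracks as a persistent pre-ART clone", {
  cfg <- generator_config("plhiv", n_participants = 1, n_clones = 400,
                          samples_per_participant = c(4, 4),
                          art_sample_index = 2, persistence = 0.95,
                          total_count_per_sample = 6000, seed = 13)
  co <- generate_cohort(cfg)
  tr <- track_cohort(co, n = 10)
  dom <- co$truth$participants[["1001"]]$dominant
  dom_rows <- tr[tr$cdr3_aa == dom, ]
  expect_equal(nrow(dom_rows), 4)
  expect_true(all(dom_rows$frequency > 0))
  expect_equal(unique(dom_rows$first_observed), "pre_art")
})

test_that("annotation labels require the participant to carry the allele", {
  db <- make_db("CASSIVTGPYNEQFF", "CMV", "HLA-B*44")
  with_b44 <- c("HLA-A*02:01:01", "HLA-B*44:03:01")
  without <- c("HLA-A*02:01:01", "HLA-B*07:02:01")
  expect_equal(annotate_cdr3("CASSIVTGPYNEQFF", with_b44, db)$label, "CMV")
  ann <- annotate_cdr3("CASSIVTGPYNEQFF", without, db)
  expect_true(is.na(ann$label))
  expect_equal(nrow(ann$matches), 1)  # match reported, label withheld
  expect_true(is.na(annotate_cdr3("CASSUNSEENF", with_b44, db)$label))
})

test_that("multi-source annotation conflicts resolve by majority then other_public", {
  db <- rbind(make_db("CASSXF", "CMV", "HLA-B*44"),
              make_db("CASSXF", "CMV", "HLA-B*44", epitope = "EP2"),
              make_db("CASSXF", "EBV", "HLA-B*44", db_name = "mcpas"))
  alleles <- "HLA-B*44:02:01"
  expect_equal(annotate_cdr3("CASSXF", alleles, db)$label, "CMV")
  db_tie <- rbind(make_db("CASSXF", "CMV", "HLA-B*44"),
                  make_db("CASSXF", "EBV", "HLA-B*44", db_name = "mcpas"))
  expect_equal(annotate_cdr3("CASSXF", alleles, db_tie)$label, "other_public")
})

test_that("specificity groups propagate likely labels under the MHC filter", {
  db <- make_db("CASSIVTGPYNEQFF", "CMV", "HLA-B*44")
  groups <- structure(list(
    list(group_id = "G1",
         member_cdr3s = c("CASSIVTGPYNEQFF", "CASSIVQGPYNEQFF"),
         predicted_mhc = "HLA-B*44:03")),
    class = "trb_specificity_groups")
  alleles <- c("HLA-B*44:03:01", "HLA-A*02:01:01")
  lab <- propagate_specificity(groups, db, alleles)
  expect_equal(unname(lab["CASSIVQGPYNEQFF"]), "likely_CMV")
  # group with no annotated member propagates nothing
  g2 <- structure(list(list(group_id = "G2",
                            member_cdr3s = c("CASSAAAAF", "CASSAAASF"),
                            predicted_mhc = "HLA-B*44:03")),
                  class = "trb_specificity_groups")
  expect_length(propagate_specificity(g2, db, alleles), 0)
  # predicted restriction conflicting with the seed allele blocks propagation
  g3 <- structure(list(list(group_id = "G3",
                            member_cdr3s = c("CASSIVTGPYNEQFF",
                                             "CASSIVQGPYNEQFF"),
                            predicted_mhc = "HLA-A*02:01")),
                  class = "trb_specificity_groups")
  expect_length(propagate_specificity(g3, db, c(alleles, "HLA-A*02:01:01")), 0)
  # participant lacking the predicted allele blocks propagation too
  expect_length(propagate_specificity(groups, db, "HLA-B*07:02:01"), 0)
})

test_that("public candidates need two carriers and database absence", {
  shared <- "CAWSVLKGETQYF"
  mk <- function(pid, extra, date = as.Date("2010-01-01")) {
    make_rep(c(shared, extra), c(10, rep(5, length(extra))),
             sample_id = paste0(pid, "_a"), participant_id = pid,
             date = date)
  }
  reps <- list(mk("1010", rand_cdr3(5)), mk("1017", rand_cdr3(5)),
               mk("1023", rand_cdr3(5)),
               make_rep(rand_cdr3(6), rep(4, 6), sample_id = "1030_a",
                        participant_id = "1030"))
  mhc <- list(`1010` = c("HLA-B*44:02:01", "HLA-A*01:01:01"),
              `1017` = c("HLA-B*44:02:01", "HLA-A*02:01:01"),
              `1023` = c("HLA-B*44:02:01", "HLA-A*03:01:01"),
              `1030` = c("HLA-B*07:02:01", "HLA-A*01:01:01"))
  co <- make_cohort(reps, art = as.Date("2009-01-01"), mhc = mhc)
  cand <- find_public_candidates(co, dbs = NULL)
  hit <- cand[cand$cdr3_aa == shared, ]
  expect_equal(hit$n_carriers, 3L)
  expect_setequal(hit$carriers[[1]], c("1010", "1017", "1023"))
  expect_equal(unname(hit$detection[[1]]), c(1, 1, 1))
  expect_equal(hit$shared_alleles[[1]], "HLA-B*44:02:01")
  # singleton sequences are not candidates
  expect_false(any(cand$n_carriers < 2))
  # a database listing removes the candidate
  db <- make_db(shared, "other", "HLA-B*44:02")
  cand2 <- find_public_candidates(co, db)
  expect_false(shared %in% cand2$cdr3_aa)
})

test_that("label precedence is direct > likely > candidate_public > private", {
  direct <- "CASSIVTGPYNEQFF"
  likely <- "CASSIVQGPYNEQFF"
  pub <- "CAWSVLKGETQYF"
  priv <- "CASSPRIVATEF"
  mk <- function(pid, aas, sid, date) {
    make_rep(aas, rep(10, length(aas)), sample_id = sid,
             participant_id = pid, date = date)
  }
  reps <- list(mk("P1", c(direct, likely, pub, priv), "P1_a",
                  as.Date("2009-01-01")),
               mk("P1", c(direct, likely, pub, priv), "P1_b",
                  as.Date("2011-01-01")),
               mk("P2", c(pub, rand_cdr3(3)), "P2_a", as.Date("2010-01-01")),
               mk("P2", rand_cdr3(4), "P2_b", as.Date("2011-02-01")))
  mhc <- list(P1 = c("HLA-B*44:03:01"), P2 = c("HLA-B*44:02:01"))
  co <- make_cohort(reps, art = as.Date("2010-06-01"), mhc = mhc)
  db <- make_db(direct, "CMV", "HLA-B*44")
  groups <- structure(list(list(group_id = "G1",
                                member_cdr3s = c(direct, likely),
                                predicted_mhc = "HLA-B*44:03")),
                      class = "trb_specificity_groups")
  tr <- label_trajectories(track_cohort(co, n = 10), co, db, groups)
  lab <- tr$label[match(c(direct, likely, pub, priv), tr$cdr3_aa)]
  expect_equal(lab, c("CMV", "likely_CMV", "candidate_public", "private"))
})

test_that("annotated abundance sums frequencies and MHC filtering only shrinks them", {
  aa <- c("CASSIVTGPYNEQFF", rand_cdr3(4))
  reps <- list(make_rep(aa, c(2, rep(24.5, 4)), sample_id = "P1_a",
                        participant_id = "P1", date = as.Date("2009-01-01")))
  co <- make_cohort(reps, art = as.Date("2010-01-01"),
                    mhc = list(P1 = "HLA-B*07:02:01"))
  db <- make_db("CASSIVTGPYNEQFF", "CMV", "HLA-B*44")
  ab <- annotated_abundance_by_group(co, db)
  cmv <- ab[ab$antigen_source == "CMV", ]
  expect_equal(cmv$frequency[!cmv$mhc_enforced], 0.02)
  expect_equal(cmv$frequency[cmv$mhc_enforced], 0)  # participant lacks B*44
  expect_true(all(ab$frequency[ab$mhc_enforced] <=
                    ab$frequency[!ab$mhc_enforced] + 1e-12))
  # a repertoire with no matches reports zero everywhere
  co2 <- make_cohort(list(make_rep(rand_cdr3(5), rep(2, 5),
                                   sample_id = "Q_a", participant_id = "Q",
                                   date = as.Date("2009-01-01"))),
                     art = as.Date("2010-01-01"), mhc = list(Q = "HLA-A*01:01"))
  expect_true(all(annotated_abundance_by_group(co2, db)$frequency == 0))
})
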