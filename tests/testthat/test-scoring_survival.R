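mk_lfc <- function(values, rnas = c("pos", "neg1", "neg2")) {
  m <- matrix(values, ncol = length(rnas), byrow = TRUE,
              dimnames = list(sprintf("P%d", seq_len(length(values) / length(rnas))),
                              rnas))
  m
}

test_that("composite score follows the +pos -neg -neg convention", {
  lfc <- mk_lfc(c(0, 0, 0,
                  1, 1, 1,
                  2, -1, 0.5))
  cs <- composite_score(lfc, "pos", c("neg1", "neg2"))
  expect_equal(cs$score, c(0, -1, 2.5))
  expect_identical(as.character(cs$group), c("score>=0", "score<0", "score>=0"))
  # linearity / sign flip: negating all three components negates the score
  cs2 <- composite_score(-lfc, "pos", c("neg1", "neg2"))
  expect_equal(cs2$score, -cs$score)
  # missing RNA is named
  expect_error(composite_score(lfc, "pos", c("neg1", "absent")), "absent")
})

test_that("group assignment uses the absolute zero threshold", {
  lfc <- mk_lfc(c(0.2, 0, 0, -0.2, 0, 0))
  cs <- composite_score(lfc, "pos", c("neg1", "neg2"))
  expect_identical(as.character(cs$group), c("score>=0", "score<0"))
  # adding a constant to every score changes groups (threshold is absolute)
  shifted <- lfc; shifted[, "pos"] <- shifted[, "pos"] + 1
  cs2 <- composite_score(shifted, "pos", c("neg1", "neg2"))
  expect_false(identical(cs2$group, cs$group))
})

surv_clinical <- function(ids, death_time, cause, fu) {
  data.frame(patient_id = ids, progression_time = NA_real_,
             death_time = death_time, death_cause = cause, follow_up = fu,
             stringsAsFactors = FALSE)
}

test_that("Kaplan-Meier matches a hand computation and the empirical survival", {
  ids <- sprintf("P%d", 1:10)
  # disease deaths at 5, 10, 20; everyone else followed beyond 30
  cl <- surv_clinical(ids,
                      death_time = c(5, 10, 20, rep(NA, 7)),
                      cause = c(rep("disease", 3), rep("alive", 7)),
                      fu = c(5, 10, 20, rep(40, 7)))
  scores <- data.frame(patient_id = ids, score = rep(-1, 10),
                       group = factor(rep("score<0", 10),
                                      levels = c("score<0", "score>=0")))
  expect_message(r <- km_logrank(scores, cl), "single")
  expect_equal(unname(r$surv_at_horizon["score<0"]), 0.7, tolerance = 1e-12)
  expect_true(is.na(r$logrank_p))
  # without censoring before the last event, KM equals the empirical
  # survivor function at every event time
  sm <- summary(r$fit, times = c(5, 10, 20))
  expect_equal(sm$surv, c(0.9, 0.8, 0.7), tolerance = 1e-12)
})

test_that("no events in a group gives 100% survival; other causes are censored", {
  ids <- sprintf("P%d", 1:8)
  cl <- surv_clinical(ids,
                      death_time = c(4, 8, NA, 25, NA, NA, NA, NA),
                      cause = c("disease", "disease", "alive", "other",
                                rep("alive", 4)),
                      fu = c(4, 8, 50, 25, 50, 50, 50, 50))
  grp <- factor(c(rep("score>=0", 4), rep("score<0", 4)),
                levels = c("score<0", "score>=0"))
  scores <- data.frame(patient_id = ids, score = ifelse(grp == "score<0", -1, 1),
                       group = grp)
  r <- km_logrank(scores, cl)
  expect_equal(unname(r$surv_at_horizon["score<0"]), 1.0)
  # non-disease death at 25 censored, not an event: 2 events among 4
  expect_equal(unname(r$surv_at_horizon["score>=0"]), 0.5, tolerance = 1e-12)
})

test_that("log-rank is symmetric in group labels and null for identical groups", {
  ids <- sprintf("P%d", 1:12)
  times <- rep(c(6, 12, 40), 4)
  cause <- rep(c("disease", "disease", "alive"), 4)
  cl <- surv_clinical(ids,
                      death_time = ifelse(cause == "disease", times, NA),
                      cause = cause, fu = times)
  grp <- factor(rep(c("score<0", "score>=0"), each = 6),
                levels = c("score<0", "score>=0"))
  scores <- data.frame(patient_id = ids, score = ifelse(grp == "score<0", -1, 1),
                       group = grp)
  r <- km_logrank(scores, cl)
  expect_equal(r$logrank_p, 1, tolerance = 1e-10)   # identical groups
  # swap labels: statistic unchanged
  scores2 <- scores
  scores2$group <- factor(ifelse(grp == "score<0", "score>=0", "score<0"),
                          levels = c("score<0", "score>=0"))
  r2 <- km_logrank(scores2, cl)
  expect_equal(r2$logrank_chisq, r$logrank_chisq, tolerance = 1e-10)
})

test_that("planted ED patients score higher than non-ED in a coupled cohort", {
  co <- simulate_cohort(sim_config(n_patients = 40, driver_effect = 1.5,
                                   cbc_coupling = 0.7, seed = 55))
  lfc <- paired_log2fc(detection_filter(co$counts))
  tr <- co$truth
  pos <- tr$driver_rna_ids[tr$driver_sign > 0][1]
  neg <- tr$driver_rna_ids[tr$driver_sign < 0]
  cs <- composite_score(lfc, pos, neg)
  r <- km_logrank(cs, co$clinical, outcomes = outcome_indicators(co$clinical))
  ed <- tr$true_group == "ED"
  expect_gt(median(cs$score[ed]), median(cs$score[!ed]))
  expect_lt(r$wilcoxon_p, 0.05)
})

test_that("over-representation p-values equal the hypergeometric tail", {
  sets <- list(term_a = sprintf("g%d", 1:20),
               term_b = sprintf("h%d", 1:30))
  query <- sprintf("g%d", c(1:5, 100:144))   # 5 of 20 from term_a, |query|=50
  res <- local_ora(query, sets, background_size = 1000)
  # direct hypergeometric tail sum: P(X >= 5), X ~ Hyper(K=20, N-K=980, n=50)
  tail_sum <- sum(vapply(5:20, function(k)
    choose(20, k) * choose(980, 50 - k) / choose(1000, 50), numeric(1)))
  expect_equal(res$p[res$term == "term_a"], tail_sum, tolerance = 1e-10)
  # disjoint query/term -> p = 1
  expect_equal(res$p[res$term == "term_b"], 1)
  # the query exactly equal to a tight term is the most enriched
  res2 <- local_ora(sprintf("g%d", 1:20), sets, background_size = 100)
  expect_identical(res2$term[1], "term_a")
  expect_lt(res2$p[1], 1e-12)
  # FDR is monotone BH
  expect_equal(res2$fdr, p.adjust(res2$p, "BH"))
  # term larger than the universe is a validation error
  expect_error(local_ora(query, sets, background_size = 25), "universe")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  gs <- read_gmt(path)
  expect_identical(gs$setA, c("g1", "g2", "g3"))
  expect_identical(gs$setB, c("g2", "g4"))
})
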