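test_that("dynamics features follow their defining identities", {
  dyn <- derive_cbc_dynamics(toy_cbc())
  expect_equal(dyn$ANC1, 2000)              # sqrt(4000 * 1000)
  expect_equal(dyn$ANC1^2, dyn$ANC0 * dyn$minANC)
  expect_equal(dyn$ANC2, 2000)
  expect_equal(dyn$NLR0, 4000 / 1800)
  expect_equal(dyn$PLR0, 250 / 1800)
  expect_equal(dyn$LMR0, 1800 / 450)
  # Hb2 = Hb0 -> Hb3 = 0
  dyn0 <- derive_cbc_dynamics(toy_cbc(Hb = c(12, 11, 12)))
  expect_equal(dyn0$Hb3, 0)
  # doubling from baseline: natural log by default, base-10 configurable
  d2 <- derive_cbc_dynamics(toy_cbc(ANC = c(2000, 1500, 4000)))
  expect_equal(d2$ANC3, log(2), tolerance = 1e-10)
  d10 <- derive_cbc_dynamics(toy_cbc(ANC = c(2000, 1500, 4000)), log_base = 10)
  expect_equal(d10$ANC3, log10(2), tolerance = 1e-10)
})

test_that("dynamics are scale-consistent per cell type", {
  base <- toy_cbc()
  k <- 3.7
  scaled <- base
  scaled$ANC <- scaled$ANC * k
  a <- derive_cbc_dynamics(base)
  b <- derive_cbc_dynamics(scaled)
  expect_equal(b$ANC0, k * a$ANC0)
  expect_equal(b$minANC, k * a$minANC)
  expect_equal(b$ANC1, k * a$ANC1)
  expect_equal(b$ANC2, k * a$ANC2)
  expect_equal(b$ANC3, a$ANC3)          # log ratio is scale-free
})

test_that("missing panels and nonpositive values are rejected with context", {
  no_week2 <- toy_cbc(weeks = c(0, 1), ANC = c(4000, 1000), PLT = c(250, 150),
                      Hb = c(12, 11), ALC = c(1800, 500), Mo = c(450, 300))
  expect_error(derive_cbc_dynamics(no_week2), "P1.*week-2")
  bad <- toy_cbc(); bad$Hb[2] <- 0
  expect_error(derive_cbc_dynamics(bad), "positive")
})

test_that("outcome groups follow the progression/death timing rules", {
  cl <- data.frame(
    patient_id = c("ed", "prog", "nonprog", "none_late", "none_short"),
    progression_time = c(6, 20, NA, 20, NA),
    death_time = c(10, NA, NA, 25, NA),
    death_cause = c("disease", "alive", "alive", "disease", "alive"),
    follow_up = c(10, 40, 72, 25, 20),
    stringsAsFactors = FALSE)
  grp <- assign_groups(cl)
  expect_identical(grp$group, c(1L, 2L, 3L, NA, NA))
  expect_identical(grp$group_label[1:3], c("ED", "progression", "non-progression"))
  ind <- outcome_indicators(cl)
  expect_identical(ind$ED, c(1L, 0L, 0L, 0L, 0L))
  expect_identical(ind$EP, c(1L, 0L, 0L, 0L, 0L))
  cl$death_time[2] <- 15   # death before progression
  expect_error(assign_groups(cl), "prog")
})

test_that("propensity matching is greedy nearest-neighbour without replacement", {
  # 2 treated, 4 controls; brute-force oracle on the same logistic fit
  d <- data.frame(patient_id = sprintf("S%d", 1:6),
                  arm = c("T", "T", "C", "C", "C", "C"),
                  age = c(50, 60, 49, 58, 70, 40),
                  stringsAsFactors = FALSE)
  m <- propensity_match(d, "arm", "T", "C", covariates = "age", ratio = 2)
  fit <- glm(I(arm == "T") ~ age, data = d, family = binomial())
  lp <- log(fitted(fit) / (1 - fitted(fit)))
  avail <- 3:6
  oracle <- list()
  for (ti in 1:2) {
    picks <- avail[order(abs(lp[avail] - lp[ti]))][1:2]
    avail <- setdiff(avail, picks)
    oracle[[ti]] <- d$patient_id[picks]
  }
  expect_setequal(m$matches$control[m$matches$treated == "S1"], oracle[[1]])
  expect_setequal(m$matches$control[m$matches$treated == "S2"], oracle[[2]])
  expect_false(anyDuplicated(m$matches$control) > 0)
  expect_lte(length(unique(m$matches$treated)), 2)
})

test_that("exchangeable arms match fully with near-zero post-match imbalance", {
  set.seed(7)
  d <- data.frame(patient_id = sprintf("S%02d", 1:40),
                  arm = rep(c("T", "C"), each = 20),
                  age = rep(round(runif(20, 40, 70)), 2),
                  stage = rep(sample(c("II", "III"), 20, TRUE), 2),
                  stringsAsFactors = FALSE)
  m <- propensity_match(d, "arm", "T", "C", covariates = c("age", "stage"))
  expect_identical(length(unique(m$matches$treated)), 20L)
  expect_true(all(abs(m$smd_after) < 0.25))
})

test_that("complete separation falls back to exact stratum matching", {
  d <- data.frame(patient_id = sprintf("S%d", 1:8),
                  arm = rep(c("T", "C"), each = 4),
                  sep = c(1, 1, 1, 1, 0, 0, 0, 0),   # perfectly separates arms
                  stringsAsFactors = FALSE)
  expect_warning(m <- propensity_match(d, "arm", "T", "C", covariates = "sep"),
                 "separation")
  expect_identical(m$method, "exact_strata")
  expect_identical(nrow(m$matches), 0L)   # no shared stratum
})

test_that("group comparisons choose tests by normality and flag by p", {
  # identical samples -> Wilcoxon p = 1
  d <- data.frame(arm = rep(c("A", "B"), each = 5), x = rep(1:5, 2))
  r <- compare_groups(d, "arm", "x")
  expect_equal(r$p, 1)
  # massive separation -> p < 0.001 with the right direction
  set.seed(1)
  d2 <- data.frame(arm = rep(c("hi", "lo"), each = 20),
                   x = c(rnorm(20, 10, 1), rnorm(20, 0, 1)))
  r2 <- compare_groups(d2, "arm", "x")
  expect_lt(r2$p, 1e-3)
  expect_identical(r2$direction, "A>B")
  # symmetry: swapping arm labels preserves p, flips direction
  d3 <- d2; d3$arm <- ifelse(d2$arm == "hi", "z_hi", "a_lo")
  r3 <- compare_groups(d3, "arm", "x")
  expect_equal(r3$p, r2$p)
  expect_identical(r3$direction, "A<B")
  # zero variance in both arms -> skipped with note
  d4 <- data.frame(arm = rep(c("A", "B"), each = 3), x = rep(2, 6))
  r4 <- compare_groups(d4, "arm", "x")
  expect_match(r4$note, "skipped")
  expect_true(is.na(r4$p))
})

test_that("a coupled synthetic cohort reproduces the ED-arm neutrophil excess", {
  co <- simulate_cohort(sim_config(n_patients = 40, cbc_coupling = 0.7, seed = 5))
  dyn <- derive_cbc_dynamics(co$cbc)
  dyn$ed_arm <- factor(ifelse(co$truth$true_group == "ED", "ED", "nonED"),
                       levels = c("ED", "nonED"))
  r <- compare_groups(dyn, "ed_arm", c("ANC1", "Hb1"))
  expect_identical(r$direction[r$variable == "ANC1"], "A>B")  # ANC1 up in ED
  expect_lt(r$p[r$variable == "ANC1"], 0.05)
  expect_identical(r$direction[r$variable == "Hb1"], "A<B")   # anaemia in ED
})
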