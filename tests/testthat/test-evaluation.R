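test_that("concordance index matches its examples and tie rules", {
  expect_equal(concordance_index(c(4, 3, 2, 1), 1:4, rep(1, 4)), 1)
  expect_equal(concordance_index(rep(2, 4), 1:4, rep(1, 4)), 0.5)
  expect_equal(concordance_index(c(4, 3, 1, 2), 1:4, rep(1, 4)), 5 / 6)
  expect_error(concordance_index(1, 5, 1), "no comparable")
  expect_error(concordance_index(c(1, 2), c(3, 4), c(0, 0)), "no comparable")
  # a censor preceding every event leaves no comparable pair
  expect_error(concordance_index(c(2, 1), c(1, 5), c(0, 1)), "no comparable")
  # event before a later censor is comparable; discordant here
  expect_equal(concordance_index(c(2, 1), c(5, 1), c(0, 1)), 0)
  expect_equal(concordance_index(c(1, 2), c(5, 1), c(0, 1)), 1)
})

test_that("concordance equals the brute-force pairwise oracle", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    risk <- sample(round(runif(n, 0, 5), 1))  # ties in score
    time <- sample(round(rexp(n, 0.1), 0))    # ties in time
    status <- rbinom(n, 1, 0.7)
    if (sum(status) == 0) next
    expect_equal(concordance_index(risk, time, status),
                 brute_cindex(risk, time, status))
  }
})

test_that("concordance is invariant under strictly monotone risk transforms", {
  set.seed(5)
  n <- 80
  risk <- runif(n); time <- rexp(n); status <- rbinom(n, 1, 0.6)
  c1 <- concordance_index(risk, time, status)
  expect_equal(concordance_index(exp(3 * risk) + 2, time, status), c1)
  expect_equal(concordance_index(rank(risk), time, status), c1)
})

test_that("stratified repeated CV produces balanced, deterministic splits", {
  strata <- rep(c("A", "B", "C"), times = c(40, 35, 25))
  sp <- cv_splits(strata, folds = 5, repeats = 10, seed = 3)
  expect_length(sp, 50L)
  # within each repeat the test folds partition the cohort
  for (r in 1:10) {
    tests <- unlist(lapply(sp[vapply(sp, function(s) s$repeat_, 0) == r],
                           `[[`, "test"))
    expect_setequal(tests, seq_along(strata))
    expect_equal(length(tests), length(strata))
  }
  # stratum proportions preserved within one member
  for (s in sp[1:5]) {
    tab <- table(strata[s$test])
    expect_true(all(abs(tab - c(8, 7, 5)) <= 1))
  }
  expect_identical(cv_splits(strata, 5, 2, seed = 7),
                   cv_splits(strata, 5, 2, seed = 7))
  expect_false(identical(cv_splits(strata, 5, 1, seed = 1),
                         cv_splits(strata, 5, 1, seed = 2)))
  # n = 10, 5 folds -> every test set of size 2
  sp10 <- cv_splits(rep("x", 10), folds = 5, repeats = 1, seed = 1)
  expect_true(all(vapply(sp10, function(s) length(s$test), 0) == 2))
  expect_warning(cv_splits(c(rep("A", 9), "B"), folds = 5, repeats = 1),
                 "smaller than fold")
})

test_that("endpoint extraction maps states to EFS/OS events", {
  h <- data.frame(patient_id = c("a", "a", "b", "b", "c"),
                  state = c("S0", "S1", "S0", "S3", "S0"),
                  entry_time = c(0, 5, 0, 6, 0))
  fu <- c(a = 30, b = 40, c = 20)
  efs <- extract_endpoint(h, fu, "EFS")
  expect_equal(efs$time, c(5, 40, 20))
  expect_equal(efs$status, c(1L, 0L, 0L))
  os <- extract_endpoint(h, fu, "OS")
  expect_equal(os$status, c(0L, 0L, 0L))
  h2 <- rbind(h, data.frame(patient_id = "a", state = "S5", entry_time = 9))
  os2 <- extract_endpoint(h2, fu, "OS")
  expect_equal(os2$time[1], 9)
  expect_equal(os2$status[1], 1L)
})

test_that("calibration table contrasts predicted and KM-observed risk", {
  set.seed(21)
  n <- 3000
  lam <- runif(n, 0.005, 0.08)
  horizon <- 24
  risk <- 1 - exp(-lam * horizon)  # true event probability, no censoring
  time <- rexp(n) / lam
  status <- as.integer(time <= 60)
  time <- pmin(time, 60)
  tab <- calibration_table(risk, time, status, horizon = horizon, bins = 5)
  expect_equal(nrow(tab), 5L)
  filled <- !is.na(tab$observed) & tab$n > 100
  expect_true(all(abs(tab$predicted[filled] - tab$observed[filled]) <
                    3 * sqrt(0.25 / tab$n[filled])))
  # single bin = overall event rate at the horizon
  tab1 <- calibration_table(risk, time, status, horizon = horizon, bins = 1)
  expect_equal(tab1$observed, mean(time <= horizon & status == 1),
               tolerance = 0.02)
  # all risks in one bin -> other bins reported NA, not dropped
  tab2 <- calibration_table(rep(0.35, 50), time[1:50], status[1:50],
                            horizon, bins = 10)
  expect_equal(sum(!is.na(tab2$predicted)), 1L)
  expect_equal(nrow(tab2), 10L)
  expect_error(calibration_table(1.2, 5, 1), "\\[0, 1\\]")
})

test_that("ablation validates blocks and sees a null block as ~0", {
  co <- small_cohort()
  expect_error(ablation(co, blocks = c("age", "age")), "duplicate")
  expect_error(ablation(co, blocks = "nonsense"), "unknown block")
  ab <- ablation(co, blocks = "other_clinical",
                 folds = 3, repeats = 1, seed = 2)
  # other_clinical carries no true effect in the synthetic world
  expect_true(all(abs(ab$delta) < 0.06))
})

test_that("an uninformative design gives chance-level concordance", {
  co <- small_cohort()
  cfg <- multistate_config(masked_blocks = feature_blocks(), seed = 3)
  rep <- evaluate_cv(co, cfg, folds = 3, repeats = 1, seed = 3)
  m <- rep$cindex[rep$model == "multistate"]
  expect_true(all(abs(m - 0.5) < 0.08))
})

test_that("knowledge-bank prediction works without refitting", {
  co <- small_cohort()
  fit <- small_fit()
  expect_error(knowledge_bank_predict(fit, list(clinical = co$clinical[, 1:3])),
               "schema mismatch")
  kb <- knowledge_bank_predict(fit, co)
  expect_true(all(kb$predictions$risk_efs >= 0 & kb$predictions$risk_efs <= 1))
  expect_equal(nrow(kb$report), 2L)
  # in-sample application reproduces the in-sample risk ordering
  sc <- mmstate:::.risk_scores(fit, co)
  expect_equal(kb$predictions$risk_os, unname(sc$os))
  # an external cohort from the same generator scores comparably
  ext <- simulate_cohort(n = 300, seed = 777)
  kb2 <- knowledge_bank_predict(fit, ext)
  expect_true(all(kb2$report$cindex > 0.45))
  # permuted outcomes are chance level
  set.seed(1)
  perm <- ext
  idx <- sample(nrow(ext$clinical))
  perm$clinical$followup_months <- ext$clinical$followup_months[idx]
  old_ids <- ext$clinical$patient_id
  perm$histories <- ext$histories
  perm$histories$patient_id <- old_ids[match(perm$histories$patient_id,
                                             old_ids[idx])]
  kb3 <- knowledge_bank_predict(fit, perm)
  expect_true(all(abs(kb3$report$cindex - 0.5) < 0.07))
})
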