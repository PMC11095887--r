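test_that("copy-number classification follows the absolute-copies thresholds", {
  expect_identical(call_cnv_class(c(0, 1, 2, 3, 4, 7)),
                   c("biallelic-loss", "loss", "neutral", "gain", "amp", "amp"))
  expect_error(call_cnv_class(-1), "non-negative")
  # total and monotone in copy number
  lv <- c("biallelic-loss", "loss", "neutral", "gain", "amp")
  ranks <- match(call_cnv_class(0:10), lv)
  expect_false(is.unsorted(ranks))
  expect_false(anyNA(ranks))
  # configurable baseline shifts the neutral point
  expect_identical(call_cnv_class(4, ploidy_baseline = 4L), "neutral")
})

test_that("hyperdiploidy needs two large gains on distinct odd chromosomes", {
  p <- one_profile(cnv = rbind(cnv_row("PT1", "3", 3, "large"),
                               cnv_row("PT1", "5", 3, "large")))
  expect_true(unname(call_hyperdiploid(p)["PT1"]))
  p <- one_profile(cnv = cnv_row("PT1", "9", 3, "large"))
  expect_false(unname(call_hyperdiploid(p)["PT1"]))
  # even chromosomes never count
  p <- one_profile(cnv = rbind(cnv_row("PT1", "2", 3, "large"),
                               cnv_row("PT1", "4q", 3, "large")))
  expect_false(unname(call_hyperdiploid(p)["PT1"]))
  # focal gains never count, and two gains on the same odd chromosome count once
  p <- one_profile(cnv = rbind(cnv_row("PT1", "1q21", 4, "focal"),
                               cnv_row("PT1", "11q", 3, "large"),
                               cnv_row("PT1", "11", 3, "large")))
  expect_false(unname(call_hyperdiploid(p)["PT1"]))
  # masked CNV assay yields NA, not FALSE
  p <- one_profile(assays = data.frame(patient_id = "PT1", mutations = TRUE,
                                       cnv = FALSE, translocations = TRUE,
                                       signatures = TRUE))
  expect_true(is.na(call_hyperdiploid(p)["PT1"]))
})

test_that("allelic status matches exhaustive case enumeration", {
  expect_identical(call_allelic_status("TP53", TRUE, 1L), "biallelic")
  expect_identical(call_allelic_status("TP53", FALSE, 2L), "WT")
  expect_identical(call_allelic_status("TP53", FALSE, 0L), "biallelic")
  expect_error(call_allelic_status("NOTAGENE", TRUE, 1L), "unknown TSG")
  # oracle: brute enumeration over (mutated) x (copies 0..2)
  for (m in c(FALSE, TRUE)) for (cp in 0:2) {
    deleted <- cp < 2
    expected <- if ((m && deleted) || cp == 0) "biallelic"
                else if (m || deleted) "monoallelic" else "WT"
    expect_identical(call_allelic_status("RB1", m, cp), expected)
  }
})

test_that("hyper-APOBEC flagging honours both modes and the tie policy", {
  expect_true(call_hyper_apobec(0.15, "fixed-threshold"))
  expect_false(call_hyper_apobec(0.11, "fixed-threshold"))  # strict >
  expect_equal(sum(call_hyper_apobec(rep(0, 50), "decile")), 0)
  # 1000 distinct positive fractions -> exactly 100 flagged
  fr <- seq_len(1000) / 2000
  expect_equal(sum(call_hyper_apobec(fr, "decile")), 100)
  # zero-evidence patients never flagged even in decile mode
  fr2 <- c(rep(0, 900), seq(0.2, 0.3, length.out = 100))
  flg <- call_hyper_apobec(fr2, "decile")
  expect_equal(sum(flg[1:900]), 0)
  expect_equal(sum(flg), 10)  # top decile of the 100 eligible
  expect_error(call_hyper_apobec(numeric(0)), "empty")
  expect_error(call_hyper_apobec(rep(0.5, 5), "decile"), "at least 10")
  expect_error(call_hyper_apobec(1.2), "\\[0, 1\\]")
})

test_that("feature assembly derives the documented vector", {
  p <- one_profile(
    mutations = rbind(mut_row("PT1", "KRAS"), mut_row("PT1", "TP53")),
    cnv = rbind(cnv_row("PT1", "1q21", 5), cnv_row("PT1", "17p", 1),
                cnv_row("PT1", "13q", 1, "large"),
                cnv_row("PT1", "16q", 1, "large"),
                cnv_row("PT1", "8p", 1, "large")),
    translocations = tra_row("PT1", "NSD2"),
    apobec = 0.2, chromo = TRUE)
  f <- build_features(p)
  expect_s3_class(f, "genomic_features")
  expect_identical(f$gain1q, "amp")
  expect_identical(f$tp53_status, "biallelic")
  expect_true(f$del13q && f$del16q && f$del8p && f$t_NSD2)
  expect_true(f$ras_pathway_mut && f$hyper_apobec && f$chromothripsis_cnvsig)
  expect_identical(f$n_large_deletions, 3L)
  expect_identical(f$n_biallelic_events, 1L)
})

test_that("masked assay classes propagate as masked features", {
  p <- one_profile(mutations = mut_row("PT1", "KRAS"),
                   assays = data.frame(patient_id = "PT1", mutations = TRUE,
                                       cnv = FALSE, translocations = TRUE,
                                       signatures = FALSE))
  f <- build_features(p)
  expect_true(is.na(f$gain1q) && is.na(f$del13q) && is.na(f$hyperdiploid))
  expect_true(is.na(f$n_large_deletions))
  expect_true(is.na(f$hyper_apobec) && is.na(f$chromothripsis_cnvsig))
  # TSG status needs CNV too
  expect_true(is.na(f$tp53_status))
  # unmasked classes still there
  expect_true(f$ras_pathway_mut)
  expect_false(f$t_NSD2)
})

test_that("contradictory CNV calls at one locus raise a consistency error", {
  p <- one_profile(cnv = rbind(cnv_row("PT1", "1q21", 5),
                               cnv_row("PT1", "1q21", 0)))
  expect_error(build_features(p), "contradictory")
})

test_that("feature derivation is deterministic and order-independent", {
  co <- small_cohort()
  pr <- co$drivers
  f1 <- build_features(pr)
  # permute every call table
  set.seed(1)
  pr2 <- pr
  pr2$mutations <- pr$mutations[sample(nrow(pr$mutations)), ]
  pr2$cnv <- pr$cnv[sample(nrow(pr$cnv)), ]
  pr2$translocations <- pr$translocations[sample(nrow(pr$translocations)), ]
  f2 <- build_features(pr2)
  rownames(f1) <- rownames(f2) <- NULL
  expect_identical(f1, f2)
  # idempotent: rebuilding gives the same result
  expect_identical(f1, {f3 <- build_features(pr); rownames(f3) <- NULL; f3})
})
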