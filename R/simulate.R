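#' Simulation configuration
#'
#' The generator states a fixed synthetic world: genomic group mixture
#' weights set to the cohort prevalences of the twelve groups, driver-gene
#' mutation rates matching the reported marginal frequencies (KRAS 24.3%,
#' NRAS 20.1%, BRAF 7.8%, DIS3 9.4%, TENT5C 8.6%, TRAF3 6.6%), group-first
#' feature sampling that reproduces the co-occurrence structure the
#' classifier assumes, independent clinical covariates, an observational
#' treatment-assignment policy, piecewise-constant (exponential)
#' cause-specific transition hazards with known log-hazard effects, and
#' uniform administrative censoring over 24-96 months (bracketing a median
#' follow-up of about 43 months).
#'
#' Free-sampling rates for RAS-pathway genes and DIS3 are adjusted
#' analytically for the groups in which they are forced or excluded, so the
#' cohort-marginal prevalence equals the stated target.
#'
#' @param n cohort size.
#' @param seed integer seed; all randomness flows from it.
#' @param group_weights named numeric over the 12 group labels (renormalized).
#' @param censor_range administrative censoring window in months.
#' @param hazard_spec per-edge truth, see [default_hazard_spec()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 2000L, seed = 1L,
                       group_weights = NULL,
                       censor_range = c(24, 96),
                       hazard_spec = default_hazard_spec()) {
  if (is.null(group_weights)) {
    group_weights <- c(
      MAF_APOBEC = 8.7, NSD2_1q_13q = 5.9, NSD2_13q = 4.3, NSD2_Simple = 1.2,
      `1q_13q` = 3.6, CCND1_Complex = 9.4, CCND1_Simple = 8.9,
      HRD_Complex = 32, HRD_RAS = 9, HRD_Gains = 4.6,
      Multiple_Losses = 8.3, Simple = 3.6)
  }
  stopifnot(setequal(names(group_weights), genomic_group_labels()),
            all(group_weights >= 0))
  w <- group_weights / sum(group_weights)

  ras_target <- c(KRAS = 0.243, NRAS = 0.201, BRAF = 0.078)
  ras_pick <- ras_target / sum(ras_target)
  # forced RAS mass: all of HRD_RAS, half of CCND1_Simple (its RAS flavour)
  forced_mass <- unname(w["HRD_RAS"] + 0.5 * w["CCND1_Simple"])
  # free sampling is disabled in HRD_Gains (RAS-free by definition) and in
  # all of CCND1_Simple (its non-RAS flavours must stay RAS-free)
  excluded_mass <- unname(w["HRD_Gains"] + 0.5 * w["CCND1_Simple"])
  free_denom <- 1 - forced_mass - excluded_mass
  ras_free <- if (free_denom > 1e-9)
    pmax((ras_target - forced_mass * ras_pick) / free_denom, 0)
  else stats::setNames(rep(0, 3), names(ras_target))
  dis3_denom <- unname(1 - w["NSD2_1q_13q"])
  dis3_forced <- unname(0.4 * w["NSD2_1q_13q"])
  dis3_free <- if (dis3_denom > 1e-9)
    max((0.094 - dis3_forced) / dis3_denom, 0) else 0
  mut_free <- c(ras_free, DIS3 = dis3_free, TENT5C = 0.086, TRAF3 = 0.066)

  structure(list(n = as.integer(n), seed = as.integer(seed),
                 group_weights = w,
                 ras_pick = ras_pick, mut_free = mut_free,
                 censor_range = censor_range,
                 hazard_spec = hazard_spec),
            class = "sim_config")
}

#' True transition hazards of the synthetic world
#'
#' Baseline rates are per month on each edge's phase clock; `effects` are
#' log-hazard ratios on named design columns (see [build_design()]).
#' Magnitudes follow the cohort's reported event flow: about 15% of patients
#' progress during induction, 7% are lost in phase I, induction completes in
#' about six months, and HDM-ASCT and maintenance reduce the post-induction
#' progression hazard. Effects are deliberately placed on covariates whose
#' Fisher information at the standard fixture size (n = 2000) supports
#' recovery to within +-0.15 (age on every edge; the prevalent genomic and
#' treatment indicators on the event-rich post-induction progression edge).
#'
#' @return named list over default graph edges of `list(base, effects)`.
#' @export
default_hazard_spec <- function() {
  list(
    "S0->S1" = list(base = 0.028, effects = c(age_dec = 0.3)),
    "S0->S2" = list(base = 0.012, effects = c()),
    "S0->S3" = list(base = 0.16, effects = c(age_dec = -0.1, iss3 = -0.2)),
    "S1->S5" = list(base = 0.035, effects = c(age_dec = 0.3)),
    "S3->S4" = list(base = 0.02, effects = c(
      age_dec = 0.15, n_large_deletions = 0.3,
      hdm_asct = -0.45, maintenance = -0.5)),
    "S3->S5" = list(base = 0.0025, effects = c()),
    "S4->S5" = list(base = 0.02, effects = c(age_dec = 0.3))
  )
}

# -- group-conditional driver-call sampling ---------------------------------

# accumulators for long call tables
.acc <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}
.push <- function(a, ...) a$rows[[length(a$rows) + 1L]] <- data.frame(
  ..., stringsAsFactors = FALSE)
.collect <- function(a) if (length(a$rows)) do.call(rbind, a$rows) else NULL

#' Generate driver profiles by group-first sampling
#'
#' Samples a genomic group per patient from the mixture weights, then samples
#' raw driver calls conditional on the group's defining rules so that
#' [build_features()] followed by [classify_genomic_group()] recovers the
#' intended label. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param seed optional override; `NULL` uses the surrounding RNG stream.
#' @return list with `profiles` (a [driver_profiles()]) and `groups`
#'   (data.frame patient_id, group).
#' @export
generate_genomics <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  ids <- sprintf("P%05d", seq_len(n))
  grp <- sample(names(config$group_weights), n, replace = TRUE,
                prob = config$group_weights)

  mut <- .acc(); cnv <- .acc(); tra <- .acc()
  apobec <- numeric(n); chromo <- logical(n)
  odd_chroms <- c("3", "5", "7", "9", "11", "15", "19", "21")
  rbern <- function(m, p) stats::runif(m) < p

  add_mut <- function(pids, gene) if (length(pids))
    .push(mut, patient_id = pids, gene = gene, hotspot = FALSE)
  add_cnv <- function(pids, locus, copies, size) if (length(pids))
    .push(cnv, patient_id = pids, locus = locus, copies = copies,
          size_class = size)
  add_tra <- function(pids, partner) if (length(pids))
    .push(tra, patient_id = pids, partner = partner)

  # >= `k` large odd-chromosome gains per patient (hyperdiploid trisomies)
  add_odd_gains <- function(pids, kmin, kmax) {
    for (pid in pids) {
      k <- sample(kmin:kmax, 1L)
      for (ch in sample(odd_chroms, k)) add_cnv(pid, ch, 3L, "large")
    }
  }
  # `k` distinct large deletions avoiding `avoid` loci; the default pool
  # avoids loci of background-mutated TSGs (1p/TENT5C, 14q/TRAF3) so simple
  # groups cannot acquire accidental biallelic events
  add_large_dels <- function(pids, kmin, kmax,
                             pool = c("16q", "8p", "6q", "20p", "13q"),
                             avoid = character(0)) {
    pool <- setdiff(pool, avoid)
    for (pid in pids) {
      k <- min(sample(kmin:kmax, 1L), length(pool))
      for (lo in sample(pool, k)) add_cnv(pid, lo, 1L, "large")
    }
  }
  # one biallelic TSG hit (mutation + focal deletion at its locus)
  add_biallelic <- function(pids,
                            genes = c("CYLD", "MAX", "TENT5C", "TP53")) {
    reg <- default_registry()$tsg
    for (pid in pids) {
      g <- sample(genes, 1L)
      add_mut(pid, g)
      add_cnv(pid, reg$locus[reg$gene == g], 1L, "focal")
    }
  }
  low_apobec <- function(pids) {
    pos <- pids[rbern(length(pids), 0.35)]
    apobec[match(pos, ids)] <<- stats::runif(length(pos), 0.01, 0.10)
  }
  # del13q / 1q status with the (del13q & 1q gain) combination excluded,
  # which would re-route the label to 1q_13q
  excl_13q_1q <- function(pids, p13 = 0.15, p1q = 0.2) {
    d13 <- rbern(length(pids), p13)
    g1q <- !d13 & rbern(length(pids), p1q)
    add_cnv(pids[d13], "13q", 1L, "large")
    add_cnv(pids[g1q], "1q21", 3L, "focal")
  }
  force_complex <- function(pids, p_chromo = 0.5) {
    ch <- rbern(length(pids), p_chromo)
    chromo[match(pids[ch], ids)] <<- TRUE
    rest <- pids[!ch]
    bia <- rbern(length(rest), 0.4)
    add_biallelic(rest[bia])
    add_large_dels(rest[!bia], 2L, 3L, avoid = "13q")
    # extra instability on top of chromothripsis
    extra <- pids[ch][rbern(sum(ch), 0.5)]
    add_large_dels(extra, 1L, 2L, avoid = "13q")
  }
  force_ras <- function(pids) {
    if (!length(pids)) return()
    g <- sample(names(config$ras_pick), length(pids), replace = TRUE,
                prob = config$ras_pick)
    for (gene in unique(g)) add_mut(pids[g == gene], gene)
  }

  for (g in unique(grp)) {
    pids <- ids[grp == g]
    m <- length(pids)
    switch(g,
      "MAF_APOBEC" = {
        kind <- sample(c("MAF", "MAFB", "apobec"), m, replace = TRUE,
                       prob = c(0.55, 0.15, 0.30))
        add_tra(pids[kind == "MAF"], "MAF")
        add_tra(pids[kind == "MAFB"], "MAFB")
        hi <- kind == "apobec" | rbern(m, 0.6)
        apobec[match(pids[hi], ids)] <- stats::runif(sum(hi), 0.12, 0.35)
        low_apobec(pids[!hi])
        chromo[match(pids[rbern(m, 0.4)], ids)] <- TRUE
        add_large_dels(pids[rbern(m, 0.5)], 1L, 2L)
      },
      "NSD2_1q_13q" = {
        add_tra(pids, "NSD2")
        add_cnv(pids, "13q", 1L, "large")
        amp <- rbern(m, 0.5)
        add_cnv(pids[amp], "1q21", 4L, "focal")
        add_cnv(pids[!amp], "1q21", 3L, "focal")
        add_mut(pids[rbern(m, 0.4)], "DIS3")
        low_apobec(pids)
      },
      "NSD2_13q" = {
        add_tra(pids, "NSD2")
        add_cnv(pids, "13q", 1L, "large")
        low_apobec(pids)
      },
      "NSD2_Simple" = {
        add_tra(pids, "NSD2")
        add_odd_gains(pids[rbern(m, 0.5)], 1L, 1L)
        low_apobec(pids)
      },
      "1q_13q" = {
        add_cnv(pids, "13q", 1L, "large")
        amp <- rbern(m, 0.35)
        add_cnv(pids[amp], "1q21", 4L, "focal")
        add_cnv(pids[!amp], "1q21", 3L, "focal")
        low_apobec(pids)
      },
      "CCND1_Complex" = {
        add_tra(pids, "CCND1")
        force_complex(pids)
        excl_13q_1q(pids, 0.1, 0.3)
        low_apobec(pids)
      },
      "CCND1_Simple" = {
        add_tra(pids, "CCND1")
        flavour <- sample(c("ras", "irf4", "hrd"), m, replace = TRUE,
                          prob = c(0.5, 0.2, 0.3))
        force_ras(pids[flavour == "ras"])
        add_mut(pids[flavour == "irf4"], "IRF4")
        add_odd_gains(pids[flavour == "hrd"], 2L, 3L)
        excl_13q_1q(pids, 0.08, 0.1)
        low_apobec(pids)
      },
      "HRD_Complex" = {
        add_odd_gains(pids, 2L, 5L)
        force_complex(pids, p_chromo = 0.46)
        excl_13q_1q(pids, 0.15, 0.35)
        low_apobec(pids)
      },
      "HRD_RAS" = {
        add_odd_gains(pids, 2L, 4L)
        force_ras(pids)
        excl_13q_1q(pids, 0.1, 0.15)
        low_apobec(pids)
      },
      "HRD_Gains" = {
        add_odd_gains(pids, 2L, 4L)
        gl <- default_registry()$hrd_gain_loci
        for (pid in pids)
          for (lo in sample(gl, sample(2:3, 1L))) add_cnv(pid, lo, 3L, "large")
        excl_13q_1q(pids, 0.08, 0.1)
        low_apobec(pids)
      },
      "Multiple_Losses" = {
        d13 <- rbern(m, 0.4)
        add_large_dels(pids[d13], 2L, 4L,
                       pool = c("13q", "16q", "8p", "6q", "20p"))
        add_cnv(pids[d13], "13q", 1L, "large")
        add_large_dels(pids[!d13], 2L, 4L, avoid = "13q")
        add_cnv(pids[!d13 & rbern(m, 0.3)], "1q21", 3L, "focal")
        chromo[match(pids[rbern(m, 0.4)], ids)] <- TRUE
        add_biallelic(pids[rbern(m, 0.25)])
        add_odd_gains(pids[rbern(m, 0.3)], 1L, 1L)
        low_apobec(pids)
      },
      "Simple" = {
        d13 <- rbern(m, 0.2)
        g1q <- !d13 & rbern(m, 0.15)
        add_cnv(pids[d13], "13q", 1L, "large")
        add_cnv(pids[g1q], "1q21", 3L, "focal")
        add_odd_gains(pids[rbern(m, 0.3)], 1L, 1L)
        # at most one large deletion in total keeps the genome simple
        add_large_dels(pids[!d13 & rbern(m, 0.25)], 1L, 1L, avoid = "13q")
        low_apobec(pids)
      },
      stop("unknown group: ", g))

    # background mutations (free rates; RAS suppressed where forced/excluded)
    ras_ok <- !(g %in% c("HRD_RAS", "HRD_Gains", "CCND1_Simple"))
    for (gene in names(config$mut_free)) {
      if (gene %in% c("KRAS", "NRAS", "BRAF") && !ras_ok) next
      if (gene == "DIS3" && g == "NSD2_1q_13q") next
      add_mut(pids[rbern(m, config$mut_free[[gene]])], gene)
    }
    # monoallelic TP53 variation (mutation XOR del17p, so no accidental
    # biallelic complexity in simple groups); feeds R-ISS/R2-ISS cytogenetics
    u <- stats::runif(m)
    add_mut(pids[u < 0.05], "TP53")
    add_cnv(pids[u >= 0.05 & u < 0.10], "17p", 1L, "focal")
  }

  mut_df <- .collect(mut)
  cnv_df <- .collect(cnv)
  # deduplicate accidental repeated calls (same patient, gene / locus)
  if (!is.null(mut_df))
    mut_df <- mut_df[!duplicated(mut_df[c("patient_id", "gene")]), ]
  if (!is.null(cnv_df))
    cnv_df <- cnv_df[!duplicated(cnv_df[c("patient_id", "locus")]), ]
  sig <- data.frame(patient_id = ids, apobec_fraction = apobec,
                    chromothripsis_cnvsig = chromo,
                    stringsAsFactors = FALSE)
  profiles <- driver_profiles(ids, mut_df, cnv_df, .collect(tra), sig)
  list(profiles = profiles,
       groups = data.frame(patient_id = ids, group = grp,
                           stringsAsFactors = FALSE))
}

#' Simulate clinical covariates
#'
#' Age, beta-2-microglobulin, albumin, LDH ratio, ECOG, sex and race are
#' drawn independently of the genomic group (a stated simplification; the
#' correlation is unreported for real cohorts and a hook exists via editing
#' the returned table).
#'
#' @param ids patient identifiers.
#' @return clinical data.frame (without follow-up, added by the history
#'   simulator).
#' @export
simulate_clinical <- function(ids) {
  n <- length(ids)
  age <- pmin(pmax(round(stats::rnorm(n, 65, 10)), 30), 92)
  # b2m rises with age (renal function), so ISS carries prognostic signal
  # through the age effects even where it has no direct hazard effect
  data.frame(
    patient_id = ids,
    age = age,
    b2m = round(exp(stats::rnorm(n, log(3.5) + 0.3 * (age - 65) / 10, 0.45)), 2),
    albumin = round(pmin(pmax(stats::rnorm(n, 3.9, 0.45), 2), 5.5), 2),
    ldh_ratio = round(exp(stats::rnorm(n, -0.1, 0.25)), 2),
    ecog = sample(0:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.15, 0.1)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45)),
    race = sample(c("White", "Other"), n, replace = TRUE, prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)
}

#' Observational treatment-assignment policy
#' @param ids patient identifiers.
#' @return courses data.frame (patient_id, induction, postinduction).
#' @export
assign_treatment <- function(ids) {
  n <- length(ids)
  data.frame(
    patient_id = ids,
    induction = sample(induction_categories(), n, replace = TRUE,
                       prob = c(0.03, 0.05, 0.12, 0.15, 0.05, 0.07, 0.45, 0.08)),
    postinduction = sample(postinduction_categories(), n, replace = TRUE,
                           prob = c(0.25, 0.20, 0.30, 0.25)),
    stringsAsFactors = FALSE)
}

#' Simulate multi-state event histories from known hazards
#'
#' Cause-specific exponential competing risks per state, with per-patient
#' rates `base * exp(x' effects)` from the phase-appropriate design, the
#' phase-II clock reset at remission entry, and uniform administrative
#' censoring.
#'
#' @param clinical,features,courses cohort tables.
#' @param hazard_spec per-edge truth, see [default_hazard_spec()].
#' @param censor_range uniform censoring window (months).
#' @param seed optional seed; `NULL` continues the surrounding stream.
#' @return list with `histories` (patient_id, state, entry_time) and
#'   `followup` (months, aligned with `clinical`).
#' @export
simulate_histories <- function(clinical, features, courses,
                               hazard_spec = default_hazard_spec(),
                               censor_range = c(24, 96), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (e in names(hazard_spec))
    if (hazard_spec[[e]]$base < 0) stop("negative rate for edge ", e)
  n <- nrow(clinical)
  ids <- clinical$patient_id
  X1 <- build_design(features, clinical, courses, phase = 1L)
  X2 <- build_design(features, clinical, courses, phase = 2L)
  rate <- function(edge, X) {
    hs <- hazard_spec[[edge]]
    if (is.null(hs)) stop("hazard spec missing edge ", edge)
    eff <- hs$effects
    lp <- if (length(eff)) {
      miss <- setdiff(names(eff), colnames(X))
      if (length(miss)) stop("effect on unknown column: ",
                             paste(miss, collapse = ", "))
      drop(X[, names(eff), drop = FALSE] %*% eff)
    } else rep(0, nrow(X))
    hs$base * exp(lp)
  }
  cens <- stats::runif(n, censor_range[1L], censor_range[2L])
  rexp_s <- function(r) ifelse(r > 0, stats::rexp(n) / pmax(r, 1e-300), Inf)

  t01 <- rexp_s(rate("S0->S1", X1))
  t02 <- rexp_s(rate("S0->S2", X1))
  t03 <- rexp_s(rate("S0->S3", X1))
  t0 <- pmin(t01, t02, t03)
  dest <- ifelse(t0 == t01, "S1", ifelse(t0 == t02, "S2", "S3"))
  moved <- t0 < cens

  hist_rows <- list(data.frame(patient_id = ids, state = "S0",
                               entry_time = 0, stringsAsFactors = FALSE))
  add_state <- function(pids, state, times) {
    if (!length(pids)) return(invisible())
    hist_rows[[length(hist_rows) + 1L]] <<- data.frame(
      patient_id = pids, state = state, entry_time = times,
      stringsAsFactors = FALSE)
  }

  # S1 -> S5 on the calendar clock (memoryless: fresh exponential)
  s1 <- moved & dest == "S1"
  add_state(ids[s1], "S1", t0[s1])
  t15 <- rexp_s(rate("S1->S5", X1))
  die1 <- s1 & (t0 + t15) < cens
  add_state(ids[die1], "S5", (t0 + t15)[die1])

  s2 <- moved & dest == "S2"
  add_state(ids[s2], "S2", t0[s2])

  # phase II: clock resets at S3 entry
  s3 <- moved & dest == "S3"
  add_state(ids[s3], "S3", t0[s3])
  t34 <- rexp_s(rate("S3->S4", X2))
  t35 <- rexp_s(rate("S3->S5", X2))
  t3 <- pmin(t34, t35)
  phase_cens <- cens - t0  # remaining follow-up on the reset clock
  s4 <- s3 & t3 < phase_cens & t34 <= t35
  s5d <- s3 & t3 < phase_cens & t35 < t34
  add_state(ids[s4], "S4", (t0 + t3)[s4])
  add_state(ids[s5d], "S5", (t0 + t3)[s5d])
  t45 <- rexp_s(rate("S4->S5", X2))
  die4 <- s4 & (t3 + t45) < phase_cens
  add_state(ids[die4], "S5", (t0 + t3 + t45)[die4])

  histories <- do.call(rbind, hist_rows)
  histories <- histories[order(histories$patient_id, histories$entry_time), ]
  rownames(histories) <- NULL
  list(histories = histories, followup = cens)
}

#' Simulate a complete synthetic cohort
#'
#' Chains [generate_genomics()], [build_features()], [simulate_clinical()],
#' [assign_treatment()] and [simulate_histories()] into a cohort bundle
#' ready for fitting and evaluation. The truth (intended group labels and the
#' hazard spec) is attached for parameter-recovery checks.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param config optional [sim_config()] (overrides `n`/`seed`).
#' @return a `cohort_bundle` list: `clinical` (with `followup_months`),
#'   `drivers`, `features`, `courses`, `histories`, `groups`, `truth`.
#' @export
simulate_cohort <- function(n = 500L, seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(n = n, seed = seed)
  set.seed(config$seed)
  gen <- generate_genomics(config, seed = NULL)
  features <- build_features(gen$profiles)
  clinical <- simulate_clinical(gen$profiles$patient_id)
  courses <- assign_treatment(clinical$patient_id)
  sim <- simulate_histories(clinical, features, courses,
                            config$hazard_spec, config$censor_range,
                            seed = NULL)
  clinical$followup_months <- sim$followup
  structure(list(clinical = clinical, drivers = gen$profiles,
                 features = features, courses = courses,
                 histories = sim$histories, groups = gen$groups,
                 truth = list(hazard_spec = config$hazard_spec,
                              config = config)),
            class = "cohort_bundle")
}

#' Write a bundled acceptance fixture
#'
#' Generates a cohort at a registered size profile and writes the TSV set
#' (clinical, drivers, courses, histories) consumed by the pipeline. The
#' regeneration is byte-identical given the seed.
#'
#' @param profile `"tiny"` (200 patients) or `"standard"` (2000).
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
make_acceptance_fixture <- function(profile = c("tiny", "standard"),
                                    seed = 1L, dir = tempfile("fixture")) {
  profile <- match.arg(profile)
  n <- switch(profile, tiny = 200L, standard = 2000L)
  cohort <- simulate_cohort(n = n, seed = seed)
  write_cohort(cohort, dir)
}
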