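#' Harrell's concordance index
#'
#' Fraction of comparable pairs whose predicted risk orders them correctly.
#' Under right censoring a pair is comparable when the earlier time is an
#' observed event (or when times tie with exactly one event); tied risk
#' scores score 0.5. Invariant under strictly monotone transforms of risk.
#'
#' @param risk numeric risk scores (higher = expected to fail sooner).
#' @param time observed times.
#' @param status 1 = event, 0 = censored.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, time, status) {
  n <- length(risk)
  stopifnot(length(time) == n, length(status) == n)
  d <- as.numeric(status)
  # f[i, j] = 1 when i observably fails before j
  earlier <- outer(time, time, `<`) & (d == 1)
  tied_t <- outer(time, time, `==`) & outer(d == 1, d == 0, `&`)
  f <- earlier | tied_t
  comparable <- sum(f)
  if (!comparable) stop("no comparable pairs: concordance undefined")
  rgt <- outer(risk, risk, `>`)
  req <- outer(risk, risk, `==`)
  (sum(f & rgt) + 0.5 * sum(f & req)) / comparable
}

#' Stratified repeated k-fold splits
#'
#' Within each repeat the test folds partition the cohort and every stratum
#' is spread across folds as evenly as possible (proportions preserved within
#' one member). Deterministic given the seed.
#'
#' @param strata stratum label per subject (length n).
#' @param folds number of folds (>= 2).
#' @param repeats number of random repeats.
#' @param seed integer seed.
#' @return list of `folds x repeats` splits, each
#'   `list(train, test, repeat_, fold)` of integer indices.
#' @export
cv_splits <- function(strata, folds = 5L, repeats = 10L, seed = 1L) {
  stopifnot(folds >= 2L)
  n <- length(strata)
  small <- names(which(table(strata) < folds))
  if (length(small))
    warning("strata smaller than fold count (best-effort allocation): ",
            paste(small, collapse = ", "))
  state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  out <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(n)
    offset <- 0L
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      # rotate the fold sequence so small strata do not pile on fold 1
      fold_of[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      out[[length(out) + 1L]] <- list(train = setdiff(seq_len(n), test),
                                      test = test, repeat_ = r, fold = f)
    }
  }
  out
}

#' Endpoint extraction from multi-state histories
#'
#' EFS events are entries into progression or death states (S1, S4, S5);
#' OS events are entries into death (S5; optionally also phase-I non-disease
#' death S2). Times are months from diagnosis, censored at last follow-up.
#'
#' @param histories long history table.
#' @param followup named follow-up vector (months).
#' @param endpoint `"EFS"` or `"OS"`.
#' @param os_includes_s2 count phase-I loss-to-follow-up/non-disease death as
#'   an OS event (default `FALSE`).
#' @return data.frame (patient_id, time, status).
#' @export
extract_endpoint <- function(histories, followup,
                             endpoint = c("EFS", "OS"),
                             os_includes_s2 = FALSE) {
  endpoint <- match.arg(endpoint)
  ev_states <- if (endpoint == "EFS") c("S1", "S4", "S5")
               else c("S5", if (os_includes_s2) "S2")
  ids <- names(followup)
  ev <- histories[histories$state %in% ev_states, , drop = FALSE]
  t_ev <- tapply(ev$entry_time, ev$patient_id, min)
  time <- unname(followup)
  status <- integer(length(ids))
  hit <- match(ids, names(t_ev))
  has <- !is.na(hit)
  time[has] <- t_ev[hit[has]]
  status[has] <- 1L
  data.frame(patient_id = ids, time = time, status = status,
             stringsAsFactors = FALSE)
}

# risk score at the horizon: 1 - endpoint-free occupation probability
.risk_scores <- function(fit, cohort, idx = NULL, horizon = 60,
                         grid = seq(0, 120, by = 1)) {
  cl <- cohort$clinical
  fx <- cohort$features
  co <- cohort$courses
  if (!is.null(idx)) {
    cl <- cl[idx, , drop = FALSE]
    co <- co[match(cl$patient_id, co$patient_id), , drop = FALSE]
    if (!is.null(fx)) fx <- fx[match(cl$patient_id, fx$patient_id), , drop = FALSE]
  }
  traj <- predict_trajectories(fit, cl, fx, course = co, grid = grid)
  occ <- occupancy_at(traj, horizon)
  list(efs = 1 - rowSums(occ[, c("S0", "S3"), drop = FALSE]),
       os = occ[, "S5"],
       patient_id = cl$patient_id)
}

#' Cross-validated concordance evaluation with staging comparators
#'
#' For each stratified split the multi-state model is refitted on the
#' training fold and 5-year risk (1 - predicted endpoint-free probability)
#' is scored on the test fold. ISS, R-ISS and R2-ISS stage scores are
#' evaluated on the same folds as comparator risk rankings.
#'
#' @param cohort a cohort bundle.
#' @param config a [multistate_config()] for the refits.
#' @param folds,repeats CV geometry (default protocol: 5 x 10).
#' @param seed split seed.
#' @param horizon risk horizon in months.
#' @param grid prediction grid.
#' @return object of class `eval_report`: data.frame (repeat_, fold,
#'   endpoint, model, cindex) with a summary attribute.
#' @export
evaluate_cv <- function(cohort, config = multistate_config(),
                        folds = 5L, repeats = 10L, seed = 1L,
                        horizon = 60, grid = seq(0, 120, by = 1)) {
  cl <- cohort$clinical
  followup <- stats::setNames(cl$followup_months, cl$patient_id)
  eps <- list(EFS = extract_endpoint(cohort$histories, followup, "EFS"),
              OS = extract_endpoint(cohort$histories, followup, "OS"))
  stages <- stage_cohort(cl, cohort$features)
  stage_num <- list(ISS = match(stages$iss, c("I", "II", "III")),
                    `R-ISS` = match(stages$r_iss, c("I", "II", "III")),
                    `R2-ISS` = stages$r2_iss_score)
  strata <- paste(stages$iss, eps$OS$status)
  splits <- cv_splits(strata, folds, repeats, seed)
  rows <- list()
  for (sp in splits) {
    train <- subset_cohort(cohort, sp$train)
    cfg <- config
    cfg$seed <- config$seed + sp$repeat_
    fit <- fit_multistate(train, cfg)
    sc <- .risk_scores(fit, cohort, sp$test, horizon, grid)
    for (ep in c("EFS", "OS")) {
      y <- eps[[ep]][sp$test, ]
      risk <- if (ep == "EFS") sc$efs else sc$os
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = sp$repeat_, fold = sp$fold, endpoint = ep,
        model = "multistate",
        cindex = concordance_index(risk, y$time, y$status))
      for (cmp in names(stage_num))
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = sp$repeat_, fold = sp$fold, endpoint = ep, model = cmp,
          cindex = concordance_index(stage_num[[cmp]][sp$test],
                                     y$time, y$status))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Summarize an evaluation report
#' @param object an `eval_report`.
#' @param ... unused.
#' @return data.frame of mean and quartile c-index per endpoint and model.
#' @export
summary.eval_report <- function(object, ...) {
  agg <- stats::aggregate(cindex ~ endpoint + model, data = object,
                          FUN = function(x)
                            c(mean = mean(x), q1 = unname(stats::quantile(x, .25)),
                              median = stats::median(x),
                              q3 = unname(stats::quantile(x, .75))))
  cbind(agg[c("endpoint", "model")], as.data.frame(agg$cindex))
}

#' Calibration table
#'
#' Bins predicted risks on \[0,1\] and contrasts the mean predicted risk per
#' bin with the Kaplan-Meier observed event probability at the horizon.
#' Empty bins are reported as `NA` rows, not dropped.
#'
#' @param risk predicted event probabilities at `horizon`.
#' @param time,status observed endpoint data.
#' @param horizon months.
#' @param bins number of equal-width bins (default 10).
#' @return data.frame (bin, n, predicted, observed).
#' @export
calibration_table <- function(risk, time, status, horizon = 60, bins = 10L) {
  if (any(risk < 0 | risk > 1)) stop("risks must lie in [0, 1]")
  br <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(risk, br, rightmost.closed = TRUE), 1L), bins)
  out <- data.frame(bin = seq_len(bins),
                    lower = br[-length(br)], upper = br[-1L],
                    n = NA_integer_, predicted = NA_real_,
                    observed = NA_real_)
  for (b in seq_len(bins)) {
    sel <- idx == b
    out$n[b] <- sum(sel)
    if (!any(sel)) next
    out$predicted[b] <- mean(risk[sel])
    km <- survival::survfit(survival::Surv(time[sel], status[sel]) ~ 1)
    s <- summary(km, times = horizon, extend = TRUE)$surv
    out$observed[b] <- 1 - s
  }
  out
}

#' Feature-block ablation
#'
#' Refits and re-evaluates the model with one covariate block masked at a
#' time; the change in mean CV c-index relative to the full model measures
#' the block's contribution, per endpoint.
#'
#' @param cohort cohort bundle.
#' @param blocks block names (see [feature_blocks()]); must be unique.
#' @param config base [multistate_config()].
#' @param folds,repeats,seed,horizon,grid evaluation settings (repeats
#'   defaults low because each block costs a full CV run).
#' @return data.frame (block, endpoint, cindex_full, cindex_masked, delta).
#' @export
ablation <- function(cohort, blocks = feature_blocks(),
                     config = multistate_config(),
                     folds = 5L, repeats = 2L, seed = 1L,
                     horizon = 60, grid = seq(0, 120, by = 1)) {
  if (anyDuplicated(blocks)) stop("duplicate block names")
  unknown <- setdiff(blocks, feature_blocks())
  if (length(unknown)) stop("unknown block(s): ",
                            paste(unknown, collapse = ", "))
  full <- evaluate_cv(cohort, config, folds, repeats, seed, horizon, grid)
  full_mean <- tapply(full$cindex[full$model == "multistate"],
                      full$endpoint[full$model == "multistate"], mean)
  rows <- list()
  for (b in blocks) {
    cfg <- config
    cfg$masked_blocks <- union(config$masked_blocks, b)
    rep_b <- evaluate_cv(cohort, cfg, folds, repeats, seed, horizon, grid)
    m <- tapply(rep_b$cindex[rep_b$model == "multistate"],
                rep_b$endpoint[rep_b$model == "multistate"], mean)
    for (ep in names(m))
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, endpoint = ep,
        cindex_full = unname(full_mean[ep]),
        cindex_masked = unname(m[ep]),
        delta = unname(full_mean[ep] - m[ep]))
  }
  do.call(rbind, rows)
}

#' Knowledge-bank external prediction
#'
#' Applies a fitted model, without refitting, to an external cohort with a
#' compatible schema, returning predicted 5-year risks and external
#' concordance per endpoint.
#'
#' @param fit a `multistate_fit` trained elsewhere.
#' @param external external cohort bundle.
#' @param horizon,grid prediction settings.
#' @return list with `predictions` (patient_id, risk_efs, risk_os) and
#'   `report` (endpoint, cindex, n).
#' @export
knowledge_bank_predict <- function(fit, external, horizon = 60,
                                   grid = seq(0, 120, by = 1)) {
  need <- c("patient_id", "age", "b2m", "albumin", "ldh_ratio", "ecog",
            "sex", "followup_months")
  miss <- setdiff(need, names(external$clinical))
  if (length(miss))
    stop("external cohort schema mismatch; missing clinical columns: ",
         paste(miss, collapse = ", "))
  sc <- .risk_scores(fit, external, NULL, horizon, grid)
  followup <- stats::setNames(external$clinical$followup_months,
                              external$clinical$patient_id)
  rows <- lapply(c("EFS", "OS"), function(ep) {
    y <- extract_endpoint(external$histories, followup, ep)
    risk <- if (ep == "EFS") sc$efs else sc$os
    data.frame(endpoint = ep,
               cindex = concordance_index(risk, y$time, y$status),
               n = nrow(y))
  })
  list(predictions = data.frame(patient_id = sc$patient_id,
                                risk_efs = sc$efs, risk_os = sc$os,
                                stringsAsFactors = FALSE),
       report = do.call(rbind, rows))
}
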