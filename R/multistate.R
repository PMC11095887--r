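#' Configuration for the multi-state risk model
#'
#' @param graph a [build_state_graph()].
#' @param coxnp a [coxnp_config()] shared by all transitions (the seed is
#'   offset per edge so initializations differ but remain reproducible).
#' @param mask_dropout probability of zeroing a training patient's genomic
#'   block (with the mask bit set), teaching the model the no-genomics mode.
#'   Default 0 so that fitted effects are unattenuated; enable (e.g. 0.2)
#'   when the model must also serve genomics-free prediction.
#' @param masked_blocks feature blocks excluded from the design entirely
#'   (used by ablation).
#' @param seed master seed for fitting.
#' @return list of class `multistate_config`.
#' @export
multistate_config <- function(graph = build_state_graph(),
                              coxnp = coxnp_config(),
                              mask_dropout = 0,
                              masked_blocks = character(0),
                              seed = 1L) {
  structure(list(graph = graph, coxnp = coxnp,
                 mask_dropout = mask_dropout,
                 masked_blocks = masked_blocks, seed = as.integer(seed)),
            class = "multistate_config")
}

#' Fit the two-phase multi-state risk model
#'
#' Fits one cause-specific hazard model per graph transition on the
#' transition's phase clock, with phase-appropriate designs: phase-I edges
#' see clinical, genomic and induction covariates; phase-II edges
#' additionally see the HDM-ASCT and maintenance indicators of the patient's
#' course (time-dependent treatment entering at remission). Transitions with
#' zero events are kept as degenerate (zero-hazard) models with a warning.
#'
#' @param cohort list with `clinical` (incl. `followup_months`), `features`
#'   (may be `NULL`), `courses`, `histories` — see [read_cohort()] /
#'   [simulate_cohort()].
#' @param config a [multistate_config()].
#' @return object of class `multistate_fit`.
#' @export
fit_multistate <- function(cohort, config = multistate_config()) {
  graph <- config$graph
  clinical <- cohort$clinical
  validate_histories(cohort$histories, graph)
  followup <- stats::setNames(clinical$followup_months, clinical$patient_id)

  dropout_mask <- NULL
  if (config$mask_dropout > 0) {
    state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(config$seed + 7919L)
    dropout_mask <- stats::runif(nrow(clinical)) < config$mask_dropout
    if (!is.null(state)) assign(".Random.seed", state, globalenv())
  }
  X1 <- build_design(cohort$features, clinical, cohort$courses, phase = 1L,
                     masked_blocks = config$masked_blocks,
                     mask_genomics = dropout_mask)
  X2 <- build_design(cohort$features, clinical, cohort$courses, phase = 2L,
                     masked_blocks = config$masked_blocks,
                     mask_genomics = dropout_mask)
  td <- transition_data(cohort$histories, followup, graph)
  models <- vector("list", nrow(graph$edges))
  names(models) <- graph$edges$id
  for (j in seq_len(nrow(graph$edges))) {
    e <- graph$edges$id[j]
    dat <- td[[e]]
    X <- if (graph$phase[graph$edges$from[j]] == 2L) X2 else X1
    cfg <- config$coxnp
    cfg$seed <- config$coxnp$seed + j
    models[[e]] <- coxnp_fit(X[dat$patient_id, , drop = FALSE], dat, cfg)
  }
  structure(list(models = models, graph = graph, config = config,
                 coefnames = list(phase1 = colnames(X1), phase2 = colnames(X2)),
                 n = nrow(clinical)),
            class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat("multistate_fit over", nrow(x$graph$edges), "transitions, n =", x$n, "\n")
  for (e in names(x$models))
    cat(sprintf("  %-8s events: %5d%s\n", e, x$models[[e]]$n_events,
                if (x$models[[e]]$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Predict individualized state-occupation trajectories
#'
#' Computes per-edge expected hazard increments for each subject under the
#' requested treatment course and chains them through
#' [occupancy_from_hazards()]. Times beyond the fitted baseline support carry
#' zero hazard increments (trajectories go flat); `extrapolated` is flagged
#' on the result.
#'
#' @param fit a `multistate_fit`.
#' @param clinical clinical table for the subjects to predict.
#' @param features their `genomic_features` rows (or `NULL` for the
#'   no-genomics mode).
#' @param course either a 1-row course data.frame (applied to everyone, as in
#'   treatment-variance sweeps) or a per-patient courses table.
#' @param grid uniform month grid (default 0..120 by 1).
#' @param mask_genomics optional logical per-subject genomics mask.
#' @return a [occupancy_from_hazards()] `risk_trajectories` object.
#' @export
predict_trajectories <- function(fit, clinical, features = NULL,
                                 course = NULL, grid = seq(0, 120, by = 1),
                                 mask_genomics = NULL) {
  graph <- fit$graph
  if (is.null(course)) stop("a treatment course (or course table) is required")
  X1 <- build_design(features, clinical, course, phase = 1L,
                     masked_blocks = fit$config$masked_blocks,
                     mask_genomics = mask_genomics)
  X2 <- build_design(features, clinical, course, phase = 2L,
                     masked_blocks = fit$config$masked_blocks,
                     mask_genomics = mask_genomics)
  inc <- vector("list", nrow(graph$edges))
  names(inc) <- graph$edges$id
  extrapolated <- FALSE
  for (j in seq_len(nrow(graph$edges))) {
    e <- graph$edges$id[j]
    m <- fit$models[[e]]
    X <- if (graph$phase[graph$edges$from[j]] == 2L) X2 else X1
    inc[[e]] <- .edge_hazard_increments(m, X, grid)
    if (!m$degenerate && nrow(m$baseline) &&
        max(grid) > max(m$baseline$time)) extrapolated <- TRUE
  }
  out <- occupancy_from_hazards(graph, inc, grid,
                                patient_id = clinical$patient_id)
  attr(out, "extrapolated") <- extrapolated
  out
}
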