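#' Write / read a cohort bundle as TSV files
#'
#' The interchange format is a directory of tab-separated UTF-8 tables with
#' header rows: `clinical.tsv` (patient_id, age, b2m, albumin, ldh_ratio,
#' ecog, sex, race, followup_months), `drivers.tsv` (the driver-call dialect
#' of [write_driver_tsv()]), `courses.tsv` (patient_id, induction,
#' postinduction), `histories.tsv` (patient_id, state, entry_time), and
#' optionally `groups.tsv`. Times are months, 0-based from diagnosis
#' (phase-II rows are still recorded on the diagnosis clock; the reset
#' happens inside the model).
#'
#' @param cohort a `cohort_bundle`.
#' @param dir target directory.
#' @return invisibly, named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(clinical = w(cohort$clinical, "clinical.tsv"),
             courses = w(cohort$courses, "courses.tsv"),
             histories = w(cohort$histories, "histories.tsv"))
  if (!is.null(cohort$drivers)) {
    paths["drivers"] <- file.path(dir, "drivers.tsv")
    write_driver_tsv(cohort$drivers, paths["drivers"])
  }
  if (!is.null(cohort$groups))
    paths["groups"] <- w(cohort$groups, "groups.tsv")
  invisible(paths)
}

#' @rdname write_cohort
#' @param require_genomics error (rather than mask) when drivers.tsv is
#'   absent.
#' @return `read_cohort`: a validated `cohort_bundle`; genomic features are
#'   rebuilt from the driver calls (masked throughout when genomics are
#'   absent — age, ISS inputs and treatment remain mandatory).
#' @export
read_cohort <- function(dir, require_genomics = FALSE) {
  rd <- function(f, required = TRUE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing cohort table: ", p)
      return(NULL)
    }
    utils::read.delim(p, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE)
  }
  clinical <- rd("clinical.tsv")
  courses <- rd("courses.tsv")
  histories <- rd("histories.tsv")
  problems <- character(0)
  mand <- c("patient_id", "age", "b2m", "albumin", "ldh_ratio", "ecog",
            "sex", "followup_months")
  miss <- setdiff(mand, names(clinical))
  if (length(miss))
    problems <- c(problems, paste("clinical.tsv missing mandatory columns:",
                                  paste(miss, collapse = ", ")))
  if (!all(c("patient_id", "induction", "postinduction") %in% names(courses)))
    problems <- c(problems, "courses.tsv must have patient_id, induction, postinduction")
  if (length(problems)) stop(paste(problems, collapse = "\n"))
  if (anyDuplicated(clinical$patient_id))
    stop("duplicate patient_id in clinical.tsv")
  for (nm in c("courses", "histories")) {
    tab <- get(nm)
    extra <- setdiff(unique(tab$patient_id), clinical$patient_id)
    if (length(extra))
      stop(nm, ".tsv has patients absent from clinical.tsv: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  if (!file.exists(file.path(dir, "drivers.tsv")) && require_genomics)
    stop("missing cohort table: ", file.path(dir, "drivers.tsv"))
  drivers <- if (file.exists(file.path(dir, "drivers.tsv")))
    read_driver_tsv(file.path(dir, "drivers.tsv")) else NULL
  features <- if (!is.null(drivers)) build_features(drivers) else NULL
  groups <- rd("groups.tsv", required = FALSE)
  structure(list(clinical = clinical, drivers = drivers, features = features,
                 courses = courses, histories = histories, groups = groups),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$clinical), "patients;",
      if (is.null(x$features)) "no genomics" else "genomics present", "\n")
  invisible(x)
}

#' Subset a cohort bundle by row index or patient id
#' @param cohort a `cohort_bundle`.
#' @param idx integer indices into the clinical table, or patient ids.
#' @return the subsetted `cohort_bundle`.
#' @export
subset_cohort <- function(cohort, idx) {
  ids <- if (is.character(idx)) idx else cohort$clinical$patient_id[idx]
  keep <- function(tab) tab[tab$patient_id %in% ids, , drop = FALSE]
  out <- cohort
  out$clinical <- keep(cohort$clinical)
  out$courses <- keep(cohort$courses)
  out$histories <- keep(cohort$histories)
  if (!is.null(cohort$features)) out$features <- keep(cohort$features)
  if (!is.null(cohort$groups)) out$groups <- keep(cohort$groups)
  out$drivers <- NULL  # raw calls are not needed downstream of features
  out
}

# -- model bundle serialization ---------------------------------------------

.mat2list <- function(m) if (is.null(m)) NULL else
  list(dim = dim(m) %||% length(m), values = as.numeric(m))
.list2mat <- function(l) {
  if (is.null(l)) return(NULL)
  if (length(l$dim) == 2L) matrix(l$values, l$dim[1L], l$dim[2L])
  else l$values
}

#' Serialize / restore a fitted multi-state model
#'
#' The bundle is a documented JSON container: graph, per-edge parameters,
#' time-bin breaks, baseline cumulative-hazard increments, coefficient
#' names and fitting configuration.
#'
#' @param fit a `multistate_fit`.
#' @param path JSON file path.
#' @return `write_model_bundle`: the path invisibly;
#'   `read_model_bundle`: the restored `multistate_fit`.
#' @export
write_model_bundle <- function(fit, path) {
  edges <- lapply(fit$models, function(m) list(
    par = lapply(m$par, .mat2list),
    breaks = m$breaks,
    baseline = as.list(m$baseline),
    loglik = m$loglik, n_events = m$n_events,
    coefnames = m$coefnames,
    degenerate = m$degenerate,
    config = unclass(m$config)))
  obj <- list(format = "mmstate-model-bundle-v1",
              graph = list(states = fit$graph$states,
                           edges = list(from = fit$graph$edges$from,
                                        to = fit$graph$edges$to),
                           phase = as.list(fit$graph$phase),
                           initial = fit$graph$initial),
              masked_blocks = fit$config$masked_blocks,
              mask_dropout = fit$config$mask_dropout,
              seed = fit$config$seed,
              coefnames = fit$coefnames,
              n = fit$n,
              models = edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "mmstate-model-bundle-v1"))
    stop("not a recognized model bundle: ", path)
  graph <- build_state_graph(list(
    states = as.character(obj$graph$states),
    edges = data.frame(from = as.character(obj$graph$edges$from),
                       to = as.character(obj$graph$edges$to),
                       stringsAsFactors = FALSE),
    phase = unlist(obj$graph$phase),
    initial = obj$graph$initial))
  models <- lapply(obj$models, function(m) {
    cfg <- m$config
    class(cfg) <- "coxnp_config"
    structure(list(par = lapply(m$par, .list2mat),
                   breaks = as.numeric(m$breaks %||% numeric(0)),
                   baseline = data.frame(
                     time = as.numeric(m$baseline$time %||% numeric(0)),
                     dH0 = as.numeric(m$baseline$dH0 %||% numeric(0)),
                     bin = as.integer(m$baseline$bin %||% integer(0))),
                   loglik = m$loglik, loglik0 = NA_real_,
                   n_events = m$n_events, coefnames = m$coefnames,
                   config = cfg, degenerate = isTRUE(m$degenerate)),
              class = "coxnp_fit")
  })
  names(models) <- graph$edges$id
  config <- multistate_config(graph = graph,
                              mask_dropout = obj$mask_dropout %||% 0,
                              masked_blocks = as.character(obj$masked_blocks %||% character(0)),
                              seed = obj$seed %||% 1L)
  structure(list(models = models, graph = graph, config = config,
                 coefnames = obj$coefnames, n = obj$n),
            class = "multistate_fit")
}

# tiny polynomial hash for reproducibility logging
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run one pipeline command
#'
#' End-to-end driver behind the command-line interface. Commands operate on
#' artifacts inside `out_dir`: `simulate` writes the cohort TSVs; `classify`
#' and `stage` append classification/staging tables; `fit` trains the
#' multi-state model and writes `model.json`; `predict` writes per-patient
#' 5-year risks under observed courses; `treatment-variance` writes the
#' per-course PFS long table; `evaluate` writes the CV concordance report.
#' Each run logs the command, a config hash and the seed.
#'
#' @param command one of `simulate`, `classify`, `stage`, `fit`, `predict`,
#'   `treatment-variance`, `evaluate`.
#' @param config list: `out_dir` (required); `n`, `seed`; fitting options
#'   `time_interactions`, `hidden_width`, `mask_dropout`; evaluation options
#'   `folds`, `repeats`; variance options `all_courses` (default `FALSE` =
#'   the 4 VRd courses), `horizon`.
#' @return invisibly, the path(s) of the artifacts written.
#' @export
run_pipeline <- function(command, config = list()) {
  command <- match.arg(command, c("simulate", "classify", "stage", "fit",
                                  "predict", "treatment-variance", "evaluate"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  message(sprintf("[mmstate] command=%s config=%s seed=%d",
                  command, .config_hash(config), seed))
  need_cohort <- function() {
    if (!file.exists(file.path(out_dir, "clinical.tsv")))
      stop("no cohort found in ", out_dir,
           "; run the `simulate` command (or place cohort TSVs) first")
    read_cohort(out_dir)
  }
  need_model <- function() {
    p <- file.path(out_dir, "model.json")
    if (!file.exists(p))
      stop("no fitted model in ", out_dir, "; run the `fit` command first")
    read_model_bundle(p)
  }
  wtsv <- function(x, f) {
    p <- file.path(out_dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  horizon <- config$horizon %||% 60
  grid <- seq(0, config$grid_max %||% 120, by = 1)

  paths <- switch(command,
    "simulate" = {
      cohort <- simulate_cohort(n = config$n %||% 500L, seed = seed)
      write_cohort(cohort, out_dir)
    },
    "classify" = {
      cohort <- need_cohort()
      if (is.null(cohort$features))
        stop("classification requires genomics (drivers.tsv)")
      wtsv(classify_genomic_group(cohort$features), "classification.tsv")
    },
    "stage" = {
      cohort <- need_cohort()
      wtsv(stage_cohort(cohort$clinical, cohort$features), "staging.tsv")
    },
    "fit" = {
      cohort <- need_cohort()
      cfg <- multistate_config(
        coxnp = coxnp_config(
          time_interactions = isTRUE(config$time_interactions),
          hidden_width = config$hidden_width %||% 0L,
          seed = seed),
        mask_dropout = config$mask_dropout %||% 0,
        seed = seed)
      fit <- fit_multistate(cohort, cfg)
      write_model_bundle(fit, file.path(out_dir, "model.json"))
      file.path(out_dir, "model.json")
    },
    "predict" = {
      fit <- need_model()
      cohort <- need_cohort()
      sc <- .risk_scores(fit, cohort, NULL, horizon, grid)
      traj <- predict_trajectories(fit, cohort$clinical, cohort$features,
                                   course = cohort$courses, grid = grid)
      wtsv(data.frame(patient_id = sc$patient_id,
                      risk_efs = sc$efs, risk_os = sc$os,
                      pfs = predict_pfs(traj, horizon)),
           "predictions.tsv")
    },
    "treatment-variance" = {
      fit <- need_model()
      cohort <- need_cohort()
      courses <- if (isTRUE(config$all_courses)) enumerate_courses()
                 else vrd_courses()
      tv <- treatment_variance(fit, cohort$clinical, cohort$features,
                               courses, horizon, grid)
      long <- data.frame(
        patient_id = rep(rownames(tv$pfs), ncol(tv$pfs)),
        course_id = rep(colnames(tv$pfs), each = nrow(tv$pfs)),
        pfs_5y = as.vector(tv$pfs))
      wtsv(long, "treatment_variance.tsv")
    },
    "evaluate" = {
      cohort <- need_cohort()
      rep <- evaluate_cv(cohort,
                         folds = config$folds %||% 5L,
                         repeats = config$repeats %||% 2L,
                         seed = seed, horizon = horizon, grid = grid)
      p <- file.path(out_dir, "evaluation.json")
      jsonlite::write_json(list(splits = rep, summary = summary(rep)),
                           p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      p
    })
  invisible(paths)
}
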