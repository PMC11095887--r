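#' Per-patient predicted PFS across treatment courses, and treatment variance
#'
#' Predicts 5-year progression-free survival (probability of being alive and
#' in remission) for every enumerated treatment course and every patient,
#' holding clinical and genomic covariates fixed. The within-patient spread
#' of predicted PFS across courses — max minus min, plus the full pairwise
#' difference matrix on request — is the treatment-variance statistic.
#'
#' @param fit a [fit_multistate()] model.
#' @param clinical,features subject tables as in [predict_trajectories()].
#' @param courses course table from [enumerate_courses()] /
#'   [vrd_courses()] (>= 2 rows).
#' @param horizon months (default 60).
#' @param grid prediction grid.
#' @param remission_states see [predict_pfs()].
#' @return object of class `treatment_variance_profile`: list with `pfs`
#'   (n x n_courses matrix), `variance` (max-min per patient), `courses`.
#' @export
treatment_variance <- function(fit, clinical, features = NULL,
                               courses = vrd_courses(), horizon = 60,
                               grid = seq(0, 120, by = 1),
                               remission_states = c("S0", "S3")) {
  if (nrow(courses) < 2L) stop("need at least two treatment courses")
  pfs <- matrix(NA_real_, nrow(clinical), nrow(courses),
                dimnames = list(clinical$patient_id, courses$course_id))
  partial <- FALSE
  for (k in seq_len(nrow(courses))) {
    res <- try(predict_trajectories(fit, clinical, features,
                                    course = courses[k, , drop = FALSE],
                                    grid = grid), silent = TRUE)
    if (inherits(res, "try-error")) { partial <- TRUE; next }
    pfs[, k] <- predict_pfs(res, horizon, remission_states)
  }
  structure(list(pfs = pfs,
                 variance = apply(pfs, 1L, function(x)
                   if (all(is.na(x))) NA_real_ else
                     max(x, na.rm = TRUE) - min(x, na.rm = TRUE)),
                 courses = courses, horizon = horizon, partial = partial),
            class = "treatment_variance_profile")
}

#' @export
print.treatment_variance_profile <- function(x, ...) {
  cat("treatment_variance_profile:", nrow(x$pfs), "patients x",
      ncol(x$pfs), "courses; median variance",
      format(stats::median(x$variance, na.rm = TRUE), digits = 3),
      if (x$partial) "(partial)" else "", "\n")
  invisible(x)
}

#' Pairwise predicted-PFS differences for one patient
#' @param profile a `treatment_variance_profile`.
#' @param patient_id which patient.
#' @return antisymmetric courses x courses matrix of PFS differences.
#' @export
pairwise_differences <- function(profile, patient_id) {
  v <- profile$pfs[patient_id, ]
  outer(v, v, `-`)
}

#' Cluster patients by predicted treatment benefit
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of the
#' per-course predicted-PFS matrix; the default k = 6 mirrors the number of
#' benefit patterns the statistic is meant to separate. The algorithm is
#' deterministic; `seed` is accepted for interface stability and recorded.
#'
#' @param profile a `treatment_variance_profile` (or a numeric matrix).
#' @param k number of clusters (default 6).
#' @param seed recorded seed.
#' @return integer cluster labels named by patient.
#' @export
cluster_benefit <- function(profile, k = 6L, seed = 1L) {
  X <- if (inherits(profile, "treatment_variance_profile")) profile$pfs
       else as.matrix(profile)
  if (anyNA(X)) stop("cannot cluster a partial profile (NA predictions)")
  if (k > nrow(X)) stop("k exceeds the number of patients")
  d <- stats::dist(X)
  # indistinguishable profiles share one cluster regardless of k
  if (k == 1L || max(d) == 0)
    return(stats::setNames(rep(1L, nrow(X)), rownames(X)))
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(X)
  attr(labels, "seed") <- seed
  labels
}
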