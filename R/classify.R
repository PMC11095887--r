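#' The twelve genomic group labels
#' @return character vector of the 12 labels, fixed order.
#' @export
genomic_group_labels <- function() {
  c("MAF_APOBEC",
    "NSD2_1q_13q", "NSD2_13q", "NSD2_Simple",
    "1q_13q",
    "CCND1_Complex", "CCND1_Simple",
    "HRD_Complex", "HRD_RAS", "HRD_Gains",
    "Multiple_Losses", "Simple")
}

#' Simple/complex genome call
#'
#' A genome is called complex when it shows the co-occurring instability
#' pattern: the chromothripsis CNV-signature, or at least `D` distinct large
#' deletions, or at least `B` biallelic TSG inactivations. Everything else is
#' simple. Thresholds are configuration values.
#'
#' @param features a `genomic_features` row set (data.frame).
#' @param rule_config list with `min_large_deletions` (D, default 2) and
#'   `min_biallelic` (B, default 1).
#' @return data.frame (patient_id, verdict, chromothripsis_cnvsig,
#'   n_large_deletions, n_biallelic_events, gain1q).
#' @export
complexity_call <- function(features,
                            rule_config = list(min_large_deletions = 2L,
                                               min_biallelic = 1L)) {
  D <- rule_config$min_large_deletions %||% 2L
  B <- rule_config$min_biallelic %||% 1L
  ch <- features$chromothripsis_cnvsig
  nd <- features$n_large_deletions
  nb <- features$n_biallelic_events
  if (any(is.na(ch) & is.na(nd) & is.na(nb)))
    stop("complexity indeterminate: all evidence features masked for some patients")
  complex <- (!is.na(ch) & ch) | (!is.na(nd) & nd >= D) | (!is.na(nb) & nb >= B)
  # a patient is confidently simple only when every unmasked criterion fails
  data.frame(patient_id = features$patient_id,
             verdict = ifelse(complex, "complex", "simple"),
             chromothripsis_cnvsig = ch,
             n_large_deletions = nd,
             n_biallelic_events = nb,
             gain1q = features$gain1q,
             stringsAsFactors = FALSE)
}

#' Assign patients to the twelve genomic groups
#'
#' An ordered, mutually exclusive rule set over the derived feature vector.
#' Precedence (first match wins):
#' \enumerate{
#'   \item t(14;16)/t(14;20) (MAF/MAFB) or hyper-APOBEC -> `MAF_APOBEC`
#'     (hyper-APOBEC without a MAF translocation is merged in; when
#'     hyper-APOBEC co-occurs with t(4;14), the NSD2 branch wins by default).
#'   \item t(4;14) (NSD2): with del(13q) and 1q gain/amp -> `NSD2_1q_13q`;
#'     with del(13q) alone -> `NSD2_13q`; otherwise `NSD2_Simple`.
#'   \item del(13q) and 1q gain/amp without t(4;14) -> `1q_13q`.
#'   \item t(11;14) (CCND1): complex genome -> `CCND1_Complex`, else
#'     `CCND1_Simple`.
#'   \item hyperdiploid without canonical translocation: complex ->
#'     `HRD_Complex`; simple with RAS-pathway mutation -> `HRD_RAS`;
#'     simple without -> `HRD_Gains`.
#'   \item remainder: complex -> `Multiple_Losses`, else `Simple`.
#' }
#' Patients with any required feature masked raise an error (they are
#' unclassifiable, not defaulted).
#'
#' @param features `genomic_features` data.frame.
#' @param rule_config complexity thresholds plus `nsd2_overrides_apobec`
#'   (default `TRUE`).
#' @return data.frame (patient_id, group, complexity, rule_fired).
#' @export
classify_genomic_group <- function(features, rule_config = list()) {
  need <- c("t_MAF_or_MAFB", "t_NSD2", "t_CCND1", "hyper_apobec",
            "hyperdiploid", "gain1q", "del13q", "ras_pathway_mut",
            "chromothripsis_cnvsig", "n_large_deletions", "n_biallelic_events")
  miss <- vapply(need, function(nm) any(is.na(features[[nm]])), TRUE)
  if (any(miss))
    stop("unclassifiable: required features masked: ",
         paste(need[miss], collapse = ", "))
  cx <- complexity_call(features, rule_config)$verdict == "complex"
  nsd2_wins <- rule_config$nsd2_overrides_apobec %||% TRUE

  n <- nrow(features)
  grp <- rep(NA_character_, n)
  rule <- rep(NA_integer_, n)
  gain1q_pos <- features$gain1q %in% c("gain", "amp")
  maf <- features$t_MAF_or_MAFB |
    (features$hyper_apobec & !(nsd2_wins & features$t_NSD2))
  take <- function(cond, label, r) {
    sel <- is.na(grp) & cond
    grp[sel] <<- label
    rule[sel] <<- r
  }
  take(maf, "MAF_APOBEC", 1L)
  take(features$t_NSD2 & features$del13q & gain1q_pos, "NSD2_1q_13q", 2L)
  take(features$t_NSD2 & features$del13q, "NSD2_13q", 2L)
  take(features$t_NSD2, "NSD2_Simple", 2L)
  take(features$del13q & gain1q_pos, "1q_13q", 3L)
  take(features$t_CCND1 & cx, "CCND1_Complex", 4L)
  take(features$t_CCND1, "CCND1_Simple", 4L)
  take(features$hyperdiploid & cx, "HRD_Complex", 5L)
  take(features$hyperdiploid & features$ras_pathway_mut, "HRD_RAS", 5L)
  take(features$hyperdiploid, "HRD_Gains", 5L)
  take(cx, "Multiple_Losses", 6L)
  take(rep(TRUE, n), "Simple", 6L)
  data.frame(patient_id = features$patient_id,
             group = grp,
             complexity = ifelse(cx, "complex", "simple"),
             rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Exhaustive discretized classifier input lattice
#'
#' Enumerates every combination of the features the rule set consumes
#' (booleans, the 3-level 1q status, and representative values either side of
#' the complexity-count thresholds). Used to check totality: every fully
#' observed point maps to exactly one of the 12 labels.
#'
#' @return a `genomic_features`-shaped data.frame covering the lattice.
#' @export
classifier_feature_lattice <- function() {
  g <- expand.grid(
    t_MAF_or_MAFB = c(FALSE, TRUE),
    hyper_apobec = c(FALSE, TRUE),
    t_NSD2 = c(FALSE, TRUE),
    t_CCND1 = c(FALSE, TRUE),
    del13q = c(FALSE, TRUE),
    gain1q = c("neutral", "gain", "amp"),
    hyperdiploid = c(FALSE, TRUE),
    ras_pathway_mut = c(FALSE, TRUE),
    chromothripsis_cnvsig = c(FALSE, TRUE),
    n_large_deletions = c(0L, 2L),
    n_biallelic_events = c(0L, 1L),
    stringsAsFactors = FALSE
  )
  g$patient_id <- sprintf("L%05d", seq_len(nrow(g)))
  g
}

#' Cross-tabulate two aligned label vectors
#'
#' Supports comparison of the genomic grouping with legacy classifications
#' (e.g. translocation-cyclin-D or expression-based labels supplied as input).
#'
#' @param labels_a,labels_b equal-length label vectors, aligned by patient.
#' @return a contingency table (class `table`); marginals equal input counts.
#' @export
cross_tabulate <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  table(a = labels_a, b = labels_b)
}
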