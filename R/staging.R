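#' International Staging System (ISS)
#'
#' Stage I: beta-2-microglobulin < 3.5 mg/L and albumin >= 3.5 g/dL;
#' stage III: b2m >= 5.5 mg/L; stage II otherwise. Missing inputs give `NA`.
#'
#' @param b2m serum beta-2-microglobulin, mg/L.
#' @param albumin serum albumin, g/dL.
#' @return character vector in `c("I", "II", "III")`.
#' @export
iss_stage <- function(b2m, albumin) {
  if (any(b2m <= 0 | albumin <= 0, na.rm = TRUE))
    stop("b2m and albumin must be positive")
  out <- rep(NA_character_, max(length(b2m), length(albumin)))
  b2m <- rep_len(b2m, length(out)); albumin <- rep_len(albumin, length(out))
  ok <- !is.na(b2m) & !is.na(albumin)
  out[ok] <- "II"
  out[ok & b2m < 3.5 & albumin >= 3.5] <- "I"
  out[ok & b2m >= 5.5] <- "III"
  out
}

#' Revised ISS (R-ISS)
#'
#' Stage I: ISS I with normal LDH and no high-risk cytogenetics
#' (del(17p), t(4;14), t(14;16)); stage III: ISS III with high LDH or
#' high-risk cytogenetics; stage II otherwise.
#'
#' @param iss ISS stage (`"I"/"II"/"III"`).
#' @param ldh_ratio LDH over the upper limit of normal.
#' @param del17p,t_nsd2,t_maf logical high-risk cytogenetic flags
#'   (del(17p), t(4;14), t(14;16)).
#' @return character vector in `c("I", "II", "III")`.
#' @export
r_iss_stage <- function(iss, ldh_ratio, del17p, t_nsd2, t_maf = FALSE) {
  n <- max(length(iss), length(ldh_ratio), length(del17p), length(t_nsd2),
           length(t_maf))
  iss <- rep_len(iss, n); ldh_ratio <- rep_len(ldh_ratio, n)
  hr <- rep_len(del17p, n) | rep_len(t_nsd2, n) | rep_len(t_maf, n)
  high_ldh <- ldh_ratio > 1
  out <- rep(NA_character_, n)
  ok <- !is.na(iss) & !is.na(high_ldh) & !is.na(hr)
  out[ok] <- "II"
  out[ok & iss == "I" & !hr & !high_ldh] <- "I"
  out[ok & iss == "III" & (hr | high_ldh)] <- "III"
  out
}

#' Second revision of the ISS (R2-ISS)
#'
#' Additive score: ISS II +1, ISS III +1.5, del(17p) +1, high LDH +1,
#' t(4;14) +1, 1q gain/amp +0.5. Groups: 0 Low; 0.5-1 Low-Intermediate;
#' 1.5-2.5 Intermediate-High; 3-5 High. The 1q component counts gain and
#' amplification alike.
#'
#' @param iss ISS stage.
#' @param ldh_ratio LDH / upper limit of normal.
#' @param del17p logical del(17p).
#' @param t_nsd2 logical t(4;14).
#' @param gain1q `"neutral"/"gain"/"amp"` (or logical).
#' @return data.frame (r2_iss_score, r2_iss_group).
#' @export
r2_iss <- function(iss, ldh_ratio, del17p, t_nsd2, gain1q) {
  n <- max(length(iss), length(ldh_ratio), length(del17p), length(t_nsd2),
           length(gain1q))
  iss <- rep_len(iss, n)
  g1q <- if (is.logical(gain1q)) rep_len(gain1q, n)
         else rep_len(gain1q, n) %in% c("gain", "amp")
  score <- (iss == "II") * 1 + (iss == "III") * 1.5 +
    rep_len(del17p, n) * 1 + (rep_len(ldh_ratio, n) > 1) * 1 +
    rep_len(t_nsd2, n) * 1 + g1q * 0.5
  grp <- rep(NA_character_, n)
  grp[!is.na(score) & score == 0] <- "Low"
  grp[!is.na(score) & score >= 0.5 & score <= 1] <- "Low-Int"
  grp[!is.na(score) & score >= 1.5 & score <= 2.5] <- "Int-High"
  grp[!is.na(score) & score >= 3] <- "High"
  data.frame(r2_iss_score = score, r2_iss_group = grp,
             stringsAsFactors = FALSE)
}

#' Staging summary for a cohort
#'
#' Convenience wrapper computing ISS, R-ISS and R2-ISS columns from a clinical
#' table and a genomic feature table.
#'
#' @param clinical data.frame with `b2m`, `albumin`, `ldh_ratio`.
#' @param features `genomic_features` table aligned on `patient_id` (may be
#'   `NULL`: cytogenetic components treated as absent-with-missing marker).
#' @return data.frame (patient_id, iss, r_iss, r2_iss_score, r2_iss_group).
#' @export
stage_cohort <- function(clinical, features = NULL) {
  iss <- iss_stage(clinical$b2m, clinical$albumin)
  if (is.null(features)) {
    del17p <- t_nsd2 <- t_maf <- rep(NA, nrow(clinical))
    gain1q <- rep(NA_character_, nrow(clinical))
  } else {
    idx <- match(clinical$patient_id, features$patient_id)
    del17p <- features$del17p[idx]
    t_nsd2 <- features$t_NSD2[idx]
    t_maf <- features$t_MAF_or_MAFB[idx]
    gain1q <- features$gain1q[idx]
  }
  r2 <- r2_iss(iss, clinical$ldh_ratio, del17p, t_nsd2, gain1q)
  data.frame(patient_id = clinical$patient_id,
             iss = iss,
             r_iss = r_iss_stage(iss, clinical$ldh_ratio, del17p, t_nsd2, t_maf),
             r2_iss_score = r2$r2_iss_score,
             r2_iss_group = r2$r2_iss_group,
             stringsAsFactors = FALSE)
}
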