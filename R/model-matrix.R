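#' Covariate blocks and the cohort design matrix
#'
#' The risk model consumes a fixed-layout numeric design split into named
#' blocks, mirroring how feature importance is reported: `age`, `iss`,
#' `other_clinical` (ECOG, sex, LDH), `genomics` (the 20 prognostic genomic
#' features plus a missingness mask bit), and `treatment` (induction drug
#' classes in both phases; HDM-ASCT and maintenance indicators in phase II
#' only, where they act as time-dependent course covariates). Age is centred
#' at 65 years and scaled by decades. Masked genomics (assay unavailable, or
#' ablation) zero the genomic columns and set `genomics_missing = 1`.
#'
#' @param features `genomic_features` table (or `NULL` for a genomics-free
#'   design: all genomic columns zero, mask bit set).
#' @param clinical data.frame with `patient_id`, `age`, `b2m`, `albumin`,
#'   `ldh_ratio`, `ecog`, `sex`.
#' @param courses data.frame (patient_id, induction, postinduction) or a
#'   single course applied to everyone (1-row data.frame without patient_id).
#' @param phase 1 or 2; phase II adds the post-induction indicators.
#' @param masked_blocks character vector of block names to zero out
#'   (genomics masking also sets the mask bit).
#' @param mask_genomics logical vector (per patient) forcing the genomics
#'   mask, e.g. for missing-assay patients or mask-dropout during training.
#' @return numeric matrix with `attr(, "blocks")` naming column membership.
#' @export
build_design <- function(features, clinical, courses, phase = 1L,
                         masked_blocks = character(0),
                         mask_genomics = NULL) {
  n <- nrow(clinical)
  ids <- clinical$patient_id
  iss <- iss_stage(clinical$b2m, clinical$albumin)
  cols <- list()
  blocks <- character(0)
  add <- function(name, value, block) {
    cols[[name]] <<- as.numeric(value)
    blocks[name] <<- block
  }
  add("age_dec", (clinical$age - 65) / 10, "age")
  add("iss2", iss == "II", "iss")
  add("iss3", iss == "III", "iss")
  add("ecog", pmin(clinical$ecog, 4), "other_clinical")
  add("sex_male", clinical$sex == "M", "other_clinical")
  add("ldh_high", clinical$ldh_ratio > 1, "other_clinical")

  if (is.null(features)) {
    fx <- NULL
  } else {
    fx <- features[match(ids, features$patient_id), , drop = FALSE]
  }
  gval <- function(col, f) if (is.null(fx)) rep(0, n) else f(fx[[col]])
  asnum <- function(x) {
    x <- as.numeric(x)
    ifelse(is.na(x), 0, x)
  }
  add("gain1q_gain", gval("gain1q", function(x) asnum(x == "gain")), "genomics")
  add("gain1q_amp", gval("gain1q", function(x) asnum(x == "amp")), "genomics")
  for (cn in c("del1p", "del13q", "del17p", "del8p", "del16q"))
    add(cn, gval(cn, asnum), "genomics")
  add("tp53_mono", gval("tp53_status", function(x) asnum(x == "monoallelic")), "genomics")
  add("tp53_bi", gval("tp53_status", function(x) asnum(x == "biallelic")), "genomics")
  add("rb1_bi", gval("rb1_status", function(x) asnum(x == "biallelic")), "genomics")
  add("dnmt3a_bi", gval("dnmt3a_status", function(x) asnum(x == "biallelic")), "genomics")
  for (cn in c("t_NSD2", "t_CCND1", "t_MAF_or_MAFB", "hyperdiploid",
               "ras_pathway_mut", "chromothripsis_cnvsig", "hyper_apobec"))
    add(cn, gval(cn, asnum), "genomics")
  add("n_large_deletions", gval("n_large_deletions", asnum), "genomics")
  add("n_biallelic_events", gval("n_biallelic_events", asnum), "genomics")

  co <- courses
  if (!is.null(co) && !("patient_id" %in% names(co))) {
    co <- co[rep(1L, n), , drop = FALSE]
    co$patient_id <- ids
  }
  cidx <- match(ids, co$patient_id)
  ind <- .induction_indicators(co$induction[cidx])
  add("ind_imid", ind$ind_imid, "treatment")
  add("ind_pi", ind$ind_pi, "treatment")
  add("ind_chemo", ind$ind_chemo, "treatment")
  if (phase == 2L) {
    post <- .post_indicators(co$postinduction[cidx])
    add("hdm_asct", post$hdm_asct, "treatment")
    add("maintenance", post$maintenance, "treatment")
  }

  X <- do.call(cbind, cols)
  rownames(X) <- ids
  gen_cols <- names(blocks)[blocks == "genomics"]

  # per-patient genomics mask: explicit argument, absent feature table, or
  # NA-bearing rows (unassayed classes)
  gmask <- rep(FALSE, n)
  if (is.null(fx)) gmask <- rep(TRUE, n)
  else {
    core <- c("gain1q", "del13q", "t_NSD2", "hyperdiploid",
              "chromothripsis_cnvsig")
    gmask <- Reduce(`|`, lapply(core, function(cn) is.na(fx[[cn]])))
    gmask <- gmask | is.na(match(ids, features$patient_id))
  }
  if (!is.null(mask_genomics)) gmask <- gmask | mask_genomics
  unknown <- setdiff(masked_blocks, unique(blocks))
  if (length(unknown))
    stop("unknown feature block(s): ", paste(unknown, collapse = ", "))
  if ("genomics" %in% masked_blocks) gmask <- rep(TRUE, n)
  X[gmask, gen_cols] <- 0
  X <- cbind(X, genomics_missing = as.numeric(gmask))
  blocks["genomics_missing"] <- "genomics_mask"
  for (blk in setdiff(masked_blocks, "genomics")) {
    X[, names(blocks)[blocks == blk]] <- 0
  }
  if (anyNA(X)) stop("design matrix contains NA (incomplete clinical data?)")
  attr(X, "blocks") <- blocks
  X
}

#' Names of the maskable feature blocks
#' @return character vector.
#' @export
feature_blocks <- function()
  c("age", "iss", "other_clinical", "genomics", "treatment")
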