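#' Classify an absolute copy number
#'
#' Copy-number states follow the absolute-copies convention used for myeloma
#' GISTIC summaries: with a diploid baseline, 0 copies is biallelic loss, 1 is
#' (monoallelic) loss, 2 neutral, 3 gain, and more than 3 copies is
#' amplification. The baseline is configurable but deliberately NOT shifted for
#' hyperdiploid genomes: thresholds are expressed in absolute copies.
#'
#' @param copy_number non-negative integer vector of absolute copies.
#' @param ploidy_baseline the neutral copy number (default 2).
#' @return character vector with levels
#'   `biallelic-loss < loss < neutral < gain < amp`.
#' @examples
#' call_cnv_class(c(0, 1, 2, 3, 4))
#' @export
call_cnv_class <- function(copy_number, ploidy_baseline = 2L) {
  if (any(is.na(copy_number))) stop("copy_number contains NA")
  if (any(copy_number < 0)) stop("copy_number must be non-negative")
  stopifnot(length(ploidy_baseline) == 1L, ploidy_baseline >= 1)
  out <- character(length(copy_number))
  out[copy_number == 0] <- "biallelic-loss"
  out[copy_number > 0 & copy_number < ploidy_baseline] <- "loss"
  out[copy_number == ploidy_baseline] <- "neutral"
  out[copy_number == ploidy_baseline + 1] <- "gain"
  out[copy_number > ploidy_baseline + 1] <- "amp"
  out
}

#' Hyperdiploidy call
#'
#' A genome is hyperdiploid when at least two distinct odd-numbered
#' chromosomes carry a large-class (>= 5 Mb) gain. Patients whose CNV assay is
#' unavailable get `NA`, not `FALSE`.
#'
#' @param profiles a [driver_profiles()] cohort.
#' @param min_odd_gains minimum number of distinct odd chromosomes with a
#'   large gain (default 2).
#' @return named logical vector over the cohort roster.
#' @export
call_hyperdiploid <- function(profiles, min_odd_gains = 2L) {
  stopifnot(inherits(profiles, "driver_profiles"))
  reg <- profiles$registry$loci
  cv <- profiles$cnv
  out <- stats::setNames(rep(FALSE, length(profiles$patient_id)),
                         profiles$patient_id)
  if (nrow(cv)) {
    gains <- cv[cv$size_class == "large" & cv$copies > 2, , drop = FALSE]
    gains$chrom <- reg$chrom[match(gains$locus, reg$locus)]
    gains <- gains[gains$chrom %% 2L == 1L, , drop = FALSE]
    if (nrow(gains)) {
      n_odd <- tapply(gains$chrom, gains$patient_id,
                      function(ch) length(unique(ch)))
      out[names(n_odd)] <- n_odd >= min_odd_gains
    }
  }
  masked <- profiles$assays$patient_id[!profiles$assays$cnv]
  out[masked] <- NA
  out
}

#' Mono-/biallelic tumour-suppressor status
#'
#' A TSG is biallelically inactivated when a mutation co-occurs with a
#' deletion of its mapped locus, or the locus is homozygously deleted
#' (0 copies); exactly one hit class gives monoallelic status; otherwise WT.
#'
#' @param gene TSG symbol(s); must be present in the registry TSG table.
#' @param mutated logical vector, nonsynonymous mutation present.
#' @param locus_copy_number integer vector of copies at the gene's deletion
#'   locus.
#' @param registry registry list.
#' @return character vector in `c("WT", "monoallelic", "biallelic")`.
#' @export
call_allelic_status <- function(gene, mutated, locus_copy_number,
                                registry = default_registry()) {
  unknown <- setdiff(unique(gene), registry$tsg$gene)
  if (length(unknown))
    stop("unknown TSG (not in registry): ", paste(unknown, collapse = ", "))
  if (any(locus_copy_number < 0, na.rm = TRUE)) stop("negative copy number")
  n <- max(length(gene), length(mutated), length(locus_copy_number))
  mutated <- rep_len(as.logical(mutated), n)
  copies <- rep_len(locus_copy_number, n)
  deleted <- copies < 2
  out <- rep("WT", n)
  out[xor(mutated, deleted)] <- "monoallelic"
  out[(mutated & deleted) | copies == 0] <- "biallelic"
  out
}

#' Hyper-APOBEC flag
#'
#' Flags patients whose APOBEC mutational-signature contribution (SBS2+SBS13
#' fraction) is extreme. In `"decile"` mode the top tenth of patients with
#' nonzero APOBEC evidence is flagged (ties at the cutoff value are all
#' included); in `"fixed-threshold"` mode any fraction strictly above the
#' threshold (default 0.11, i.e. >11%) is flagged. Patients with zero APOBEC
#' evidence are never flagged; `NA` fractions propagate as `NA`.
#'
#' @param cohort_fractions numeric vector of APOBEC fractions in \[0,1\].
#' @param mode `"decile"` or `"fixed-threshold"`.
#' @param threshold fixed-mode cutoff (strict inequality), default 0.11.
#' @return logical vector aligned with `cohort_fractions`.
#' @export
call_hyper_apobec <- function(cohort_fractions,
                              mode = c("fixed-threshold", "decile"),
                              threshold = 0.11) {
  mode <- match.arg(mode)
  fr <- cohort_fractions
  if (!length(fr)) stop("empty cohort")
  if (any(fr < 0 | fr > 1, na.rm = TRUE)) stop("fractions must lie in [0, 1]")
  out <- rep(FALSE, length(fr))
  out[is.na(fr)] <- NA
  if (mode == "fixed-threshold") {
    out[!is.na(fr)] <- fr[!is.na(fr)] > threshold
    return(out)
  }
  elig <- which(!is.na(fr) & fr > 0)
  if (length(elig) && sum(!is.na(fr)) >= 10) {
    k <- max(1L, floor(0.1 * length(elig)))
    cutoff <- sort(fr[elig], decreasing = TRUE)[k]
    out[elig] <- fr[elig] >= cutoff
  } else if (sum(!is.na(fr)) < 10) {
    stop("decile mode requires at least 10 patients")
  }
  out
}

.feature_columns <- function(registry) {
  c("gain1q", "del1p", "del13q", "del17p", "del8p", "del16q",
    paste0(tolower(registry$tsg$gene), "_status"),
    "t_NSD2", "t_CCND1", "t_MAF_or_MAFB",
    "hyperdiploid", "ras_pathway_mut", "irf4_mut",
    "chromothripsis_cnvsig", "hyper_apobec", "apobec_fraction",
    "n_large_deletions", "n_biallelic_events")
}

#' Assemble the model-ready genomic feature table
#'
#' Derives the prognostic and classifier-ready features from raw driver calls:
#' 1q21 gain/amp status, arm-level deletion flags, per-TSG allelic status,
#' canonical IGH translocation flags, hyperdiploidy, RAS-pathway and IRF4
#' mutation flags, the chromothripsis CNV-signature flag, hyper-APOBEC, and
#' the genome-complexity counts (large deletions, biallelic TSG events).
#' Unassayed data classes propagate as `NA` (masked) in every feature they
#' feed; masked features carry no value.
#'
#' @param profiles a [driver_profiles()] cohort.
#' @param cohort_context list of cohort-level settings: `apobec_mode`
#'   (`"fixed-threshold"` default, or `"decile"`), `apobec_threshold` (0.11).
#'   In decile mode the cutoff is computed over the cohort passed in, so the
#'   same patient can flip between cohorts; fixed mode is the deterministic
#'   per-patient default.
#' @return data.frame, one row per roster patient, class `genomic_features`.
#' @export
build_features <- function(profiles, cohort_context = list()) {
  stopifnot(inherits(profiles, "driver_profiles"))
  reg <- profiles$registry
  ids <- profiles$patient_id
  n <- length(ids)
  asy <- profiles$assays[match(ids, profiles$assays$patient_id), ]

  cv <- profiles$cnv
  if (nrow(cv)) {
    # contradictory duplicate calls at one locus (e.g. amp and biallelic loss)
    key <- paste(cv$patient_id, cv$locus)
    if (anyDuplicated(key)) {
      agg_min <- tapply(cv$copies, key, min)
      agg_max <- tapply(cv$copies, key, max)
      bad <- names(agg_min)[agg_min < 2 & agg_max > 2]
      if (length(bad))
        stop("contradictory CNV calls (loss and gain at same locus): ",
             paste(utils::head(bad, 5), collapse = "; "))
    }
  }
  locus_copies <- function(prefix) {
    # minimum copies over calls at loci on the given arm/locus prefix
    out <- rep(NA_integer_, n)
    hit <- cv[startsWith(cv$locus, prefix), , drop = FALSE]
    have_cnv <- asy$cnv
    out[have_cnv] <- 2L
    if (nrow(hit)) {
      mn <- tapply(hit$copies, hit$patient_id, min)
      mx <- tapply(hit$copies, hit$patient_id, max)
      idx <- match(names(mn), ids)
      # report the call farthest from neutral
      dev <- ifelse(abs(mn - 2) >= abs(mx - 2), mn, mx)
      out[idx] <- as.integer(dev)
    }
    out[!have_cnv] <- NA_integer_
    out
  }

  gain1q_copies <- locus_copies("1q")
  gain1q <- ifelse(is.na(gain1q_copies), NA_character_,
                   ifelse(gain1q_copies > 3, "amp",
                          ifelse(gain1q_copies == 3, "gain", "neutral")))
  del_flag <- function(prefix) {
    cp <- locus_copies(prefix)
    ifelse(is.na(cp), NA, cp < 2)
  }

  mut <- profiles$mutations
  has_mut <- function(genes) {
    out <- rep(FALSE, n)
    if (nrow(mut)) {
      hit <- unique(mut$patient_id[mut$gene %in% genes])
      out[match(hit, ids)] <- TRUE
    }
    out[!asy$mutations] <- NA
    out
  }

  # per-TSG allelic status; needs both mutation and CNV assays
  tsg_status <- lapply(seq_len(nrow(reg$tsg)), function(i) {
    g <- reg$tsg$gene[i]
    cp <- locus_copies(reg$tsg$locus[i])
    m <- has_mut(g)
    st <- rep(NA_character_, n)
    ok <- !is.na(m) & !is.na(cp)
    st[ok] <- call_allelic_status(g, m[ok], cp[ok], reg)
    st
  })
  names(tsg_status) <- paste0(tolower(reg$tsg$gene), "_status")

  tra <- profiles$translocations
  has_tra <- function(partners) {
    out <- rep(FALSE, n)
    if (nrow(tra)) {
      hit <- unique(tra$patient_id[tra$partner %in% partners])
      out[match(hit, ids)] <- TRUE
    }
    out[!asy$translocations] <- NA
    out
  }

  sig <- profiles$signatures
  sidx <- match(ids, sig$patient_id)
  apobec_fraction <- sig$apobec_fraction[sidx]
  chromo <- sig$chromothripsis_cnvsig[sidx]
  apobec_fraction[!asy$signatures] <- NA
  chromo[!asy$signatures] <- NA
  apobec_fraction[asy$signatures & is.na(apobec_fraction)] <- 0
  chromo[asy$signatures & is.na(chromo)] <- FALSE

  mode <- cohort_context$apobec_mode %||% "fixed-threshold"
  thr <- cohort_context$apobec_threshold %||% 0.11
  hyper_apobec <- rep(NA, n)
  ok <- !is.na(apobec_fraction)
  if (any(ok))
    hyper_apobec[ok] <- call_hyper_apobec(apobec_fraction[ok], mode, thr)

  n_large_del <- rep(NA_integer_, n)
  n_large_del[asy$cnv] <- 0L
  if (nrow(cv)) {
    ld <- cv[cv$size_class == "large" & cv$copies < 2, , drop = FALSE]
    if (nrow(ld)) {
      cnt <- tapply(ld$locus, ld$patient_id, function(x) length(unique(x)))
      n_large_del[match(names(cnt), ids)] <- as.integer(cnt)
    }
  }
  n_large_del[!asy$cnv] <- NA_integer_

  st_mat <- do.call(cbind, lapply(tsg_status, function(s) s == "biallelic"))
  n_biallelic <- rowSums(st_mat)
  n_biallelic[apply(st_mat, 1L, function(r) all(is.na(r)))] <- NA

  out <- data.frame(
    patient_id = ids,
    gain1q = gain1q,
    del1p = del_flag("1p"), del13q = del_flag("13q"),
    del17p = del_flag("17p"), del8p = del_flag("8p"),
    del16q = del_flag("16q"),
    stringsAsFactors = FALSE
  )
  for (nm in names(tsg_status)) out[[nm]] <- tsg_status[[nm]]
  out$t_NSD2 <- has_tra("NSD2")
  out$t_CCND1 <- has_tra("CCND1")
  out$t_MAF_or_MAFB <- has_tra(c("MAF", "MAFB"))
  out$hyperdiploid <- unname(call_hyperdiploid(profiles))
  out$ras_pathway_mut <- has_mut(reg$ras_pathway)
  out$irf4_mut <- has_mut("IRF4")
  out$chromothripsis_cnvsig <- as.logical(chromo)
  out$hyper_apobec <- hyper_apobec
  out$apobec_fraction <- apobec_fraction
  out$n_large_deletions <- n_large_del
  out$n_biallelic_events <- as.integer(n_biallelic)
  class(out) <- c("genomic_features", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
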