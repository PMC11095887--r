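# shared fixtures, built lazily once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_cohort <- function() cached("small_cohort", simulate_cohort(n = 300, seed = 101))

small_fit <- function() cached("small_fit",
  fit_multistate(small_cohort(), multistate_config(seed = 101)))

# deliberately naive O(n^2) pairwise oracle for Harrell's c-index,
# independent of the package implementation
brute_cindex <- function(risk, time, status) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && status[i] == 1) ||
      (time[i] == time[j] && status[i] == 1 && status[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# one-patient driver profile builder for feature tests
one_profile <- function(id = "PT1", mutations = NULL, cnv = NULL,
                        translocations = NULL, apobec = 0, chromo = FALSE,
                        assays = NULL) {
  sig <- data.frame(patient_id = id, apobec_fraction = apobec,
                    chromothripsis_cnvsig = chromo, stringsAsFactors = FALSE)
  driver_profiles(id, mutations, cnv, translocations, sig, assays)
}

cnv_row <- function(id, locus, copies, size = "focal")
  data.frame(patient_id = id, locus = locus, copies = copies,
             size_class = size, stringsAsFactors = FALSE)

mut_row <- function(id, gene)
  data.frame(patient_id = id, gene = gene, hotspot = FALSE,
             stringsAsFactors = FALSE)

tra_row <- function(id, partner)
  data.frame(patient_id = id, partner = partner, stringsAsFactors = FALSE)

# a feature row with every classifier input observed, overridable
feature_row <- function(...) {
  base <- data.frame(
    patient_id = "PT1", gain1q = "neutral", del1p = FALSE, del13q = FALSE,
    del17p = FALSE, del8p = FALSE, del16q = FALSE,
    traf3_status = "WT", cyld_status = "WT", tp53_status = "WT",
    rb1_status = "WT", max_status = "WT", tent5c_status = "WT",
    cdkn2c_status = "WT", dnmt3a_status = "WT",
    t_NSD2 = FALSE, t_CCND1 = FALSE, t_MAF_or_MAFB = FALSE,
    hyperdiploid = FALSE, ras_pathway_mut = FALSE, irf4_mut = FALSE,
    chromothripsis_cnvsig = FALSE, hyper_apobec = FALSE,
    apobec_fraction = 0, n_large_deletions = 0L, n_biallelic_events = 0L,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
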