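#' Driver-level genomic call container
#'
#' A `driver_profiles` object holds raw per-patient genomic calls for a cohort:
#' driver-gene mutations, locus-level copy number (with the focal/large segment
#' size class at the 5 Mb cut), IGH translocation partners, the APOBEC
#' mutational-signature fraction, and the chromothripsis copy-number-signature
#' flag. Assay flags record which data classes were actually assayed per
#' patient; derived features for unassayed classes are masked (`NA`), never
#' silently imputed.
#'
#' @param patient_id character vector of cohort patient identifiers.
#' @param mutations data.frame (patient_id, gene, hotspot) of present mutations;
#'   `hotspot` logical.
#' @param cnv data.frame (patient_id, locus, copies, size_class) with
#'   `size_class` in `c("focal", "large")` and non-negative integer `copies`.
#' @param translocations data.frame (patient_id, partner).
#' @param signatures data.frame (patient_id, apobec_fraction,
#'   chromothripsis_cnvsig).
#' @param assays data.frame (patient_id, mutations, cnv, translocations,
#'   signatures) of logical availability flags; defaults to all available.
#' @param registry locus/gene registry, see [default_registry()].
#' @return an object of class `driver_profiles`.
#' @export
driver_profiles <- function(patient_id,
                            mutations = NULL, cnv = NULL,
                            translocations = NULL, signatures = NULL,
                            assays = NULL, registry = default_registry()) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient_id in roster")
  empty <- function(cols) {
    out <- lapply(cols, function(x) character(0))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  if (is.null(mutations)) mutations <- data.frame(patient_id = character(0),
                                                  gene = character(0),
                                                  hotspot = logical(0))
  if (is.null(cnv)) cnv <- data.frame(patient_id = character(0),
                                      locus = character(0),
                                      copies = integer(0),
                                      size_class = character(0))
  if (is.null(translocations)) translocations <- empty(c("patient_id", "partner"))
  if (is.null(signatures)) signatures <- data.frame(patient_id = character(0),
                                                    apobec_fraction = numeric(0),
                                                    chromothripsis_cnvsig = logical(0))
  if (is.null(assays)) {
    assays <- data.frame(patient_id = patient_id,
                         mutations = TRUE, cnv = TRUE,
                         translocations = TRUE, signatures = TRUE,
                         stringsAsFactors = FALSE)
  }
  if (nrow(cnv)) {
    if (any(cnv$copies < 0)) stop("negative copy number in CNV calls")
    if (!all(cnv$size_class %in% c("focal", "large")))
      stop("size_class must be 'focal' or 'large'")
    unknown <- setdiff(unique(cnv$locus), registry$loci$locus)
    if (length(unknown))
      stop("unrecognized CNV loci: ", paste(unknown, collapse = ", "))
  }
  if (nrow(signatures)) {
    af <- signatures$apobec_fraction
    if (any(af < 0 | af > 1, na.rm = TRUE))
      stop("apobec_fraction must lie in [0, 1]")
  }
  if (nrow(translocations)) {
    unknown <- setdiff(unique(translocations$partner),
                       registry$translocation_partners)
    if (length(unknown))
      stop("unrecognized translocation partners: ",
           paste(unknown, collapse = ", "))
  }
  for (tab in list(mutations, cnv, translocations, signatures)) {
    extra <- setdiff(unique(tab$patient_id), patient_id)
    if (length(extra))
      stop("calls for patients absent from roster: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(patient_id = patient_id,
                 mutations = mutations, cnv = cnv,
                 translocations = translocations, signatures = signatures,
                 assays = assays, registry = registry),
            class = "driver_profiles")
}

#' @export
print.driver_profiles <- function(x, ...) {
  cat("driver_profiles:", length(x$patient_id), "patients;",
      nrow(x$mutations), "mutation calls,", nrow(x$cnv), "CNV calls,",
      nrow(x$translocations), "translocations\n")
  invisible(x)
}

#' @export
length.driver_profiles <- function(x) length(x$patient_id)

#' Read / write the driver-profile TSV interchange format
#'
#' One row per patient-level call: columns `patient_id`, `class` in
#' `MUT`/`CNV`/`TRA`/`SIG`/`ASSAY`, `key`, `value`. Dialect:
#' \itemize{
#'   \item `MUT`: key = gene symbol, value = `present` or `hotspot`.
#'   \item `CNV`: key = `locus|size_class` (e.g. `13q|large`), value = copies.
#'   \item `TRA`: key = partner symbol, value = `1`.
#'   \item `SIG`: key = `apobec_fraction` (value in \[0,1\]) or
#'     `chromothripsis_cnvsig` (value 0/1).
#'   \item `ASSAY`: key = data class name, value 0/1; patients without ASSAY
#'     rows are assumed fully assayed. A bare `ASSAY`/`roster`/`1` row may be
#'     used to register an otherwise call-free patient.
#' }
#' Tab-separated, UTF-8, header row required.
#'
#' @param path file path.
#' @param registry registry list.
#' @return `read_driver_tsv`: a `driver_profiles` object.
#' @export
read_driver_tsv <- function(path, registry = default_registry()) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  need <- c("patient_id", "class", "key", "value")
  if (!all(need %in% names(tab)))
    stop("driver TSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$class), c("MUT", "CNV", "TRA", "SIG", "ASSAY"))
  if (length(bad)) stop("unknown call class: ", paste(bad, collapse = ", "))
  ids <- unique(tab$patient_id)
  mut <- tab[tab$class == "MUT", ]
  cnv <- tab[tab$class == "CNV", ]
  tra <- tab[tab$class == "TRA", ]
  sig <- tab[tab$class == "SIG", ]
  asy <- tab[tab$class == "ASSAY" & tab$key %in%
               c("mutations", "cnv", "translocations", "signatures"), ]
  mutations <- data.frame(patient_id = mut$patient_id, gene = mut$key,
                          hotspot = mut$value == "hotspot",
                          stringsAsFactors = FALSE)
  ks <- strsplit(cnv$key, "|", fixed = TRUE)
  cnv_df <- data.frame(patient_id = cnv$patient_id,
                       locus = vapply(ks, `[`, "", 1L),
                       copies = as.integer(cnv$value),
                       size_class = vapply(ks, function(k)
                         if (length(k) > 1L) k[2L] else "focal", ""),
                       stringsAsFactors = FALSE)
  tra_df <- data.frame(patient_id = tra$patient_id, partner = tra$key,
                       stringsAsFactors = FALSE)
  sig_wide <- data.frame(patient_id = unique(sig$patient_id),
                         apobec_fraction = NA_real_,
                         chromothripsis_cnvsig = NA,
                         stringsAsFactors = FALSE)
  if (nrow(sig)) {
    af <- sig[sig$key == "apobec_fraction", ]
    ch <- sig[sig$key == "chromothripsis_cnvsig", ]
    sig_wide$apobec_fraction <-
      as.numeric(af$value)[match(sig_wide$patient_id, af$patient_id)]
    sig_wide$chromothripsis_cnvsig <-
      (as.numeric(ch$value) > 0)[match(sig_wide$patient_id, ch$patient_id)]
  }
  assays <- data.frame(patient_id = ids, mutations = TRUE, cnv = TRUE,
                       translocations = TRUE, signatures = TRUE,
                       stringsAsFactors = FALSE)
  if (nrow(asy)) {
    for (i in seq_len(nrow(asy)))
      assays[assays$patient_id == asy$patient_id[i], asy$key[i]] <-
        as.numeric(asy$value[i]) > 0
  }
  driver_profiles(ids, mutations, cnv_df, tra_df, sig_wide, assays, registry)
}

#' @rdname read_driver_tsv
#' @param profiles a `driver_profiles` object.
#' @return `write_driver_tsv`: the path, invisibly.
#' @export
write_driver_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "driver_profiles"))
  rows <- list(data.frame(patient_id = profiles$patient_id, class = "ASSAY",
                          key = "roster", value = "1",
                          stringsAsFactors = FALSE))
  a <- profiles$assays
  for (cls in c("mutations", "cnv", "translocations", "signatures")) {
    off <- a$patient_id[!a[[cls]]]
    if (length(off))
      rows <- c(rows, list(data.frame(patient_id = off, class = "ASSAY",
                                      key = cls, value = "0")))
  }
  m <- profiles$mutations
  if (nrow(m))
    rows <- c(rows, list(data.frame(patient_id = m$patient_id, class = "MUT",
                                    key = m$gene,
                                    value = ifelse(m$hotspot, "hotspot", "present"))))
  cv <- profiles$cnv
  if (nrow(cv))
    rows <- c(rows, list(data.frame(patient_id = cv$patient_id, class = "CNV",
                                    key = paste(cv$locus, cv$size_class, sep = "|"),
                                    value = as.character(cv$copies))))
  tr <- profiles$translocations
  if (nrow(tr))
    rows <- c(rows, list(data.frame(patient_id = tr$patient_id, class = "TRA",
                                    key = tr$partner, value = "1")))
  s <- profiles$signatures
  if (nrow(s)) {
    keep <- !is.na(s$apobec_fraction)
    rows <- c(rows, list(
      data.frame(patient_id = s$patient_id[keep], class = "SIG",
                 key = "apobec_fraction",
                 value = format(s$apobec_fraction[keep], digits = 12)),
      data.frame(patient_id = s$patient_id[!is.na(s$chromothripsis_cnvsig)],
                 class = "SIG", key = "chromothripsis_cnvsig",
                 value = as.character(
                   as.integer(s$chromothripsis_cnvsig[!is.na(s$chromothripsis_cnvsig)])))))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$class, out$key), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
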