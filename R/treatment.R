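#' Treatment-course taxonomies
#'
#' Induction strategies are the eight categories generated by the three drug
#' classes used first line — immunomodulatory agents (IMID), proteasome
#' inhibitors (PI), and conventional chemotherapy — i.e. the seven non-empty
#' class combinations plus an explicit `other` reference category (the
#' subset lattice has only seven non-empty elements, so `other` keeps the
#' count at eight). Post-induction strategies are observation, HDM-ASCT,
#' HDM-ASCT plus maintenance/continuous treatment, and maintenance-only.
#'
#' @return character vector of category names.
#' @export
induction_categories <- function() {
  c("other", "chemo", "IMID", "PI",
    "IMID+chemo", "PI+chemo", "PI+IMID", "PI+IMID+chemo")
}

#' @rdname induction_categories
#' @export
postinduction_categories <- function() {
  c("observation", "HDM-ASCT", "HDM-ASCT+MCT", "MCT")
}

# drug-class indicator encoding of an induction category
.induction_indicators <- function(induction) {
  data.frame(ind_imid = as.numeric(grepl("IMID", induction)),
             ind_pi = as.numeric(grepl("PI", induction)),
             ind_chemo = as.numeric(grepl("chemo", induction)))
}

.post_indicators <- function(postinduction) {
  data.frame(hdm_asct = as.numeric(grepl("HDM-ASCT", postinduction)),
             maintenance = as.numeric(grepl("MCT", postinduction)))
}

#' Enumerate treatment courses
#'
#' Full cross product of the induction and post-induction taxonomies in a
#' stable order; default taxonomies give the 32 courses (8 x 4).
#'
#' @param inductions,postinductions category vectors (non-empty).
#' @return data.frame (course_id, induction, postinduction).
#' @export
enumerate_courses <- function(inductions = induction_categories(),
                              postinductions = postinduction_categories()) {
  if (!length(inductions) || !length(postinductions))
    stop("treatment taxonomies must be non-empty")
  g <- expand.grid(postinduction = postinductions, induction = inductions,
                   stringsAsFactors = FALSE)[, 2:1]
  g$course_id <- paste(g$induction, g$postinduction, sep = " / ")
  g[c("course_id", "induction", "postinduction")]
}

#' The four VRd-anchored courses
#'
#' PI+IMID induction (the bortezomib-lenalidomide-dexamethasone pattern) with
#' and without HDM-ASCT and maintenance/continuous treatment.
#' @return data.frame of 4 courses.
#' @export
vrd_courses <- function() enumerate_courses("PI+IMID")
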