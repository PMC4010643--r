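#' Packaged cohort fixtures
#'
#' Three published summary tables of a 14-tumour bladder-cancer
#' whole-genome discovery cohort are shipped as plain TSVs, plus a
#' partly synthetic worked-example mutant set:
#' \describe{
#'   \item{`load_patient_table()`}{demographic/clinicopathological rows:
#'     tumour id, age, sex, smoking status, stage (pTa/pT1/pT2), grade.}
#'   \item{`load_cohort_summary()`}{per-tumour burden profile: exomic
#'     (ESM) and genomic (GSM) somatic mutation counts, per cent of the
#'     genome with copy-number change (`cnv_pct`), number of discrete
#'     CNVs, and the number of sub-clonal clusters (`clonality`). Grade,
#'     age, sex and smoking status are merged in from the patient table.
#'     One tumour has exome data only (GSM and CNV columns NA).}
#'   \item{`load_driver_table()`}{the 48 driver-gene mutations surviving
#'     the prioritization cascade, with per-mutation LOH status (NA where
#'     not assessable, e.g. X-linked in males).}
#'   \item{`load_cdkn1a_set()`}{the six CDKN1A-mutant cancers used in the
#'     LOH worked example: the two discovery-set mutations are
#'     transcribed, the four replication-set rows are synthetic
#'     placeholders carrying only the published aggregate (four further
#'     mutations; two of six with LOH in total).}
#' }
#'
#' @return a data.frame.
#' @name fixtures
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "uroscape")
  if (path == "") stop("fixture not found: ", file)
  path
}

#' @rdname fixtures
#' @export
load_patient_table <- function() {
  utils::read.table(.extdata("table1_patients.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(tumour = "character"))
}

#' @rdname fixtures
#' @export
load_cohort_summary <- function() {
  t2 <- utils::read.table(.extdata("table2_cohort_summary.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(tumour = "character"))
  t1 <- load_patient_table()
  merge(t2, t1[, c("tumour", "age", "sex", "smoker", "grade")],
        by = "tumour", sort = FALSE)
}

#' @rdname fixtures
#' @export
load_driver_table <- function() {
  utils::read.table(.extdata("table3_driver_mutations.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(tumour = "character",
                                   chrom = "character"))
}

#' @rdname fixtures
#' @export
load_cdkn1a_set <- function() {
  utils::read.table(.extdata("cdkn1a_mutants_synthetic.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(sample = "character"))
}

#' Burden extrema of a cohort summary
#'
#' Convenience lookup used in reporting: the samples and values at the
#' minimum/maximum of a burden column.
#'
#' @param summary data.frame from [load_cohort_summary()].
#' @param column burden column name.
#' @return list(`min`, `min_sample`, `max`, `max_sample`).
#' @export
burden_extrema <- function(summary, column) {
  v <- summary[[column]]
  if (is.null(v)) stop("no such column: ", column)
  ok <- !is.na(v)
  list(min = min(v[ok]), min_sample = summary$tumour[ok][which.min(v[ok])],
       max = max(v[ok]), max_sample = summary$tumour[ok][which.max(v[ok])])
}
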