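# Shared constants and small helpers.

.PHENO_LABELS <- c(
  "prevalent_MI", "incident_MI",
  "prevalent_CAD_noMI", "incident_CAD_noMI",
  "sr_MI", "sr_CAD_noMI",
  "never_CAD", "no_CAD"
)
.CASE_LABELS <- .PHENO_LABELS[1:6]
.CONTROL_LABELS <- .PHENO_LABELS[7:8]
.INCIDENT_LABELS <- c("incident_MI", "incident_CAD_noMI")

.EVENT_SOURCES <- c("hospital_dx", "hospital_proc", "death_registry",
                    "selfreport_proc")
.CODE_SYSTEMS <- c("ICD10", "ICD9", "OPCS4", "SELFREPORT")
.PHENO_TAGS <- c("MI", "CAD_noMI")

#' Default administrative censor date
#'
#' Last date of guaranteed complete follow-up across the linked hospital and
#' mortality sources. Events and deaths after this date are ignored by the
#' classifier and treated as censored by the survival evaluation.
#'
#' @return A `Date` (2016-11-01).
#' @export
default_censor_date <- function() as.Date("2016-11-01")

#' Phenotype label sets
#'
#' The eight-way partition produced by the phenotyping algorithm: six CAD
#' sub-phenotype labels and two CAD-free control labels.
#'
#' @param which `"all"`, `"case"` (the six disease labels) or `"control"`.
#' @return Character vector of labels in hierarchy order.
#' @export
cad_labels <- function(which = c("all", "case", "control")) {
  switch(match.arg(which),
    all = .PHENO_LABELS,
    case = .CASE_LABELS,
    control = .CONTROL_LABELS
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# min over possibly-empty / NA-laden date vector without warnings
.min_date <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) min(x) else as.Date(NA)
}

.as_date <- function(x) {
  if (inherits(x, "Date")) return(as.Date(x))
  as.Date(as.character(x), format = "%Y-%m-%d")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
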