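# CSV ingestion ----------------------------------------------------------

#' Read a case line list
#'
#' Expects columns `admission_date` (ISO-8601), `clinic_id`, `species`,
#' `record_class`.
#' @param path CSV file.
#' @return data.frame with `admission_date` parsed as `Date`.
#' @export
read_cases <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("admission_date", "clinic_id", "species", "record_class")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("case file missing columns: ",
                         paste(miss, collapse = ", "))
  x$admission_date <- as.Date(x$admission_date)
  if (anyNA(x$admission_date)) stop("unparseable admission dates")
  x
}

#' Read a fortnightly covariate table
#'
#' Expects `year`, `fortnight` and covariate columns on a regular gap-free
#' fortnight grid.
#' @param path CSV file.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "fortnight") %in% names(x))) {
    stop("covariate file must have year and fortnight columns")
  }
  step <- x$year * 24L + x$fortnight
  if (any(diff(step) != 1L)) stop("covariate grid has gaps or is unordered")
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}
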