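#' Read and write right-censored survival data as delimited text
#'
#' The on-disk format is a plain CSV with columns `time` (years, >= 0),
#' `event` (1 = observed event, 0 = censored) and any covariate columns
#' (e.g. `arm`).
#'
#' @param path file path.
#' @return data frame validated by the package's schema checks.
#' @export
read_surv_data <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_surv_data(dat)
  dat
}

#' @rdname read_surv_data
#' @param data survival data frame to write.
#' @export
write_surv_data <- function(data, path) {
  check_surv_data(data)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
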