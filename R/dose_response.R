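#' Construct a dose-response table
#'
#' Rows pair a positive dose with the fraction of cells affected (growth
#' inhibited) at that dose. Fractions at exactly 0 or 1 are undefined on the
#' logit scale used by the median-effect fit, so observed values outside
#' \code{(eps, 1 - eps)} are clipped with a warning.
#'
#' @param dose numeric vector of positive doses
#' @param fa numeric vector of fractions affected
#' @param drug_label free-text label
#' @param eps clipping bound for \code{fa} (default \code{1e-3})
#' @return data.frame of class \code{dose_response} with columns
#'   \code{dose}, \code{fa}
#' @export
dose_response <- function(dose, fa, drug_label = "", eps = 1e-3) {
  dose <- as.numeric(dose); fa <- as.numeric(fa)
  if (length(dose) != length(fa)) stop("dose and fa differ in length")
  if (anyNA(dose) || anyNA(fa)) stop("dose/fa must not contain NA")
  if (any(dose <= 0)) stop("all doses must be > 0")
  if (length(unique(dose)) < 2L) stop("need at least 2 distinct doses")
  if (any(fa <= 0) || any(fa >= 1)) {
    warning("fa value(s) outside (0,1) clipped to [", eps, ", ", 1 - eps, "]")
    fa <- pmin(pmax(fa, eps), 1 - eps)
  }
  out <- data.frame(dose = dose, fa = fa)
  attr(out, "drug_label") <- as.character(drug_label)[1L]
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Read a dose-response CSV
#'
#' Expects a header with columns \code{dose} and \code{fa}.
#' @param path CSV file
#' @param drug_label label for the table (defaults to the file name)
#' @return a \code{\link{dose_response}} table
#' @export
read_dose_response <- function(path, drug_label = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dose", "fa") %in% names(tab)))
    stop("dose-response CSV needs columns 'dose' and 'fa'")
  dose_response(tab$dose, tab$fa, drug_label = drug_label)
}

#' Write a dose-response CSV
#' @param x a \code{dose_response}
#' @param path destination
#' @return invisibly, \code{x}
#' @export
write_dose_response <- function(x, path) {
  utils::write.csv(data.frame(dose = x$dose, fa = x$fa), path, row.names = FALSE,
                   quote = FALSE)
  invisible(x)
}
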