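#' Turbidity from percent transmittance
#'
#' Condensate formation clouds a sample; turbidity is reported as the
#' complement of the percent transmittance measured at 550 nm:
#' `turbidity = 100 - transmittance`. Fully transparent samples (100%
#' transmittance) have zero turbidity; strongly scattering samples (e.g. 5%
#' transmittance) are almost maximally turbid (95%).
#'
#' @param transmittance_percent Numeric vector of transmittance values in
#'   `[0, 100]`.
#' @return A data frame of class `turbidity_reading` with columns
#'   `transmittance_percent` and `turbidity_percent`.
#' @examples
#' turbidity_from_transmittance(c(100, 36, 5))
#' @export
turbidity_from_transmittance <- function(transmittance_percent) {
  if (any(!is.finite(transmittance_percent)) ||
      any(transmittance_percent < 0 | transmittance_percent > 100))
    stop("turbidity_from_transmittance(): transmittance must lie in ",
         "[0, 100]")
  out <- data.frame(transmittance_percent = transmittance_percent,
                    turbidity_percent = 100 - transmittance_percent)
  class(out) <- c("turbidity_reading", "data.frame")
  out
}

#' Convert a turbidity CSV
#'
#' Reads a CSV with columns `sample` and `transmittance_percent`, appends
#' `turbidity_percent` and optionally writes the result back out.
#'
#' @param path Input CSV path.
#' @param out Optional output CSV path.
#' @return The augmented data frame, invisibly when `out` is given.
#' @export
turbidity_table <- function(path, out = NULL) {
  d <- read.csv(path)
  if (!"transmittance_percent" %in% names(d))
    stop("turbidity_table(): column 'transmittance_percent' required")
  d$turbidity_percent <-
    turbidity_from_transmittance(d$transmittance_percent)$turbidity_percent
  if (!is.null(out)) {
    write.csv(d, out, row.names = FALSE)
    return(invisible(d))
  }
  d
}
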