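`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
cf_log <- function(...) {
  if (isTRUE(getOption("cryofit.verbose", FALSE))) message("cryofit: ", ...)
  invisible(NULL)
}

stop_cf <- function(...) stop(..., call. = FALSE)

## element -> atomic number for the elements that occur in macromolecular
## models; extended on demand
.element_z <- c(
  "H" = 1, "HE" = 2, "LI" = 3, "BE" = 4, "B" = 5, "C" = 6, "N" = 7,
  "O" = 8, "F" = 9, "NE" = 10, "NA" = 11, "MG" = 12, "AL" = 13, "SI" = 14,
  "P" = 15, "S" = 16, "CL" = 17, "AR" = 18, "K" = 19, "CA" = 20,
  "MN" = 25, "FE" = 26, "CO" = 27, "NI" = 28, "CU" = 29, "ZN" = 30,
  "SE" = 34, "BR" = 35, "I" = 53
)

element_to_z <- function(element) {
  z <- unname(.element_z[toupper(trimws(element))])
  z
}
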