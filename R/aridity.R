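## Aridity index, UNEP climate classification, and the x10,000 integer
## encoding used when distributing AI rasters.

#' Aridity index
#'
#' Unitless ratio of mean annual precipitation to mean annual reference
#' evapotranspiration, \eqn{AI = MA\_Prec / MA\_ET_0}; higher values are
#' more humid. A zero ET0 denominator yields `NA` (nodata), never
#' infinity.
#'
#' @param ma_prec Mean annual precipitation (mm yr-1), non-negative.
#' @param ma_et0 Mean annual reference evapotranspiration (mm yr-1).
#' @return Aridity index (unitless). Vectorised.
#' @examples
#' aridity_index(990, 1980)  # 0.5
#' @export
aridity_index <- function(ma_prec, ma_et0) {
  if (any(ma_prec < 0, na.rm = TRUE)) {
    stop("`ma_prec` must be >= 0", call. = FALSE)
  }
  if (any(ma_et0 < 0, na.rm = TRUE)) {
    stop("`ma_et0` must be >= 0", call. = FALSE)
  }
  out <- ma_prec / ma_et0
  out[!is.na(ma_et0) & ma_et0 == 0] <- NA_real_
  out
}

#' UNEP aridity classification
#'
#' Maps aridity index values onto the UNEP climate classes:
#' below 0.03 Hyper Arid; 0.03 to 0.2 Arid; 0.2 to 0.5 Semi-Arid; 0.5 to
#' 0.65 Dry sub-humid; above 0.65 Humid. Interior boundaries are
#' lower-inclusive; 0.65 itself is Dry sub-humid (Humid is strictly above
#' 0.65).
#'
#' @param ai Aridity index values, non-negative.
#' @return Factor with levels `Hyper Arid`, `Arid`, `Semi-Arid`,
#'   `Dry sub-humid`, `Humid`.
#' @examples
#' classify_unep(c(0.01, 0.3, 0.65, 0.66))
#' @export
classify_unep <- function(ai) {
  if (any(ai < 0, na.rm = TRUE)) stop("`ai` must be >= 0", call. = FALSE)
  # lower-inclusive interior boundaries; the humid end is strict (> 0.65)
  idx <- 1L + (ai >= 0.03) + (ai >= 0.2) + (ai >= 0.5) + (ai > 0.65)
  factor(unep_classes()[idx], levels = unep_classes())
}

#' @rdname classify_unep
#' @export
unep_classes <- function() {
  c("Hyper Arid", "Arid", "Semi-Arid", "Dry sub-humid", "Humid")
}

#' Integer encoding of aridity index values
#'
#' Distributed AI rasters are stored as integers, the unitless index
#' multiplied by 10,000 (4 decimal accuracy); `encode_ai()` rounds half
#' away from zero, `decode_ai()` multiplies back by 0.0001. Round-trip
#' error is at most 5e-5.
#'
#' @param ai Aridity index values, non-negative.
#' @param encoded Integer-encoded values.
#' @return `encode_ai`: integer vector; `decode_ai`: numeric vector.
#' @examples
#' encode_ai(0.1234567)  # 1235
#' decode_ai(1235)       # 0.1235
#' @export
encode_ai <- function(ai) {
  if (any(ai < 0, na.rm = TRUE)) stop("`ai` must be >= 0", call. = FALSE)
  x <- ai * 10000
  if (any(x > .Machine$integer.max - 0.5, na.rm = TRUE)) {
    stop("encoded value overflows integer storage", call. = FALSE)
  }
  as.integer(floor(x + 0.5))   # half away from zero on the non-negative axis
}

#' @rdname encode_ai
#' @export
decode_ai <- function(encoded) encoded * 0.0001

#' Aridity summary for one location
#'
#' Annual and monthly aridity indices plus the UNEP class and the integer
#' encoding, from monthly precipitation and ET0 totals. Months with zero
#' ET0 (polar winter) get `NA` monthly AI; the annual index is still
#' computed from annual totals when annual ET0 is positive.
#'
#' @param prec_monthly Monthly precipitation totals (mm), length 12.
#' @param et0_monthly Monthly ET0 totals (mm), length 12.
#' @return An object of class `aridity_result`: list with `ai`,
#'   `ai_monthly` (12), `unep_class`, `encoded`.
#' @examples
#' aridity_location(rep(50, 12), rep(100, 12))
#' @export
aridity_location <- function(prec_monthly, et0_monthly) {
  stopifnot(length(prec_monthly) == 12, length(et0_monthly) == 12)
  ai <- aridity_index(sum(prec_monthly), sum(et0_monthly))
  structure(list(
    ai = ai,
    ai_monthly = aridity_index(prec_monthly, et0_monthly),
    unep_class = if (is.na(ai)) NA_character_
                 else as.character(classify_unep(ai)),
    encoded = if (is.na(ai)) NA_integer_ else encode_ai(ai)),
    class = "aridity_result")
}

#' @export
print.aridity_result <- function(x, ...) {
  cat(sprintf("Aridity index %.4f (%s), encoded %d\n",
              x$ai, x$unep_class, x$encoded))
  invisible(x)
}
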