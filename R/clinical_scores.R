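# Clinical scoring and classification: Hyperthyroidism Symptom Scale totals,
# thyroid-status labels against assay reference ranges, the binary
# thyrotoxicosis outcome, and 1-SD standardization for the GEE analyses.

#' Thyroid assay reference ranges
#'
#' @param ft4_low,ft4_high Free T4 reference range, ng/dL (defaults
#'   0.89-1.79).
#' @param tsh_low,tsh_high TSH reference range, mIU/L (defaults 0.3-4.0).
#' @param binary_ft4_cutoff Free T4 cutoff (ng/dL) defining the binary
#'   thyrotoxicosis outcome; the boundary is inclusive ("1.8 or more").
#' @return An object of class `ref_ranges`.
#' @export
ref_ranges <- function(ft4_low = 0.89, ft4_high = 1.79,
                       tsh_low = 0.3, tsh_high = 4.0,
                       binary_ft4_cutoff = 1.8) {
  stopifnot(ft4_low < ft4_high, tsh_low < tsh_high, binary_ft4_cutoff > 0)
  structure(list(ft4_low = ft4_low, ft4_high = ft4_high,
                 tsh_low = tsh_low, tsh_high = tsh_high,
                 binary_ft4_cutoff = binary_ft4_cutoff),
            class = "ref_ranges")
}

#' Hyperthyroidism Symptom Scale total
#'
#' Sums the 10 item scores of the HSS. Each item is scored 0-4, so the
#' total ranges 0-40.
#'
#' @param items Exactly 10 integer item scores, each in 0-4.
#' @return The integer total, in \[0, 40\].
#' @export
hss_total <- function(items) {
  if (length(items) != 10L) {
    stop("HSS requires exactly 10 item scores, got ", length(items),
         call. = FALSE)
  }
  if (anyNA(items) || any(items != floor(items)) ||
      any(items < 0 | items > 4)) {
    bad <- which(is.na(items) | items != floor(items) | items < 0 | items > 4)[1]
    stop("HSS item ", bad, " has value ", format(items[bad]),
         "; items must be integers in 0-4", call. = FALSE)
  }
  as.integer(sum(items))
}

#' Classify thyroid status from free T4 and TSH
#'
#' Overt thyrotoxicosis: free T4 above and TSH below the reference range.
#' Subclinical thyrotoxicosis: free T4 within range with TSH below range.
#' Euthyroid: both within range. Everything else is `"other"`.
#'
#' @param ft4 Free T4, ng/dL (> 0). Vectorized.
#' @param tsh TSH, mIU/L (> 0). Vectorized.
#' @param refs A [ref_ranges()].
#' @return Character vector of labels in
#'   `{"overt", "subclinical", "euthyroid", "other"}`.
#' @export
classify_status <- function(ft4, tsh, refs = ref_ranges()) {
  if (any(!is.finite(ft4) | ft4 <= 0) || any(!is.finite(tsh) | tsh <= 0)) {
    stop("ft4 and tsh must be positive finite values", call. = FALSE)
  }
  ft4_in <- ft4 >= refs$ft4_low & ft4 <= refs$ft4_high
  tsh_in <- tsh >= refs$tsh_low & tsh <= refs$tsh_high
  out <- rep("other", length(ft4))
  out[ft4 > refs$ft4_high & tsh < refs$tsh_low] <- "overt"
  out[ft4_in & tsh < refs$tsh_low] <- "subclinical"
  out[ft4_in & tsh_in] <- "euthyroid"
  out
}

#' Binary thyrotoxicosis outcome
#'
#' `TRUE` iff free T4 is at or above the cutoff (boundary inclusive).
#'
#' @inheritParams classify_status
#' @return Logical vector.
#' @export
binary_thyrotoxic <- function(ft4, refs = ref_ranges()) {
  ft4 >= refs$binary_ft4_cutoff
}

#' Standardize a variable to mean 0, SD 1
#'
#' Centers and scales with the sample SD (n - 1 denominator) and retains
#' the statistics so effects can be reported per 1 SD of the original
#' variable and z-scores can be mapped back.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @param variable Name recorded in the retained statistics.
#' @return A list of class `std_scale` with `z` (the z-scores), `mean`,
#'   `sd`, `n` and `variable`.
#' @export
standardize <- function(x, variable = deparse(substitute(x))) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  if (length(unique(x[ok])) < 2L) {
    stop("cannot standardize '", variable,
         "': fewer than 2 distinct values (degenerate variance)",
         call. = FALSE)
  }
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  structure(list(z = (x - m) / s, mean = m, sd = s, n = sum(ok),
                 variable = variable),
            class = "std_scale")
}

#' Map z-scores back to the original scale
#'
#' @param z Numeric z-scores.
#' @param scale A `std_scale` from [standardize()].
#' @return `z * scale$sd + scale$mean`.
#' @export
unstandardize <- function(z, scale) {
  stopifnot(inherits(scale, "std_scale"))
  z * scale$sd + scale$mean
}

#' Add derived clinical columns to a visit table
#'
#' Adds the thyroid-status label and the binary thyrotoxicosis outcome.
#'
#' @param visits A visit table with `ft4_ng_dl` and `tsh_miu_l` columns.
#' @param refs A [ref_ranges()].
#' @return The table with `status` and `thyrotoxic_binary` columns added.
#' @export
augment_visits <- function(visits, refs = ref_ranges()) {
  visits$status <- classify_status(visits$ft4_ng_dl, visits$tsh_miu_l, refs)
  visits$thyrotoxic_binary <- binary_thyrotoxic(visits$ft4_ng_dl, refs)
  visits
}
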