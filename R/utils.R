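#' @keywords internal
"_PACKAGE"

# days per year used for all person-time conversions
DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' Analysis windows anchored at the index date
#'
#' Day offsets (closed-open) of the early-treatment baseline window and the
#' four on-treatment windows.  Months are mapped to fixed day boundaries
#' (90/365/730/1095/1460) so the partition is deterministic and independent
#' of calendar months.
#'
#' @return A data frame with columns `window`, `lo`, `hi` (day offsets from
#'   the index date; a day `t` belongs to a window iff `lo <= t < hi`).
#' @export
analysis_windows <- function() {
  data.frame(
    window = c("early", "m4_12", "m13_24", "m25_36", "m37_48"),
    lo = c(0L, 90L, 365L, 730L, 1095L),
    hi = c(90L, 365L, 730L, 1095L, 1460L),
    stringsAsFactors = FALSE
  )
}

ON_TREATMENT_WINDOWS <- c("m4_12", "m13_24", "m25_36", "m37_48")

# order-preserving first row per group (assumes x sorted as desired)
first_per_group <- function(x, key) x[!duplicated(key), , drop = FALSE]

stop_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}
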