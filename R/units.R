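# Radioactivity and sensitivity unit conversions. 1 mCi = 37 MBq exactly.

.activity_in_Bq <- c(Bq = 1, kBq = 1e3, MBq = 1e6,
                     uCi = 37e3, mCi = 37e6)

.norm_activity_unit <- function(u) {
  u <- sub("μ", "u", u)  # accept Greek mu
  if (!u %in% names(.activity_in_Bq))
    stop("unknown activity unit '", u, "' (use ",
         paste(names(.activity_in_Bq), collapse = ", "), ")")
  u
}

#' Convert radioactivity units
#'
#' Exact scale conversion between Bq, kBq, MBq, uCi and mCi
#' (1 mCi = 37 MBq exactly). Works element-wise on vectors; concentration
#' values (e.g. mCi/ml to kBq/ml) convert with the same factors since the
#' volume unit is shared.
#'
#' @param value numeric activity value(s).
#' @param from,to unit names among "Bq", "kBq", "MBq", "uCi", "mCi"
#'   (the Greek micro sign is accepted for "uCi").
#' @return converted numeric value(s).
#' @examples
#' convert_activity(1.1, "mCi", "MBq")   # 40.7
#' convert_activity(100, "mCi", "MBq")   # 3700
#' @export
convert_activity <- function(value, from, to) {
  from <- .norm_activity_unit(from); to <- .norm_activity_unit(to)
  value * .activity_in_Bq[[from]] / .activity_in_Bq[[to]]
}

#' Convert detector sensitivity units
#'
#' Converts between cpm/uCi and cpm/kBq (1 uCi = 37 kBq exactly). Camera
#' sensitivities are conventionally quoted to two decimals in cpm/kBq;
#' set `digits` to round the result for reporting.
#'
#' @param value numeric sensitivity value(s).
#' @param from,to "cpm/uCi" or "cpm/kBq".
#' @param digits optional rounding of the result (NULL = exact).
#' @return converted numeric value(s).
#' @examples
#' convert_sensitivity(90, "cpm/uCi", "cpm/kBq", digits = 2)   # 2.43
#' @export
convert_sensitivity <- function(value, from, to, digits = NULL) {
  norm <- function(u) sub("μ", "u", u)
  from <- norm(from); to <- norm(to)
  # denominator activity in kBq: cpm/uCi quotes counts per 37 kBq
  denom_kBq <- c("cpm/uCi" = 37, "cpm/kBq" = 1)
  if (!from %in% names(denom_kBq)) stop("unknown sensitivity unit '", from, "'")
  if (!to %in% names(denom_kBq)) stop("unknown sensitivity unit '", to, "'")
  out <- value * denom_kBq[[to]] / denom_kBq[[from]]
  if (!is.null(digits)) out <- round(out, digits)
  out
}
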