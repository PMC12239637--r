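#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; report tables instead round
#' half up (0.3375 -> 0.338 at 3 decimals), matching how proportions are
#' conventionally printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
roundHalfUp <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @noRd
.assertThat <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' @noRd
.speciesLevels <- function() c("SL", "SP")

#' @noRd
.tissueLevels <- function() c("leaf", "pollen", "style")

## deterministic formatting for result tables: 6 significant digits
#' @noRd
.signifCols <- function(df, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}
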