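#' Unit conversion helpers
#'
#' Internal computation is in CGS units (cm, g, s, dyn). These helpers convert
#' the clinical/reporting units used at the I/O surface.
#'
#' @param x numeric value(s) to convert.
#' @return converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_dyn <- function(x) x * 1333.22

#' @rdname units
#' @export
dyn_to_mmHg <- function(x) x / 1333.22

#' @rdname units
#' @export
mm_to_cm <- function(x) x / 10

#' @rdname units
#' @export
cm_to_mm <- function(x) x * 10
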