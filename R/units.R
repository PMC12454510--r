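# Unit conventions: all quantities are stored internally in SI (m, s, Pa).
# Configuration files accept lengths in micrometres and pressures in mmHg,
# converted on load with the exact factor below.

#' Conversion factor between mmHg and Pa
#'
#' Fixed at 133.322 Pa per mmHg throughout the package.
#' @keywords internal
.MMHG <- 133.322

#' Convert pressures between mmHg and Pa
#'
#' The package stores every quantity in SI units; these helpers convert
#' user-facing pressures (conversion factor exactly 133.322 Pa/mmHg).
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @export
#' @examples
#' mmhg_to_pa(-2.5)
mmhg_to_pa <- function(x) x * .MMHG

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / .MMHG
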