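# Unit conversions. Clinical units (mm, mmHg, mL/min) at every user surface,
# SI (m, Pa, m^3/s) internally. Conversion constants are fixed here and used
# nowhere else.

PA_PER_MMHG <- 133.322
M3S_PER_MLMIN <- 1e-6 / 60

#' Convert between clinical and SI pressure/flow units
#'
#' Pressures convert with 1 mmHg = 133.322 Pa; flows with
#' 1 mL/min = 1e-6/60 m^3/s; lengths with 1 mm = 1e-3 m.
#'
#' @param x numeric vector of values to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(69.54)
#' mlmin_to_m3s(66.75)
#' @export
mmhg_to_pa <- function(x) x * PA_PER_MMHG

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / PA_PER_MMHG

#' @rdname mmhg_to_pa
#' @export
mlmin_to_m3s <- function(x) x * M3S_PER_MLMIN

#' @rdname mmhg_to_pa
#' @export
m3s_to_mlmin <- function(x) x / M3S_PER_MLMIN

#' @rdname mmhg_to_pa
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname mmhg_to_pa
#' @export
m_to_mm <- function(x) x * 1e3
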