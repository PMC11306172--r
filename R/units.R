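#' Unit conversion between mmHg and MPa
#'
#' The solver works in a consistent mm-g-ms unit system in which stress is in
#' MPa, force in N and energy in mJ. Clinical pressures are quoted in mmHg;
#' these helpers convert at 1 mmHg = 1.33322e-4 MPa.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_mpa(15)
#' mpa_to_mmhg(mmhg_to_mpa(15))
#' @export
mmhg_to_mpa <- function(x) x * 1.33322e-4

#' @rdname mmhg_to_mpa
#' @export
mpa_to_mmhg <- function(x) x / 1.33322e-4

# gravitational acceleration, mm/ms^2
.GRAVITY <- 9.81e-3

# soft tissue density, g/mm^3
.TISSUE_DENSITY <- 1.05e-3

# smoothstep ramp on [0, 1]
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

stop_wiop <- function(...) stop(..., call. = FALSE)
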