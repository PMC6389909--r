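#' @keywords internal
#' @import methods
"_PACKAGE"

## Gas constant in kcal mol^-1 K^-1 -- all enthalpies / heat capacities in
## this package are kcal-based, matching the units DSF practitioners quote.
.RGAS <- 1.987204e-3

## Celsius <-> kelvin offset. All instrument-facing I/O is in degrees
## Celsius; thermodynamic expressions require absolute temperature.
.C2K <- 273.15

#' Convert between Celsius and kelvin
#'
#' Thin helpers used throughout: melt tables and slice temperatures are in
#' degrees Celsius (the instrument scale); Gibbs-Helmholtz math is in kelvin.
#'
#' @param x numeric vector of temperatures.
#' @return numeric vector on the other scale.
#' @examples
#' celsiusToKelvin(50)   # 323.15
#' kelvinToCelsius(323.15)
#' @export
celsiusToKelvin <- function(x) x + .C2K

#' @rdname celsiusToKelvin
#' @export
kelvinToCelsius <- function(x) x - .C2K
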