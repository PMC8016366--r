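#' Physical constants used throughout the package
#'
#' CODATA values, SI units.  `default_temperature` is room temperature.
#'
#' @format A named list with elements
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{e}{elementary charge, C}
#'   \item{h}{Planck constant, J s}
#'   \item{NA_avogadro}{Avogadro constant, 1/mol}
#'   \item{debye}{one debye in C m}
#'   \item{default_temperature}{298 K}
#' }
#' @export
pc_constants <- list(
  kB = 1.380649e-23,
  e = 1.602176634e-19,
  h = 6.62607015e-34,
  NA_avogadro = 6.02214076e23,
  debye = 3.33564e-30,
  default_temperature = 298
)
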