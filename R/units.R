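#' Unit conversion between mmHg and CGS pressure
#'
#' All internal computation in coroflow is in CGS units (cm, g, s, dyn/cm2).
#' Pressures cross the package boundary (configuration files, printed
#' summaries) in mmHg and are converted with these helpers.
#' 1 mmHg = 1333.22 dyn/cm2.
#'
#' @param p pressure (scalar or vector)
#' @return converted pressure
#' @export
mmhg_to_cgs <- function(p) p * 1333.22

#' @rdname mmhg_to_cgs
#' @export
cgs_to_mmhg <- function(p) p / 1333.22

# internal constant
MMHG <- 1333.22
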