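# Unit conversion constants and helpers. All interfaces use micrometres,
# square/cubic micrometres, nanolitres, minutes and centipoise; SI appears
# only inside flux/drag conversions, each through the constants below.

#' Unit conversions between the package's working units and SI
#'
#' The package works in micrometres, minutes, nanolitres and centipoise at
#' every interface; these helpers and constants are the single place where
#' conversions to SI happen.
#'
#' @param v_nl Volume in nanolitres.
#' @param v_um3 Volume in cubic micrometres.
#' @return `nl_to_um3()` returns cubic micrometres; `um3_to_nl()` returns
#'   nanolitres.
#' @examples
#' nl_to_um3(1)      # 1e6 um^3
#' um3_to_nl(3.78e5) # 0.378 nL
#' @name units
NULL

# 1 nL = 1e6 um^3
UM3_PER_NL <- 1e6

# 1 m^2/s = 6e13 um^2/min
M2_PER_S_TO_UM2_PER_MIN <- 6e13

# 1 cP = 1e-3 Pa s
CP_TO_PA_S <- 1e-3

# molar gas constant, J/(mol K); named R_GAS to avoid clashing with the
# droplet radius R used throughout the geometry
R_GAS <- 8.314

#' @rdname units
#' @export
nl_to_um3 <- function(v_nl) v_nl * UM3_PER_NL

#' @rdname units
#' @export
um3_to_nl <- function(v_um3) v_um3 / UM3_PER_NL
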