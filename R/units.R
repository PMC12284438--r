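# Exact unit conversion constants. All internal solver arithmetic is SI
# (m, s, kg, Pa); user-facing interfaces are clinical/CGS-style units
# (mmHg, mL/s, cm, kPa).

#' @keywords internal
.MMHG_PA <- 133.322387415    # 1 mmHg in Pa
#' @keywords internal
.KPA_PA <- 1000              # 1 kPa in Pa
#' @keywords internal
.CM_M <- 0.01                # 1 cm in m
#' @keywords internal
.CM2_M2 <- 1e-4              # 1 cm^2 in m^2
#' @keywords internal
.ML_M3 <- 1e-6               # 1 mL in m^3

# resistance: mmHg.s/mL -> Pa.s/m^3
.R_SI <- .MMHG_PA / .ML_M3
# compliance: mL/mmHg -> m^3/Pa
.C_SI <- .ML_M3 / .MMHG_PA

mmhg_to_kpa <- function(x) x * .MMHG_PA / .KPA_PA
kpa_to_mmhg <- function(x) x * .KPA_PA / .MMHG_PA
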