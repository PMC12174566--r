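# ---------------------------------------------------------------------------
# Shipped study fixtures: the Meniere's disease case (clinical pattern of
# liver excess with spleen and kidney deficiency), its clinically
# validated reference protocol, the fifteen randomized screening protocols
# (strategies R, M, C, five rounds each), and the printed component scores
# of the screening table.
# ---------------------------------------------------------------------------

#' Screening protocol fixtures
#'
#' The sixteen shipped protocols: the clinically validated reference
#' (GB20 purged at -3; GV20, GV16, BL23, KI3, GB39 tonified at +3) and the
#' fifteen randomized screening rounds R1-R5 (completely random), M1-M5
#' (meridian-based: liver/spleen/kidney meridians) and C1-C5
#' (correspondence-based: gallbladder/stomach/bladder meridians), parsed
#' and validated through the acupoint registry.
#'
#' @return Named list of [amt_protocol()] objects.
#' @export
fixture_protocols <- function() {
  path <- system.file("extdata", "protocols.json", package = "amtsim")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(raw, function(p) amt_protocol(unlist(p)))
}

#' Meniere's disease case setup
#'
#' `meniere_initial_state()`: liver 5 (excess), spleen and kidney 1
#' (deficiency), all other organs at the healthy baseline 3.
#' `meniere_reference_protocol()`: the validated treatment.
#' `meniere_condition()`: the pattern as a [condition_spec()] for the
#' protocol explorer.
#'
#' @return See above.
#' @export
meniere_initial_state <- function() {
  amt_state(liver = 5, spleen = 1, kidney = 1)
}

#' @rdname meniere_initial_state
#' @export
meniere_reference_protocol <- function() {
  fixture_protocols()[["Reference"]]
}

#' @rdname meniere_initial_state
#' @export
meniere_condition <- function() {
  condition_spec(excess = "liver", deficient = c("spleen", "kidney"),
                 reference = meniere_reference_protocol())
}

#' Printed component scores of the screening study
#'
#' The reported (PTR, fRMSD, PET, Eval) quadruples for the reference
#' protocol and the fifteen screening rounds, as printed in the original
#' study report. Used to pin down the Eval combination arithmetic; the
#' C5 row's PET is recorded as 0.01, the value consistent with its printed
#' Eval of 0.002.
#'
#' @return Data frame with columns `group`, `PTR`, `fRMSD`, `PET`, `Eval`.
#' @export
reference_eval_table <- function() {
  data.frame(
    group = c("Reference", "R1", "R2", "R3", "R4", "R5",
              "M1", "M2", "M3", "M4", "M5",
              "C1", "C2", "C3", "C4", "C5"),
    PTR   = c(0.90, 0.00, 0.00, 0.76, 0.82, 0.76,
              0.74, 0.00, 0.40, 0.48, 0.00,
              0.86, 0.84, 0.60, 0.78, 0.00),
    fRMSD = c(1L, 0L, 0L, 1L, 1L, 1L,
              1L, 0L, 1L, 0L, 1L,
              1L, 1L, 1L, 0L, 0L),
    PET   = c(1.00, 0.06, 0.14, 0.36, 0.38, 0.34,
              0.72, 0.56, 0.24, 0.36, 0.04,
              0.30, 0.06, 0.24, 0.46, 0.01),
    Eval  = c(0.960, 0.012, 0.028, 0.776, 0.804, 0.772,
              0.840, 0.112, 0.608, 0.264, 0.408,
              0.804, 0.748, 0.688, 0.404, 0.002),
    stringsAsFactors = FALSE)
}
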