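#' Antigen panel definitions
#'
#' The 19-antigen panel combines the six DTaP/Hib vaccine antigens with the
#' 13 serotype-specific capsular polysaccharides of the 13-valent
#' pneumococcal conjugate vaccine (PCV13).
#'
#' @return Character vector of antigen identifiers.
#' @export
antigen_panel <- function() c(dtap_hib_antigens(), pcv_antigens())

#' @rdname antigen_panel
#' @export
dtap_hib_antigens <- function() c("DT", "TT", "PT", "FHA", "PRN", "PRP")

#' @rdname antigen_panel
#' @export
pcv_antigens <- function() {
  paste0("PCV", c("1", "3", "4", "5", "6A", "6B", "7F",
                  "9V", "14", "18C", "19A", "19F", "23F"))
}

#' Seroprotective thresholds for the DTaP/Hib antigens
#'
#' Established or presumed protective antibody concentrations used to
#' classify low vaccine responders (LVR). Only the six DTaP/Hib antigens
#' carry thresholds; PCV serotypes are analysed on the continuous scale.
#'
#' @return Data frame with columns `antigen`, `threshold`, `units`.
#' @export
protective_thresholds <- function() {
  data.frame(
    antigen   = c("DT", "TT", "PRP", "PT", "PRN", "FHA"),
    threshold = c(0.1, 0.1, 0.15, 8, 8, 8),
    units     = c("IU/mL", "IU/mL", "ug/mL", "EU/mL", "IU/mL", "IU/mL"),
    stringsAsFactors = FALSE
  )
}
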