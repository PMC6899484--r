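# Packaged example networks (design-level CSV fixtures under extdata/).

fixture_path <- function(name) {
  system.file("extdata", name, package = "nmainc", mustWork = TRUE)
}

#' Lung cancer three-treatment network
#'
#' Design-level pooled log hazard ratios for overall survival comparing
#' radiotherapy (RT), RT plus sequential chemotherapy (SeqCT) and RT plus
#' concomitant chemotherapy (ConCT): one treatment loop, three two-arm
#' designs. Loaded from the packaged CSV fixture.
#'
#' @return an `nma_network`.
#' @export
lung_network <- function() {
  read_contrasts(fixture_path("lung_design_contrasts.csv"))
}

#' Diabetes metformin/sulfonylurea/rosiglitazone loop
#'
#' Design-level pooled HbA1c mean differences for the single treatment loop
#' metformin (metf), sulfonylurea (sulf), rosiglitazone (rosi) of the
#' 10-treatment diabetes network.
#'
#' @return an `nma_network`.
#' @export
diabetes_loop_network <- function() {
  read_contrasts(fixture_path("diabetes_loop_contrasts.csv"))
}

#' Synthetic diabetes-topology network
#'
#' The 10-treatment, 15-design structure of the diabetes network (including
#' one three-arm design) with synthetic effect values; useful for structural
#' checks only (design-matrix shape, degrees of freedom, eligibility).
#'
#' @return an `nma_network`.
#' @export
diabetes_structure_network <- function() {
  read_contrasts(fixture_path("diabetes_structure_synthetic.csv"))
}
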