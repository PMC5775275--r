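# Canonical wheat asparagine synthetase (ASN) mechanism.
#
# The glutaminase and synthetase half-reactions are split into four
# sequential elementary steps plus a dissociation step for the
# ammonia-loaded enzyme:
#   r1: ASNe + Gln                      -> ASNe_Gln
#   r2: ASNe_Gln                        -> Glu + ASNe_NH3
#   r3: ASNe_NH3 + Asp + ATP + Mg      -> bAsp_AMP_ASNe_NH3   (Mg catalytic)
#   r4: bAsp_AMP_ASNe_NH3              -> Asn + ASNe + AMP
#   D : ASNe_NH3                       -> ASNe
# Water and pyrophosphate are ubiquitous and omitted. ATP and Mg are
# clamped: they enter the r3 flux but their concentrations are held
# constant (buffered in large excess in the assay).

.asn_species <- c("AMP", "Asn", "ASNe", "ASNe_Gln", "ASNe_NH3", "Asp",
                  "ATP", "bAsp_AMP_ASNe_NH3", "Gln", "Glu", "Mg")

#' The canonical asparagine synthetase reaction network
#'
#' Builds the 11-species, 5-reaction continuous Petri net of the
#' glutamine-dependent asparagine synthetase mechanism: enzyme-glutamine
#' binding (r1), glutamine hydrolysis releasing glutamate (r2),
#' ATP/Mg-dependent beta-aspartyl-AMP complex formation (r3), asparagine
#' release (r4), and unproductive dissociation of the ammonia-loaded
#' enzyme (D). ATP and Mg2+ are clamped boundary species. Place initials
#' are all zero; use [asn_initial_state()] for the assay conditions.
#'
#' @return A validated `reaction_network`.
#' @export
#' @examples
#' net <- asn_network()
#' stoichiometry_matrix(net)
asn_network <- function() {
  places <- lapply(.asn_species, function(s)
    place(s, initial = 0, clamped = s %in% c("ATP", "Mg")))
  reactions <- list(
    reaction("r1", c(ASNe = 1, Gln = 1), c(ASNe_Gln = 1), "k1"),
    reaction("r2", c(ASNe_Gln = 1), c(Glu = 1, ASNe_NH3 = 1), "k2"),
    reaction("r3", c(ASNe_NH3 = 1, Asp = 1, ATP = 1, Mg = 1),
             c(bAsp_AMP_ASNe_NH3 = 1, Mg = 1), "k3"),
    reaction("r4", c(bAsp_AMP_ASNe_NH3 = 1), c(Asn = 1, ASNe = 1, AMP = 1),
             "k4"),
    reaction("D", c(ASNe_NH3 = 1), c(ASNe = 1), "kD"))
  reaction_network(places, reactions)
}

.asn_params <- list(
  TaASN1 = c(k1 = 0.016, k2 = 3, k3 = 0.043, k4 = 10, kD = 700),
  TaASN2 = c(k1 = 0.02,  k2 = 3, k3 = 0.043, k4 = 10, kD = 400))

.asn_enzyme_start <- c(TaASN1 = 0.1, TaASN2 = 0.09)
.asn_enzyme_molar <- c(TaASN1 = 2.03, TaASN2 = 2.10)  # nmol/mL, informational

#' Reference rate-constant sets for TaASN1 and TaASN2
#'
#' The five fitted mass-action rate constants (k1, k2, k3, k4, kD) for the
#' two wheat asparagine synthetase isoforms, as magnitudes in the package
#' concentration-unit system. The two isoforms share k2, k3 and k4 and
#' differ in k1 and, most markedly, in the dissociation constant kD.
#'
#' @param enzyme `"TaASN1"` or `"TaASN2"`.
#' @return Named numeric vector `c(k1, k2, k3, k4, kD)`.
#' @export
#' @examples
#' asn_rate_params("TaASN1")
asn_rate_params <- function(enzyme = c("TaASN1", "TaASN2")) {
  enzyme <- match.arg(enzyme)
  .asn_params[[enzyme]]
}

#' Enzyme profile: parameters plus start concentration
#'
#' Bundles an isoform's rate constants with its enzyme start value in
#' model concentration units (0.1 for TaASN1, 0.09 for TaASN2) and its
#' molar loading (nmol/mL) as informational metadata.
#'
#' @inheritParams asn_rate_params
#' @return List of class `enzyme_profile` with elements `enzyme`,
#'   `params`, `enzyme_start`, `enzyme_nmol_ml`.
#' @export
asn_enzyme_profile <- function(enzyme = c("TaASN1", "TaASN2")) {
  enzyme <- match.arg(enzyme)
  structure(list(enzyme = enzyme,
                 params = .asn_params[[enzyme]],
                 enzyme_start = .asn_enzyme_start[[enzyme]],
                 enzyme_nmol_ml = .asn_enzyme_molar[[enzyme]]),
            class = "enzyme_profile")
}

#' Default assay initial state
#'
#' The in-vitro activity-assay mixture: 1.6 mM aspartate, 10 mM glutamine,
#' 10 mM ATP, 10 mM MgCl2, enzyme at its isoform start value, and all
#' products and enzyme complexes at zero.
#'
#' @inheritParams asn_rate_params
#' @param overrides Optional named numeric vector of species
#'   concentrations applied after the defaults (e.g. `c(Asp = 0)` for an
#'   aspartate-free run). Unknown species names are an error.
#' @return Named numeric vector over all 11 species, in place order.
#' @export
#' @examples
#' asn_initial_state("TaASN1")
#' asn_initial_state("TaASN2", overrides = c(Asp = 0))
asn_initial_state <- function(enzyme = c("TaASN1", "TaASN2"),
                              overrides = NULL) {
  enzyme <- match.arg(enzyme)
  y <- stats::setNames(numeric(length(.asn_species)), .asn_species)
  y[c("Asp", "Gln", "ATP", "Mg")] <- c(1.6, 10, 10, 10)
  y["ASNe"] <- .asn_enzyme_start[[enzyme]]
  if (length(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), .asn_species)
    if (length(unknown))
      stop("unknown species in overrides: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    y[names(overrides)] <- overrides
  }
  y
}
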