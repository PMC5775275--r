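# Hand-coded reference for the asparagine synthetase ODE system, written
# directly from the printed rate equations (independent of the network
# compiler). Species order matches asn_network().
asn_derivatives_reference <- function(state, k) {
  s <- as.list(state)
  c(AMP  = k[["k4"]] * s$bAsp_AMP_ASNe_NH3,
    Asn  = k[["k4"]] * s$bAsp_AMP_ASNe_NH3,
    ASNe = k[["k4"]] * s$bAsp_AMP_ASNe_NH3 + k[["kD"]] * s$ASNe_NH3 -
           k[["k1"]] * s$Gln * s$ASNe,
    ASNe_Gln = k[["k1"]] * s$Gln * s$ASNe - k[["k2"]] * s$ASNe_Gln,
    ASNe_NH3 = k[["k2"]] * s$ASNe_Gln -
               k[["k3"]] * s$ASNe_NH3 * s$Asp * s$Mg * s$ATP -
               k[["kD"]] * s$ASNe_NH3,
    Asp  = -(k[["k3"]] * s$ASNe_NH3 * s$Asp * s$Mg * s$ATP),
    ATP  = 0,
    bAsp_AMP_ASNe_NH3 = k[["k3"]] * s$ASNe_NH3 * s$Asp * s$Mg * s$ATP -
                        k[["k4"]] * s$bAsp_AMP_ASNe_NH3,
    Gln  = -(k[["k1"]] * s$Gln * s$ASNe),
    Glu  = k[["k2"]] * s$ASNe_Gln,
    Mg   = 0)
}

random_asn_state <- function() {
  sp <- species_names(asn_network())
  stats::setNames(stats::runif(length(sp), 0, 10), sp)
}

random_rate_params <- function() {
  stats::setNames(10^stats::runif(5, -3, 3), c("k1", "k2", "k3", "k4", "kD"))
}

# Two-species toy net A -> B, handy for small structural checks.
toy_ab_network <- function() {
  reaction_network(list(place("A", 1), place("B", 0)),
                   list(reaction("r", c(A = 1), c(B = 1), "k")))
}
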