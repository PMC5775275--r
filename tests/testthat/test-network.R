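test_that("validation reports dangling references, duplicates and bad initials", {
  expect_length(validate_network(asn_network()), 0)

  bad_ref <- reaction_network(
    list(place("A", 1)),
    list(reaction("r", c(A = 1), c(X = 1), "k")),
    validate = FALSE)
  v <- validate_network(bad_ref)
  expect_length(v, 1)
  expect_match(v, "X")

  neg <- reaction_network(
    list(place("A", -1), place("B", 0)),
    list(reaction("r", c(A = 1), c(B = 1), "k")),
    validate = FALSE)
  expect_length(validate_network(neg), 1)

  dup <- reaction_network(
    list(place("A", 1), place("A", 2)),
    list(reaction("r", c(A = 1), character(), "k")),
    validate = FALSE)
  expect_match(validate_network(dup), "duplicate")
  expect_error(reaction_network(dup$places, dup$reactions), "duplicate")
})

test_that("stoichiometry matrix covers dynamic species in declared order", {
  net <- asn_network()
  S <- stoichiometry_matrix(net)
  expect_equal(dim(S), c(9, 5))
  expect_false(any(c("ATP", "Mg") %in% rownames(S)))
  expect_equal(colnames(S), c("r1", "r2", "r3", "r4", "D"))
  # asparagine is produced only by the release step r4
  expect_equal(unname(S["Asn", ]), c(0, 0, 0, 1, 0))

  expect_equal(unname(stoichiometry_matrix(toy_ab_network())),
               matrix(c(-1, 1), ncol = 1))
})

test_that("mass-action fluxes multiply rate constant and substrate concentrations", {
  net <- asn_network()
  st <- asn_initial_state("TaASN1")
  k <- asn_rate_params("TaASN1")
  v <- mass_action_fluxes(net, k, st)
  expect_equal(unname(v["r1"]), 0.016 * 10 * 0.1)       # = 0.016
  st2 <- st
  st2["ASNe_NH3"] <- 0.001
  v2 <- mass_action_fluxes(net, k, st2)
  expect_equal(unname(v2["r3"]), 0.043 * 0.001 * 1.6 * 10 * 10)  # = 0.00688
  # any reaction with a substrate at zero carries zero flux
  expect_equal(unname(v[c("r2", "r3", "r4", "D")]), rep(0, 4))
  expect_error(mass_action_fluxes(net, k[-1], st), "missing rate constant")
})

test_that("fluxes are non-negative at non-negative states", {
  net <- asn_network()
  for (i in 1:50) {
    v <- mass_action_fluxes(net, random_rate_params(), random_asn_state())
    expect_true(all(v >= 0))
  }
})

test_that("compiled derivatives match the hand-coded reference system", {
  net <- asn_network()
  for (i in 1:200) {
    k <- random_rate_params()
    st <- random_asn_state()
    d <- compile_odes(net, k)(0, st)
    ref <- asn_derivatives_reference(st, k)
    expect_equal(d, ref, tolerance = 1e-13)
  }
})

test_that("compiled system clamps ATP and Mg and couples Asn to AMP", {
  f <- compile_odes(asn_network(), asn_rate_params("TaASN1"))
  for (i in 1:20) {
    d <- f(0, random_asn_state())
    expect_identical(unname(d[c("ATP", "Mg")]), c(0, 0))
    expect_identical(d[["Asn"]], d[["AMP"]])
  }
  st <- asn_initial_state("TaASN1")
  d <- f(0, st)
  expect_equal(d[["Gln"]], -0.016)
  expect_error(f(0, st[-1]), "length")
})

test_that("conserved moieties span the expected laws and annihilate the dynamics", {
  net <- asn_network()
  B <- conserved_moieties(net)
  S <- stoichiometry_matrix(net)
  expect_equal(nrow(B), 4)
  expect_true(max(abs(B %*% S)) < 1e-9)
  expect_equal(B, round(B))           # integer basis

  in_span <- function(v) {
    # v lies in the row space of B iff appending it leaves the rank at 4
    qr(rbind(B, v))$rank == nrow(B)
  }
  law <- function(...) {
    v <- stats::setNames(numeric(ncol(B)), colnames(B))
    w <- c(...)
    v[names(w)] <- w
    v
  }
  expect_true(in_span(law(Asp = 1, bAsp_AMP_ASNe_NH3 = 1, Asn = 1)))
  expect_true(in_span(law(ASNe = 1, ASNe_Gln = 1, ASNe_NH3 = 1,
                          bAsp_AMP_ASNe_NH3 = 1)))
  expect_true(in_span(law(Gln = 1, ASNe_Gln = 1, Glu = 1)))
  expect_true(in_span(law(AMP = 1, Asn = -1)))

  # v' S flux = 0 for any state and parameters
  for (i in 1:20) {
    v <- mass_action_fluxes(net, random_rate_params(), random_asn_state())
    expect_lt(max(abs(B %*% (S %*% v[colnames(S)]))), 1e-8)
  }
})

test_that("a full-rank network has no conservation laws", {
  net <- reaction_network(
    list(place("A", 1), place("B", 0)),
    list(reaction("in_A", c(A = 1), c(A = 2), "ka"),   # net +1 A
         reaction("a_to_b", c(A = 1), c(B = 1), "kb")))
  expect_equal(nrow(conserved_moieties(net)), 0)
})

test_that("network JSON round-trips and validates on read", {
  net <- asn_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  net2 <- read_network_json(path)
  expect_identical(stoichiometry_matrix(net2), stoichiometry_matrix(net))
  expect_identical(network_initials(net2), network_initials(net))
  # compiled dynamics agree at random states
  k <- asn_rate_params("TaASN2")
  f1 <- compile_odes(net, k)
  f2 <- compile_odes(net2, k)
  for (i in 1:20) {
    st <- random_asn_state()
    expect_identical(f1(0, st), f2(0, st))
  }

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"places": []}', bad)
  expect_error(read_network_json(bad), "reactions")
})

test_that("packaged canonical network fixture matches the built-in model", {
  path <- system.file("extdata", "asn_network.json", package = "asnkin")
  expect_true(nzchar(path))
  net <- read_network_json(path)
  expect_identical(stoichiometry_matrix(net),
                   stoichiometry_matrix(asn_network()))
})

test_that("SBML export is well-formed and flags boundary species", {
  skip_if_not_installed("xml2")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(asn_network(), asn_rate_params("TaASN1"), path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  expect_length(sp, 11)
  bc <- xml2::xml_attr(sp, "boundaryCondition")
  expect_equal(sum(bc == "true"), 2)
  expect_length(xml2::xml_find_all(doc, ".//s:reaction", ns), 5)
  expect_length(xml2::xml_find_all(doc, ".//s:kineticLaw", ns), 5)
})
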