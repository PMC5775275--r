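#' Define a place (species) of a continuous Petri net
#'
#' A place holds a continuous concentration. Clamped places take part in
#' reaction fluxes but their time derivative is forced to zero (boundary
#' species such as a buffered ATP pool).
#'
#' @param name Species identifier (single string).
#' @param initial Initial concentration, in model concentration units
#'   (c.u.); must be non-negative.
#' @param clamped Logical; if `TRUE` the concentration is held constant.
#' @return An object of class `asn_place`.
#' @export
#' @examples
#' place("Asp", initial = 1.6)
place <- function(name, initial = 0, clamped = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(initial), length(initial) == 1L,
            is.logical(clamped), length(clamped) == 1L)
  structure(list(name = name, initial = as.numeric(initial),
                 clamped = isTRUE(clamped)),
            class = "asn_place")
}

#' Define a mass-action reaction (transition)
#'
#' Stoichiometries are positive integers; a species may appear on both
#' sides (e.g. a catalytic metal ion), in which case it enters the flux
#' product but has zero net stoichiometry.
#'
#' @param name Reaction identifier.
#' @param substrates Named integer vector (or named list) of substrate
#'   stoichiometries, each >= 1. At least one substrate is required.
#' @param products Named integer vector of product stoichiometries
#'   (may be empty for a pure sink).
#' @param rate_constant Name of the rate parameter governing the flux.
#' @return An object of class `asn_reaction`.
#' @export
#' @examples
#' reaction("r1", c(ASNe = 1, Gln = 1), c(ASNe_Gln = 1), "k1")
reaction <- function(name, substrates, products = numeric(), rate_constant) {
  substrates <- unlist(substrates)
  products <- unlist(products)
  if (length(substrates) == 0L)
    stop("reaction '", name, "' must have at least one substrate", call. = FALSE)
  if (is.null(names(substrates)) || any(!nzchar(names(substrates))))
    stop("substrates must be a named vector", call. = FALSE)
  if (length(products) > 0L &&
      (is.null(names(products)) || any(!nzchar(names(products)))))
    stop("products must be a named vector", call. = FALSE)
  substrates <- stats::setNames(as.numeric(substrates), names(substrates))
  products <- stats::setNames(as.numeric(products),
                              names(products) %||% character())
  structure(list(name = name,
                 substrates = substrates,
                 products = products,
                 rate_constant = rate_constant),
            class = "asn_reaction")
}

#' Assemble a continuous Petri net
#'
#' @param places List of [place()] objects (order is preserved and defines
#'   the state-vector order).
#' @param reactions List of [reaction()] objects (order defines flux-vector
#'   and stoichiometry-matrix column order).
#' @param validate If `TRUE` (default), signal an error when
#'   [validate_network()] reports violations.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(places, reactions, validate = TRUE) {
  stopifnot(is.list(places), is.list(reactions))
  net <- structure(list(places = places, reactions = reactions),
                   class = "reaction_network")
  if (validate) {
    bad <- validate_network(net)
    if (length(bad))
      stop("invalid network:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
  }
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cl <- species_names(x)[vapply(x$places, `[[`, TRUE, "clamped")]
  cat("Continuous Petri net: ", length(x$places), " places, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  species: ", paste(species_names(x), collapse = ", "), "\n", sep = "")
  if (length(cl))
    cat("  clamped: ", paste(cl, collapse = ", "), "\n", sep = "")
  for (r in x$reactions) {
    lhs <- paste(ifelse(r$substrates > 1, paste0(r$substrates, " "), ""),
                 names(r$substrates), sep = "", collapse = " + ")
    rhs <- if (length(r$products))
      paste(ifelse(r$products > 1, paste0(r$products, " "), ""),
            names(r$products), sep = "", collapse = " + ") else "(sink)"
    cat(sprintf("  %s: %s -> %s  [%s]\n", r$name, lhs, rhs, r$rate_constant))
  }
  invisible(x)
}

#' Species names of a network
#' @param net A `reaction_network`.
#' @return Character vector of place names, in place order.
#' @export
species_names <- function(net) {
  vapply(net$places, `[[`, character(1), "name")
}

#' Names of dynamic (non-clamped) species
#' @inheritParams species_names
#' @return Character vector.
#' @export
dynamic_species <- function(net) {
  species_names(net)[!vapply(net$places, `[[`, logical(1), "clamped")]
}

#' Default initial state of a network
#' @inheritParams species_names
#' @return Named numeric vector of place initials, in place order.
#' @export
network_initials <- function(net) {
  stats::setNames(vapply(net$places, `[[`, numeric(1), "initial"),
                  species_names(net))
}

#' Validate a reaction network
#'
#' Checks structural well-formedness: unique place and reaction names,
#' non-negative initial concentrations, positive integer stoichiometries,
#' and that every species referenced by a reaction is a declared place.
#'
#' @param net A `reaction_network` (possibly built with `validate = FALSE`).
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_network <- function(net) {
  out <- character()
  nm <- species_names(net)
  if (anyDuplicated(nm))
    out <- c(out, paste0("duplicate place name(s): ",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  for (p in net$places)
    if (!is.finite(p$initial) || p$initial < 0)
      out <- c(out, paste0("place '", p$name, "' has negative or non-finite initial ",
                           p$initial))
  rn <- vapply(net$reactions, `[[`, character(1), "name")
  if (anyDuplicated(rn))
    out <- c(out, paste0("duplicate reaction name(s): ",
                         paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  for (r in net$reactions) {
    refs <- c(names(r$substrates), names(r$products))
    miss <- setdiff(refs, nm)
    if (length(miss))
      out <- c(out, paste0("reaction '", r$name,
                           "' references undeclared species: ",
                           paste(miss, collapse = ", ")))
    st <- c(r$substrates, r$products)
    if (length(st) && (any(st < 1) || any(st != round(st))))
      out <- c(out, paste0("reaction '", r$name,
                           "' has non-positive-integer stoichiometry"))
    if (length(r$substrates) == 0L)
      out <- c(out, paste0("reaction '", r$name, "' has no substrates"))
  }
  out
}

stop_if_invalid <- function(net) {
  bad <- validate_network(net)
  if (length(bad))
    stop("invalid network:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(net)
}

# Net stoichiometry over ALL places (clamped rows not yet zeroed).
full_stoichiometry <- function(net) {
  nm <- species_names(net)
  S <- matrix(0L, nrow = length(nm), ncol = length(net$reactions),
              dimnames = list(nm, vapply(net$reactions, `[[`, character(1), "name")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (s in names(r$substrates))
      S[s, j] <- S[s, j] - as.integer(r$substrates[[s]])
    for (s in names(r$products))
      S[s, j] <- S[s, j] + as.integer(r$products[[s]])
  }
  S
}

#' Stoichiometry matrix of the dynamic species
#'
#' Rows are the non-clamped places (in place order), columns the reactions
#' (in reaction order); entries are net stoichiometries
#' (products minus substrates). Clamped species are excluded because their
#' derivative is identically zero.
#'
#' @param net A valid `reaction_network`.
#' @return Integer matrix with dimnames.
#' @export
stoichiometry_matrix <- function(net) {
  stop_if_invalid(net)
  full_stoichiometry(net)[dynamic_species(net), , drop = FALSE]
}

#' Mass-action reaction fluxes at a state
#'
#' Each flux is the rate constant times the product of substrate
#' concentrations raised to their stoichiometric multiplicities.
#'
#' @param net A valid `reaction_network`.
#' @param params Named numeric vector/list of rate constants; every
#'   `rate_constant` referenced by the network must be present.
#' @param state Named numeric vector of concentrations covering all species
#'   appearing as substrates.
#' @return Named numeric vector of fluxes (c.u./s), one per reaction.
#' @export
#' @examples
#' net <- asn_network()
#' mass_action_fluxes(net, asn_rate_params("TaASN1"), asn_initial_state("TaASN1"))
mass_action_fluxes <- function(net, params, state) {
  params <- unlist(params)
  v <- numeric(length(net$reactions))
  names(v) <- vapply(net$reactions, `[[`, character(1), "name")
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (!r$rate_constant %in% names(params))
      stop("missing rate constant '", r$rate_constant, "' for reaction '",
           r$name, "'", call. = FALSE)
    conc <- state[names(r$substrates)]
    if (anyNA(conc))
      stop("state is missing species: ",
           paste(names(r$substrates)[is.na(conc)], collapse = ", "),
           call. = FALSE)
    v[j] <- params[[r$rate_constant]] * prod(conc ^ r$substrates)
  }
  v
}

#' Compile a network to a mass-action ODE right-hand side
#'
#' Produces the derivative function induced by the net: derivatives equal
#' the (full) stoichiometry matrix times the mass-action flux vector, with
#' clamped species forced to zero. The returned closure is autonomous in
#' `t` and suitable both for direct evaluation and for wrapping into a
#' `deSolve` right-hand side.
#'
#' @param net A valid `reaction_network`.
#' @param params Named numeric vector/list of rate constants.
#' @return `function(t, state)` returning the named derivative vector over
#'   all species (place order). `state` must be a full named state vector.
#' @export
compile_odes <- function(net, params) {
  stop_if_invalid(net)
  params <- unlist(params)
  nm <- species_names(net)
  S <- full_stoichiometry(net)
  S[vapply(net$places, `[[`, logical(1), "clamped"), ] <- 0L
  storage.mode(S) <- "double"
  # precompute per-reaction substrate indices, stoichiometries and constants
  sub_idx <- lapply(net$reactions, function(r) match(names(r$substrates), nm))
  sub_sto <- lapply(net$reactions, function(r) as.numeric(r$substrates))
  kvals <- vapply(net$reactions, function(r) {
    if (!r$rate_constant %in% names(params))
      stop("missing rate constant '", r$rate_constant, "'", call. = FALSE)
    as.numeric(params[[r$rate_constant]])
  }, numeric(1))
  nrx <- length(net$reactions)
  nsp <- length(nm)
  function(t, state) {
    if (length(state) != nsp)
      stop("state vector has length ", length(state), ", expected ", nsp,
           call. = FALSE)
    v <- numeric(nrx)
    for (j in seq_len(nrx))
      v[j] <- kvals[j] * prod(state[sub_idx[[j]]] ^ sub_sto[[j]])
    drop(S %*% v)
  }
}

# Reduced row echelon form with partial pivoting; tol guards rank decisions.
rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A) * 1.0
  m <- nrow(A); n <- ncol(A)
  piv <- integer(0)
  i <- 1L
  for (j in seq_len(n)) {
    if (i > m) break
    p <- which.max(abs(A[i:m, j])) + i - 1L
    if (abs(A[p, j]) < tol) next
    if (p != i) A[c(i, p), ] <- A[c(p, i), ]
    A[i, ] <- A[i, ] / A[i, j]
    for (r in seq_len(m)[-i]) A[r, ] <- A[r, ] - A[r, j] * A[i, ]
    piv <- c(piv, j)
    i <- i + 1L
  }
  list(A = A, pivots = piv)
}

#' Conserved moieties (conservation laws) of a network
#'
#' Returns a basis of the left null space of the dynamic stoichiometry
#' matrix: weight vectors `v` over the dynamic species such that
#' `v %*% S == 0`, hence `sum(v * concentrations)` is constant along every
#' trajectory. The basis is scaled to small integers where possible (the
#' usual moiety totals such as total enzyme).
#'
#' @param net A valid `reaction_network`.
#' @return Numeric matrix, one row per conservation law, columns named by
#'   the dynamic species; zero rows when the matrix has full row rank.
#' @export
#' @examples
#' conserved_moieties(asn_network())
conserved_moieties <- function(net) {
  S <- stoichiometry_matrix(net)
  n <- nrow(S)
  rr <- rref(t(S))              # echelon form of S^T acting on species-space
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  if (!length(free)) {
    out <- matrix(numeric(0), nrow = 0, ncol = n,
                  dimnames = list(NULL, rownames(S)))
    return(out)
  }
  B <- matrix(0, nrow = length(free), ncol = n,
              dimnames = list(NULL, rownames(S)))
  for (k in seq_along(free)) {
    v <- numeric(n)
    v[free[k]] <- 1
    # pivot variables solve R v = 0
    for (r in seq_along(piv)) v[piv[r]] <- -rr$A[r, free[k]]
    B[k, ] <- v
  }
  # scale each row to integers when entries are near-rational with small denom
  for (k in seq_len(nrow(B))) {
    v <- B[k, ]
    nz <- abs(v) > 1e-9
    for (mult in 1:24) {
      w <- v * mult
      if (all(abs(w[nz] - round(w[nz])) < 1e-8)) {
        w <- round(w)
        g <- Reduce(function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a },
                    abs(w[w != 0]))
        B[k, ] <- w / max(g, 1)
        break
      }
    }
  }
  B
}
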