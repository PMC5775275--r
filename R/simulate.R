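#' Integrate a reaction network over a time grid
#'
#' Compiles the network to its mass-action ODE system and integrates with
#' a stiff-capable solver (`deSolve::ode`, `lsoda` by default). The
#' dissociation constant of the ASN model is orders of magnitude faster
#' than the binding steps, so the system is stiff and an implicit method
#' is the default.
#'
#' Small negative concentrations within `100 * atol` of zero (inevitable
#' round-off in non-negative mass-action systems) are clipped to zero on
#' output; anything more negative signals an integration error.
#'
#' @param net A valid `reaction_network`.
#' @param params Named rate constants.
#' @param state0 Named numeric vector of initial concentrations; species
#'   not named default to their place initials. Must be non-negative.
#' @param t_end Final time in seconds (default 2100).
#' @param n_points Number of evenly spaced output times including 0 and
#'   `t_end` (default 2001, i.e. 2000 steps of 1.05 s).
#' @param times Optional explicit output-time vector overriding
#'   `t_end`/`n_points`; must start at 0 and be strictly increasing.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param method `deSolve` integration method.
#' @return Object of class `trajectory`: list with `time` (seconds),
#'   `conc` (time x species matrix), `species`, `params`, `state0`,
#'   `solver` diagnostics.
#' @export
#' @examples
#' traj <- simulate_network(asn_network(), asn_rate_params("TaASN1"),
#'                          asn_initial_state("TaASN1"), t_end = 300,
#'                          n_points = 301)
#' plateau_metrics(traj)$glu_asn_ratio
simulate_network <- function(net, params, state0 = network_initials(net),
                             t_end = 2100, n_points = 2001, times = NULL,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stop_if_invalid(net)
  y0 <- network_initials(net)
  state0 <- unlist(state0)
  unknown <- setdiff(names(state0), names(y0))
  if (length(unknown))
    stop("unknown species in state0: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  y0[names(state0)] <- state0
  if (any(y0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  if (is.null(times)) {
    stopifnot(t_end > 0, n_points >= 2)
    times <- seq(0, t_end, length.out = n_points)
  } else {
    if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
      stop("'times' must start at 0 and be strictly increasing", call. = FALSE)
  }
  f <- compile_odes(net, params)
  rhs <- function(t, y, p) list(f(t, y))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  diag_ok <- attr(sol, "istate")[1]
  if (!is.null(diag_ok) && diag_ok < 0)
    stop("ODE integration failed (istate = ", diag_ok, "); see deSolve diagnostics",
         call. = FALSE)
  if (nrow(sol) < length(times))
    stop("ODE integration stopped early at t = ", max(sol[, 1]), call. = FALSE)
  conc <- sol[, -1, drop = FALSE]
  low <- min(conc)
  if (low < -100 * atol)
    stop("integration produced concentration ", low,
         " below the negativity tolerance; tighten rtol/atol", call. = FALSE)
  conc[conc < 0] <- 0
  structure(list(time = as.numeric(sol[, 1]),
                 conc = conc,
                 species = colnames(conc),
                 params = unlist(params),
                 state0 = y0,
                 solver = list(method = method, rtol = rtol, atol = atol)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$time), " time points over [",
      min(x$time), ", ", max(x$time), "] s, ",
      length(x$species), " species\n", sep = "")
  fin <- x$conc[nrow(x$conc), ]
  cat("final concentrations:\n")
  print(round(fin, 6))
  invisible(x)
}

#' Trajectory summary metrics around the product plateau
#'
#' For every species: final value, maximum, and time to reach 95% of the
#' net change from initial to final value (0 for constant species). When
#' the trajectory contains `Asn` and `Glu`, additionally reports their
#' final-time ratio (`Inf` when asparagine stays at zero) and a flag that
#' is `TRUE` when, over the last quartile of the grid, the relative
#' increase of glutamate exceeds ten times that of asparagine — the
#' signature of glutamate synthesis continuing after asparagine synthesis
#' has stalled for lack of aspartate.
#'
#' @param traj A `trajectory` with at least 4 time points.
#' @return List with `per_species` (data frame: species, final, max,
#'   t95_s), `glu_asn_ratio`, `glu_rising_asn_flat`.
#' @export
plateau_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$time) < 4)
    stop("trajectory must have at least 4 points", call. = FALSE)
  conc <- traj$conc
  tt <- traj$time
  n <- nrow(conc)
  final <- conc[n, ]
  init <- conc[1, ]
  t95 <- vapply(seq_along(final), function(j) {
    tol <- 0.05 * abs(final[j] - init[j])
    tt[which(abs(conc[, j] - final[j]) <= tol)[1]]
  }, numeric(1))
  per <- data.frame(species = traj$species,
                    final = as.numeric(final),
                    max = as.numeric(apply(conc, 2, max)),
                    t95_s = t95,
                    row.names = NULL)
  ratio <- NA_real_
  flag <- NA
  if (all(c("Asn", "Glu") %in% traj$species)) {
    ratio <- if (final[["Asn"]] > 0) final[["Glu"]] / final[["Asn"]] else
      if (final[["Glu"]] > 0) Inf else NA_real_
    q <- tt >= max(tt) - (max(tt) - min(tt)) / 4
    rel_inc <- function(s) {
      z <- conc[q, s]
      (z[length(z)] - z[1]) / max(z[1], .Machine$double.eps)
    }
    flag <- rel_inc("Glu") > 10 * rel_inc("Asn")
  }
  list(per_species = per, glu_asn_ratio = ratio, glu_rising_asn_flat = flag)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_s`, then one column per species; header mandatory.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `path` (writer, invisibly) or a `trajectory` (reader; `params`
#'   and `state0` provenance are not stored in the CSV).
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$time, traj$conc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s")
    stop("trajectory CSV must start with a 'time_s' column", call. = FALSE)
  conc <- as.matrix(df[, -1, drop = FALSE])
  structure(list(time = df$time_s, conc = conc, species = colnames(conc),
                 params = NULL, state0 = NULL, solver = NULL),
            class = "trajectory")
}

#' Plot species time courses
#'
#' @param traj A `trajectory`.
#' @param species Species to draw (default `Asn` and `Glu`).
#' @param data Optional assay dataset (see [generate_assay_dataset()])
#'   overlaid as points.
#' @return A `ggplot` object.
#' @export
plot_trajectory <- function(traj, species = c("Asn", "Glu"), data = NULL) {
  species <- intersect(species, traj$species)
  df <- data.frame(time_s = rep(traj$time, length(species)),
                   species = rep(species, each = length(traj$time)),
                   concentration = as.numeric(traj$conc[, species]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = concentration,
                                        colour = species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (s)", y = "concentration (c.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    dd <- data[data$species %in% species, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = dd,
      ggplot2::aes(x = time_s, y = concentration, colour = species),
      inherit.aes = FALSE, size = 2, alpha = 0.8)
  }
  p
}

utils::globalVariables(c("time_s", "concentration"))
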