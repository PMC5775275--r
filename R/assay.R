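# Synthetic emulation of the HPLC activity assay: mechanism simulation
# sampled at the assay time points, pushed through a linear peak-area
# calibration (o-phthalaldehyde fluorescence) with multiplicative
# replicate noise, then inverted back to concentrations through a freshly
# fitted standard curve — the full measurement chain applied to real data.

.assay_times_s <- c(1.5, 2.5, 3.5, 5, 15, 25, 35) * 60
.standard_concs <- c(0, 5, 10, 15, 20)

#' Default assay sampling times
#'
#' The seven aliquot times of the activity assay (1.5, 2.5, 3.5, 5, 15,
#' 25 and 35 minutes), in seconds.
#'
#' @return Numeric vector of length 7 (seconds).
#' @export
assay_time_points <- function() .assay_times_s

#' Simulate an HPLC calibration-standards table
#'
#' Generates peak areas for the five-point standard series (0, 5, 10, 15,
#' 20 nmol) under a linear response with multiplicative Gaussian noise:
#' `area = intercept + slope * conc * (1 + N(0, noise_cv))`.
#'
#' @param true_slope Area per unit concentration (> 0).
#' @param true_intercept Baseline area.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives exact areas).
#' @param seed Integer seed; same seed, same areas.
#' @param concentrations Standard concentrations (default the five-point
#'   series).
#' @return Data frame with columns `concentration`, `area`.
#' @export
#' @examples
#' simulate_calibration(100, 0, noise_cv = 0, seed = 1)
simulate_calibration <- function(true_slope, true_intercept = 0,
                                 noise_cv = 0, seed = 1,
                                 concentrations = .standard_concs) {
  stopifnot(true_slope > 0, noise_cv >= 0)
  areas <- with_seed(seed, {
    eps <- stats::rnorm(length(concentrations), 0, noise_cv)
    true_intercept + true_slope * concentrations * (1 + eps)
  })
  data.frame(concentration = concentrations, area = areas)
}

#' Fit a linear calibration curve by ordinary least squares
#'
#' Regresses peak area on standard concentration (`stats::lm`), the
#' standard treatment of amino-acid standard series.
#'
#' @param standards Data frame with columns `concentration`, `area` and
#'   at least two distinct concentrations.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `residual_se`, `standards`.
#' @export
#' @examples
#' fit_calibration(simulate_calibration(100, 5, noise_cv = 0))
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "area") %in% names(standards)))
  if (length(unique(standards$concentration)) < 2)
    stop("degenerate calibration design: need >= 2 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(area ~ concentration, data = standards)
  co <- stats::coef(fit)
  # an exact (noiseless) standards series makes summary.lm warn about a
  # perfect fit; the zero residual SE is the correct answer here
  structure(list(slope = unname(co[["concentration"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 residual_se = suppressWarnings(summary(fit)$sigma),
                 standards = standards),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration: area = %.6g + %.6g * concentration (residual SE %.3g, %d standards)\n",
    x$intercept, x$slope, x$residual_se, nrow(x$standards)))
  invisible(x)
}

#' Invert a calibration curve: peak area to concentration
#'
#' `(area - intercept) / slope`; results below zero (areas under the
#' baseline) are clipped to 0 and flagged via the `below_range`
#' attribute.
#'
#' @param curve A `calibration_curve` with positive slope.
#' @param area Numeric vector of peak areas.
#' @return Numeric concentrations with logical attribute `below_range`.
#' @export
#' @examples
#' cal <- fit_calibration(simulate_calibration(100, 0))
#' area_to_concentration(cal, 1500)
area_to_concentration <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("unusable calibration curve: slope must be > 0", call. = FALSE)
  conc <- (area - curve$intercept) / curve$slope
  below <- conc < 0
  conc[below] <- 0
  attr(conc, "below_range") <- below
  conc
}

#' Generate a synthetic assay dataset
#'
#' Emulates the complete activity-assay measurement chain for one enzyme
#' isoform: (1) simulate the mechanism from the default assay initial
#' state; (2) sample asparagine and glutamate at the assay time points;
#' (3) map concentrations to peak areas through a configured true
#' calibration; (4) add multiplicative Gaussian noise per replicate
#' measurement; (5) run a fresh standards series (same noise level), fit
#' the working calibration by OLS, and invert the noisy areas back to
#' concentrations. With `noise_cv = 0` the chain is exactly the identity.
#'
#' @param enzyme `"TaASN1"` or `"TaASN2"`.
#' @param params Rate constants used as ground truth (default the
#'   isoform's reference set).
#' @param noise_cv Measurement coefficient of variation (default 0.05,
#'   typical of HPLC fluorescence peak areas).
#' @param n_replicates Replicate assays (default 2).
#' @param seed Integer seed controlling both replicate noise and the
#'   standards run.
#' @param time_points Sampling times in seconds (default the seven assay
#'   aliquot times, [assay_time_points()]).
#' @param calibration List with `slope` and `intercept` of the true
#'   instrument response (default slope 1000, intercept 25).
#' @param state0_overrides Optional species overrides for the initial
#'   state (see [asn_initial_state()]).
#' @return Data frame of class `assay_dataset` with columns `enzyme`,
#'   `replicate`, `time_s`, `species`, `area`, `concentration`, plus
#'   attribute `meta` (true params, noise_cv, seed, calibration, unit
#'   label).
#' @export
#' @examples
#' d <- generate_assay_dataset("TaASN1", noise_cv = 0, seed = 1)
#' head(d)
generate_assay_dataset <- function(enzyme = c("TaASN1", "TaASN2"),
                                   params = asn_rate_params(enzyme),
                                   noise_cv = 0.05, n_replicates = 2,
                                   seed = 1,
                                   time_points = assay_time_points(),
                                   calibration = list(slope = 1000,
                                                      intercept = 25),
                                   state0_overrides = NULL) {
  enzyme <- match.arg(enzyme)
  stopifnot(noise_cv >= 0, n_replicates >= 1)
  time_points <- sort(unique(time_points))
  state0 <- asn_initial_state(enzyme, overrides = state0_overrides)
  traj <- simulate_network(asn_network(), params, state0,
                           times = sort(unique(c(0, time_points))))
  keep <- match(time_points, traj$time)
  species <- c("Asn", "Glu")
  truth <- traj$conc[keep, species, drop = FALSE]

  n_t <- length(time_points)
  df <- expand.grid(species = species, time_s = time_points,
                    replicate = seq_len(n_replicates),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("replicate", "time_s", "species")]
  df$enzyme <- enzyme
  conc_true <- truth[cbind(match(df$time_s, time_points),
                           match(df$species, species))]
  area_true <- calibration$intercept + calibration$slope * conc_true
  noisy <- with_seed(seed, {
    eps <- stats::rnorm(nrow(df), 0, noise_cv)
    list(area = area_true * (1 + eps), std_seed = sample.int(2^31 - 1, 1))
  })
  standards <- simulate_calibration(calibration$slope,
                                    calibration$intercept,
                                    noise_cv = noise_cv,
                                    seed = noisy$std_seed)
  curve <- fit_calibration(standards)
  df$area <- noisy$area
  df$concentration <- as.numeric(area_to_concentration(curve, df$area))
  df <- df[, c("enzyme", "replicate", "time_s", "species", "area",
               "concentration")]
  attr(df, "meta") <- list(enzyme = enzyme, true_params = unlist(params),
                           noise_cv = noise_cv, seed = seed,
                           n_replicates = n_replicates,
                           calibration_true = calibration,
                           calibration_fitted = curve[c("slope", "intercept",
                                                        "residual_se")],
                           unit = "c.u.")
  class(df) <- c("assay_dataset", class(df))
  df
}

#' Write / read an assay dataset as CSV with a JSON metadata sidecar
#'
#' The CSV holds the measurement rows (`enzyme`, `replicate`, `time_s`,
#' `species`, `area`, `concentration`); the sidecar
#' (`<path>.meta.json`) records seed, noise level, true parameters and
#' calibration so that a synthetic dataset is fully reproducible.
#'
#' @param data An `assay_dataset`.
#' @param path CSV file path.
#' @return `path` (writer, invisibly) or an `assay_dataset` (reader).
#' @export
write_assay_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- attr(data, "meta")
  if (!is.null(meta)) {
    meta$calibration_fitted <- lapply(meta$calibration_fitted, unname)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "replicate", "time_s", "species", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assay CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$concentration))
  if (length(bad))
    stop("assay CSV row ", bad[1] + 1L,
         " has a non-numeric time_s or concentration", call. = FALSE)
  side <- paste0(path, ".meta.json")
  if (file.exists(side))
    attr(df, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  class(df) <- c("assay_dataset", class(df))
  df
}
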