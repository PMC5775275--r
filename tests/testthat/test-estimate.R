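# A tiny net whose observed species sits constant at 2 (clamped place):
# makes the SSE arithmetic checkable by hand.
constant_net <- function(level = 2) {
  reaction_network(
    list(place("Asn", level, clamped = TRUE), place("X", 1)),
    list(reaction("r", c(X = 1), c(X = 1), "k")))
}

test_that("sse objective accumulates squared residuals over replicates", {
  net <- constant_net(2)
  dat <- data.frame(enzyme = "toy", replicate = c(1, 2), time_s = 10,
                    species = "Asn", concentration = 0.5)
  sse <- sse_objective(net, c(k = 0), c(Asn = 2, X = 1), dat,
                       observed = "Asn")
  expect_equal(sse, 2 * 1.5^2)   # = 4.5
  # per-species weights scale the contribution
  sse_w <- sse_objective(net, c(k = 0), c(Asn = 2, X = 1), dat,
                         observed = "Asn", weights = c(Asn = 2))
  expect_equal(sse_w, 9)
  expect_error(sse_objective(net, c(k = 0), c(Asn = 2, X = 1),
                             dat[0, ], observed = "Asn"), "no observations")
})

test_that("self-generated noiseless data has near-zero SSE and is identifiable", {
  truth <- asn_rate_params("TaASN1")
  dat <- generate_assay_dataset("TaASN1", params = truth, noise_cv = 0,
                                n_replicates = 1, seed = 3)
  net <- asn_network()
  st <- asn_initial_state("TaASN1")
  sse0 <- sse_objective(net, truth, st, dat)
  expect_lt(sse0, 1e-10)
  bumped <- truth
  bumped["k1"] <- truth["k1"] * 2
  expect_gt(sse_objective(net, bumped, st, dat), sse0 + 1e-4)
})

test_that("pattern search solves scalar and anisotropic quadratics", {
  r <- hooke_jeeves(function(x) (x - 3)^2, 0, -10, 10)
  expect_lt(abs(r$par - 3), 1e-4)
  expect_true(r$converged)

  r2 <- hooke_jeeves(function(x) x[1]^2 + 10 * x[2]^2, c(5, 5), -10, 10,
                     step0 = 1, step_tol = 1e-6)
  expect_lt(max(abs(r2$par)), 1e-3)
  # far cheaper than a brute-force grid at the same resolution
  grid_evals <- length(seq(-10, 10, by = 1e-3))^2
  expect_lt(r2$n_eval, grid_evals / 1000)

  # a monotone objective pins the lower bound
  r3 <- hooke_jeeves(function(x) x, 1.5, 1, 2)
  expect_equal(unname(r3$par), 1)
})

test_that("pattern search reaches the minimum of random positive-definite quadratics", {
  withr::local_seed(42)
  for (i in 1:20) {
    d <- sample(1:4, 1)
    M <- matrix(rnorm(d * d), d)
    A <- crossprod(M) + diag(d) * 0.5
    xstar <- runif(d, -3, 3)
    fn <- function(x) drop(t(x - xstar) %*% A %*% (x - xstar))
    r <- hooke_jeeves(fn, start = rep(0, d), lower = -10, upper = 10,
                      step0 = 1, step_tol = 1e-7)
    expect_lt(max(abs(r$par - xstar)), 1e-3)
  }
})

test_that("pattern search trace and error handling follow the contract", {
  r <- hooke_jeeves(function(x) sum(x^2), c(2, 2), -5, 5)
  expect_true(all(diff(r$trace$value) <= 0))
  expect_equal(unname(as.numeric(r$trace[nrow(r$trace), c("x1", "x2")])),
               unname(r$par), tolerance = 1e-12)

  expect_error(hooke_jeeves(function(x) NaN, 0, -1, 1), "non-finite")
  # non-finite away from the start is treated as +Inf, not an error
  spiky <- function(x) if (abs(x - 0.3) < 0.05) NaN else (x - 1)^2
  rs <- hooke_jeeves(spiky, 0, -2, 2)
  expect_lt(abs(rs$par - 1), 1e-4)
})

test_that("fit configuration is validated", {
  expect_error(fit_config(character(), start = numeric()), "no free")
  expect_error(fit_config("k1", fixed = c(k1 = 1), start = c(k1 = 1)),
               "both free and fixed")
  expect_error(fit_config("k1", start = c(k1 = 1e7)), "within bounds")
  expect_error(fit_config("k1", start = c(k2 = 1)), "start values required")
})

test_that("noiseless self-fits recover the generating k1 and kD", {
  for (enz in c("TaASN1", "TaASN2")) {
    truth <- asn_rate_params(enz)
    dat <- generate_assay_dataset(enz, params = truth, noise_cv = 0,
                                  n_replicates = 1, seed = 11,
                                  time_points = seq(0, 2100,
                                                    length.out = 50))
    cfg <- fit_config(free = c("k1", "kD"),
                      fixed = truth[c("k2", "k3", "k4")],
                      start = truth[c("k1", "kD")] * 2)
    fit <- fit_timecourse(dat, asn_network(), asn_enzyme_profile(enz), cfg)
    expect_lt(abs(fit$estimates[["k1"]] - truth[["k1"]]) / truth[["k1"]],
              0.05)
    expect_lt(abs(fit$estimates[["kD"]] - truth[["kD"]]) / truth[["kD"]],
              0.05)
    # objective at the estimates beats the start point (from the trace)
    expect_lte(fit$objective, fit$trace$value[1])
  }
})

test_that("starting at the truth returns the start unchanged", {
  truth <- asn_rate_params("TaASN1")
  dat <- generate_assay_dataset("TaASN1", params = truth, noise_cv = 0,
                                n_replicates = 1, seed = 5)
  cfg <- fit_config(free = c("k1", "kD"),
                    fixed = truth[c("k2", "k3", "k4")],
                    start = truth[c("k1", "kD")])
  fit <- fit_timecourse(dat, asn_network(), asn_enzyme_profile("TaASN1"),
                        cfg)
  expect_equal(fit$estimates, truth[c("k1", "kD")], tolerance = 1e-12)
})

test_that("the simplex fallback fits behind the same interface", {
  truth <- asn_rate_params("TaASN1")
  dat <- generate_assay_dataset("TaASN1", params = truth, noise_cv = 0,
                                n_replicates = 1, seed = 7,
                                time_points = seq(0, 2100, length.out = 30))
  cfg <- fit_config(free = "k1", fixed = truth[-1],
                    start = c(k1 = truth[["k1"]] * 2),
                    method = "nelder_mead", max_eval = 500)
  fit <- fit_timecourse(dat, asn_network(), asn_enzyme_profile("TaASN1"),
                        cfg)
  expect_lt(abs(fit$estimates[["k1"]] - truth[["k1"]]) / truth[["k1"]], 0.05)
})

test_that("fitting requires enough informative data", {
  dat <- generate_assay_dataset("TaASN1", noise_cv = 0, n_replicates = 1,
                                seed = 1, time_points = 90)
  dat <- dat[dat$species == "Asn", ]
  cfg <- fit_config(free = c("k1", "k2", "kD"),
                    fixed = asn_rate_params("TaASN1")[c("k3", "k4")],
                    start = c(k1 = 0.1, k2 = 1, kD = 100))
  expect_error(fit_timecourse(dat, asn_network(),
                              asn_enzyme_profile("TaASN1"), cfg,
                              observed = "Asn"),
               "fewer informative data points")
})

test_that("recovery experiments are reproducible and degrade gracefully with noise", {
  a <- recovery_experiment("TaASN1", noise_cv = 0, n_replicates = 1,
                           time_points = seq(0, 2100, length.out = 40),
                           seed = 9)
  b <- recovery_experiment("TaASN1", noise_cv = 0, n_replicates = 1,
                           time_points = seq(0, 2100, length.out = 40),
                           seed = 9)
  expect_identical(a$report, b$report)
  expect_true(all(a$report$rel_error < 0.05))

  noisy <- recovery_experiment("TaASN1", noise_cv = 0.05, n_replicates = 2,
                               time_points = seq(0, 2100, length.out = 40),
                               seed = 9)
  expect_gt(noisy$report$rel_error[noisy$report$parameter == "k1"],
            a$report$rel_error[a$report$parameter == "k1"])
  expect_lt(noisy$report$rel_error[noisy$report$parameter == "k1"], 0.25)
})

test_that("fit results serialize to JSON and a rate-table CSV", {
  truth <- asn_rate_params("TaASN2")
  dat <- generate_assay_dataset("TaASN2", params = truth, noise_cv = 0,
                                n_replicates = 1, seed = 2,
                                time_points = seq(0, 2100, length.out = 30))
  cfg <- fit_config(free = c("k1", "kD"), fixed = truth[c("k2", "k3", "k4")],
                    start = truth[c("k1", "kD")] * 2)
  fit <- fit_timecourse(dat, asn_network(), asn_enzyme_profile("TaASN2"),
                        cfg)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_fit_results(list(TaASN2 = fit), json_path = jp, csv_path = cp,
                    fixed = list(TaASN2 = truth[c("k2", "k3", "k4")]))
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$TaASN2$estimates$kD, fit$estimates[["kD"]])
  tab <- utils::read.csv(cp)
  expect_equal(tab$rate_parameter, c("k1", "k2", "k3", "k4", "kD"))
  expect_equal(tab$TaASN2[2:4], c(3, 0.043, 10))
})
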