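# helper: a uniform distribution table on [0,1]^d for surrogate tests
unit_uq <- function(d) {
  data.frame(name = paste0("x", seq_len(d)), family = "uniform",
             mean = 0.5, sd = NA_real_, lower = 0, upper = 1,
             stringsAsFactors = FALSE)
}

test_that("the UQ parameter set has nine members with stated families", {
  uq <- uq_parameter_set()
  expect_equal(nrow(uq), 9)
  expect_equal(uq$family[uq$name == "pct_s"], "uniform")
  expect_equal(sum(uq$family == "uniform"), 1)
  tn <- uq[uq$family == "tnorm", ]
  expect_equal(tn$lower, tn$mean - 1.96 * tn$sd)
  expect_equal(tn$upper, tn$mean + 1.96 * tn$sd)
})

test_that("input sampling is truncated, unbiased and reproducible", {
  uq <- uq_parameter_set()
  X <- sample_inputs(uq, 4000, seed = 5)
  expect_true(all(t(X) >= uq$lower & t(X) <= uq$upper))
  expect_identical(X, sample_inputs(uq, 4000, seed = 5))
  expect_false(identical(X[1, ], sample_inputs(uq, 4000, seed = 6)[1, ]))

  # symmetric +/- 1.96 sd truncation: analytic mean stays at mu and the
  # analytic sd shrinks by a known factor
  j <- which(uq$name == "T")
  mu <- uq$mean[j]; sd <- uq$sd[j]; a <- 1.96
  shrink <- sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
  se <- sd * shrink / sqrt(nrow(X))
  expect_lt(abs(mean(X[, j]) - mu), 3 * se)
  expect_equal(stats::sd(X[, j]), sd * shrink, tolerance = 0.05)

  bad <- uq; bad$sd[2] <- 0
  expect_error(sample_inputs(bad, 10), "degenerate")
})

test_that("regression sample counts follow the collocation rule", {
  expect_identical(required_sample_count(9, 2, 2), 110L)
  expect_identical(required_sample_count(9, 1, 2), 20L)
  expect_identical(required_sample_count(1, 0, 1), 1L)
  expect_error(required_sample_count(0, 1), "required")
})

test_that("PCE fitting recovers a generating polynomial", {
  set.seed(1)
  d <- 3
  X <- matrix(stats::runif(3 * 80), 80, d,
              dimnames = list(NULL, paste0("x", 1:d)))
  truth <- function(X) {
    1.5 + 2 * X[, 1] - X[, 2] + 0.5 * X[, 1]^2 + X[, 1] * X[, 3]
  }
  m <- fit_pce(X, truth(X), order = 2, bounds = cbind(rep(0, d), rep(1, d)))
  Xnew <- matrix(stats::runif(3 * 40), 40, d)
  expect_equal(as.numeric(pce_predict(m, Xnew)), truth(Xnew),
               tolerance = 1e-8)
  expect_lt(max(m$rmse), 1e-10)

  # constant response loads only the constant term
  mc <- fit_pce(X, rep(4.2, 80), order = 2,
                bounds = cbind(rep(0, d), rep(1, d)))
  expect_equal(mc$coef[1], 4.2, tolerance = 1e-10)
  expect_lt(max(abs(mc$coef[-1])), 1e-10)

  # duplicated sample rows leave the least-squares fit unchanged
  m2 <- fit_pce(rbind(X, X), c(truth(X), truth(X)), order = 2,
                bounds = cbind(rep(0, d), rep(1, d)))
  expect_equal(m2$coef, m$coef, tolerance = 1e-9)

  # degenerate inputs are reported as rank deficiency
  Xbad <- X; Xbad[, 2] <- 0.5
  expect_error(fit_pce(Xbad, truth(X), order = 2,
                       bounds = cbind(rep(0, d), rep(1, d))), "rank")
  expect_error(fit_pce(X[1:5, ], truth(X)[1:5], order = 2), "samples")
})

test_that("basis size arithmetic matches the total-degree count", {
  expect_equal(nrow(graftflow:::multi_indices(9, 2)), choose(11, 2))
  expect_equal(2 * choose(11, 2), 110)
})

test_that("cross-validated order selection finds the planted degree", {
  set.seed(7)
  X <- matrix(stats::runif(2 * 120), 120, 2)
  bounds <- cbind(c(0, 0), c(1, 1))

  y_lin <- 2 * X[, 1] - X[, 2] + stats::rnorm(120, 0, 0.01)
  expect_equal(select_order_by_cv(X, y_lin, max_order = 2, seed = 1,
                                  bounds = bounds)$order, 1)

  y_quad <- 4 * (X[, 1] - 0.5)^2 + X[, 2] + stats::rnorm(120, 0, 0.01)
  expect_equal(select_order_by_cv(X, y_quad, max_order = 2, seed = 1,
                                  bounds = bounds)$order, 2)

  # exact ties break towards the lower order
  expect_equal(select_order_by_cv(X, rep(1, 120), max_order = 2,
                                  seed = 1, bounds = bounds)$order, 1)
  expect_error(select_order_by_cv(X[1:5, ], y_lin[1:5], k = 10), "k must")
})

test_that("Sobol indices from the expansion match analytic shares", {
  set.seed(2)
  d <- 3
  uq <- unit_uq(d)
  X <- sample_inputs(uq, 400, seed = 2)
  bounds <- cbind(uq$lower, uq$upper)

  # single active variable
  m1 <- fit_pce(X, X[, 1], order = 2, bounds = bounds)
  s1 <- sobol_from_pce(m1)
  expect_equal(s1$main, c(1, 0, 0), tolerance = 1e-8)
  expect_equal(s1$total, c(1, 0, 0), tolerance = 1e-8)

  # additive linear: shares a^2 : b^2
  a <- 2; b <- 3
  m2 <- fit_pce(X, a * X[, 1] + b * X[, 2], order = 1, bounds = bounds)
  s2 <- sobol_from_pce(m2)
  expect_equal(s2$main[1], a^2 / (a^2 + b^2), tolerance = 1e-8)
  expect_equal(s2$main[2], b^2 / (a^2 + b^2), tolerance = 1e-8)
  # order-1 expansions have main = total exactly
  expect_identical(s2$main, s2$total)

  # additive orthonormal polynomials with hand-computed variance shares:
  # f = 2*phi1(z1) + 3*phi2(z2), Var = 4 + 9
  z <- 2 * X - 1
  phi1 <- sqrt(3) * z[, 1]
  phi2 <- sqrt(5) * (3 * z[, 2]^2 - 1) / 2
  m3 <- fit_pce(X, 2 * phi1 + 3 * phi2, order = 2, bounds = bounds)
  s3 <- sobol_from_pce(m3)
  expect_equal(s3$main, c(4, 9, 0) / 13, tolerance = 1e-8)

  expect_error(sobol_from_pce(fit_pce(X, rep(1, 400), order = 1,
                                      bounds = bounds)), "variance")
})

test_that("pick-freeze Monte-Carlo cross-checks the spectral indices", {
  d <- 3
  uq <- unit_uq(d)
  X <- sample_inputs(uq, 500, seed = 3)
  y <- 2 * X[, 1] + X[, 2] + 0.5 * X[, 1] * X[, 3]
  m <- fit_pce(X, y, order = 2, bounds = cbind(uq$lower, uq$upper))
  spectral <- sobol_from_pce(m)$main
  mc <- pick_freeze_sobol(m, uq, n = 20000, seed = 4)
  expect_equal(unname(mc), spectral, tolerance = 0.03)
})

test_that("diastolic-pressure-peak filtering fires on planted waveforms", {
  sims <- list(default_sim(), stenosed_sim())
  # plant an unphysical run: copy a sim and move its pressure peak into
  # diastole of the last beat
  bad <- default_sim()
  seg <- segment_beats(bad)
  b <- seg[nrow(seg), ]
  i_dia <- bad$time > b$t_sys_end + 0.1 & bad$time < b$t_end - 0.1
  bad$signals$p_ao[i_dia] <- max(bad$signals$p_ao) + 10
  expect_false(peak_in_diastole(default_sim()))
  expect_true(peak_in_diastole(bad))

  batch <- c(sims, list(bad))
  out <- filter_unphysical(batch, ids = c("a", "b", "c"))
  expect_equal(out$removed$id, "c")
  expect_equal(out$fraction_removed, 1 / 3)
  # idempotence
  again <- filter_unphysical(out$kept, ids = out$kept_ids)
  expect_equal(length(again$kept), 2)
  expect_equal(again$fraction_removed, 0)
})

test_that("the UQ stage wires sampling, filtering, CV and Sobol", {
  uq <- uq_parameter_set()
  lin_runner <- function(x) {
    list(metrics = c(Q_mean = unname(5 * x["pct_s"] + 0.1 * x["T"]),
                     PI = unname(x["R0_svb"]),
                     DS_ratio = unname(2 * x["pct_s"]),
                     DRI = unname(x["pct_s"] + 0.01 * x["C1"])),
         unphysical = FALSE)
  }
  rep <- run_uq_stage(n = 60, seed = 2, runner = lin_runner)
  for (m in c("Q_mean", "DS_ratio", "DRI")) {
    s <- rep$sobol[rep$sobol$metric == m, ]
    expect_equal(s$name[which.max(s$main)], "pct_s")
  }
  expect_equal(rep$n_kept, 60)

  # determinism end to end
  rep2 <- run_uq_stage(n = 60, seed = 2, runner = lin_runner)
  expect_equal(rep$sobol, rep2$sobol, tolerance = 1e-12)

  # aborts when more than half the runs are unusable
  flaky <- local({
    k <- 0
    function(x) {
      k <<- k + 1
      if (k %% 3 != 0) stop("boom")
      lin_runner(x)
    }
  })
  expect_error(run_uq_stage(n = 20, seed = 2, runner = flaky), "aborting")
})
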