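test_that("screening distributions mirror the registry", {
  d <- morris_distributions()
  expect_equal(nrow(d), 39)
  expect_equal(sum(d$family == "uniform"), 2)
  expect_setequal(d$name[d$family == "uniform"],
                  c("pct_s", "endo_epi_vratio"))
  expect_equal(d[d$name == "pct_s", c("lower", "upper")],
               data.frame(lower = 0, upper = 75,
                          row.names = which(d$name == "pct_s")))
  # truncated normals span mean +/- 2 sd
  tn <- d[d$family == "tnorm", ]
  expect_equal(tn$lower, tn$mean - 2 * tn$sd)
  expect_equal(tn$upper, tn$mean + 2 * tn$sd)

  # all-uniform robustness mode keeps the ranges
  du <- morris_distributions(all_uniform = TRUE)
  expect_true(all(du$family == "uniform"))
  expect_equal(du$lower, d$lower)
  expect_equal(du$upper, d$upper)
})

test_that("inverse-CDF mapping respects bounds and renormalisation", {
  d <- morris_distributions()
  u <- matrix(stats::runif(500 * 39), 500, 39)
  X <- map_to_physical(u, d)
  expect_true(all(t(X) >= d$lower - 1e-12 & t(X) <= d$upper + 1e-12))
  # median of the truncated normal maps from u = 0.5 to the mean
  mid <- map_to_physical(matrix(0.5, 1, 39), d)
  tn <- d$family == "tnorm"
  expect_equal(unname(mid[1, tn]), d$mean[tn], tolerance = 1e-9)
})

test_that("trajectory designs have the one-at-a-time structure", {
  d5 <- morris_distributions()[1:5, ]
  des <- morris_trajectories(d5, r = 8, p = 4, seed = 2, oversample = 30)
  expect_equal(nrow(des$points), 8 * 6)
  expect_equal(des$delta, 4 / (2 * 3))
  # audit: each consecutive pair differs in exactly one coordinate by
  # +/- delta, and all coordinates live on the p-level grid
  for (i in seq_len(nrow(des$pairs))) {
    dv <- des$points[des$pairs$i_to[i], ] - des$points[des$pairs$i_from[i], ]
    nz <- which(abs(dv) > 1e-12)
    expect_length(nz, 1)
    expect_equal(nz, des$pairs$coord[i])
    expect_equal(unname(dv[nz]), des$pairs$sign[i] * des$delta)
  }
  grid_pos <- des$points * 3
  expect_true(all(abs(grid_pos - round(grid_pos)) < 1e-9))

  # single tiny trajectory
  des1 <- morris_trajectories(d5[1:2, ], r = 1, p = 4, seed = 1,
                              oversample = 1)
  expect_equal(nrow(des1$points), 3)

  # determinism
  desA <- morris_trajectories(d5, r = 4, seed = 9, oversample = 12)
  desB <- morris_trajectories(d5, r = 4, seed = 9, oversample = 12)
  expect_identical(desA$points, desB$points)

  expect_error(morris_trajectories(d5, r = 10, oversample = 5), "oversample")
  expect_error(morris_trajectories(d5, r = 2, p = 3), "even")
})

test_that("elementary effects recover linear coefficients exactly", {
  d <- morris_distributions()[1:6, ]
  des <- morris_trajectories(d, r = 10, p = 4, seed = 4, oversample = 20)
  a <- c(3, -1, 0.5, 0, 2, -4)
  f <- des$points %*% a
  res <- elementary_effects(des, as.numeric(f))
  expect_equal(res$mu_star, abs(a), tolerance = 1e-10)
  expect_lt(max(res$sigma), 1e-10)
  expect_equal(res$name[res$rank == 1], d$name[6])
  expect_equal(attr(res, "n_dropped"), 0)

  # interactions create elementary-effect spread
  f2 <- des$points[, 1] * des$points[, 2]
  res2 <- elementary_effects(des, f2)
  expect_gt(res2$sigma[1], 0)

  # a flat response is flagged as uninfluential everywhere
  res3 <- elementary_effects(des, rep(2, nrow(des$points)))
  expect_true(all(res3$mu_star == 0 & res3$sigma == 0))
})

test_that("combined score is the Euclidean norm of (mu*, sigma)", {
  # one parameter, two trajectories: engineer EEs of 0.1716 and 5.8284
  # so that mu* = 3 and sigma = 4, hence score 5
  d1 <- morris_distributions()[1, , drop = FALSE]
  des <- morris_trajectories(d1, r = 2, p = 4, seed = 1, oversample = 2)
  ee_target <- c(3 - 4 / sqrt(2), 3 + 4 / sqrt(2))
  f <- numeric(4)
  for (k in 1:2) {
    i1 <- des$pairs$i_from[k]; i2 <- des$pairs$i_to[k]
    f[i2] <- f[i1] + ee_target[k] * des$delta * des$pairs$sign[k]
  }
  res <- elementary_effects(des, f)
  expect_equal(res$mu_star, 3, tolerance = 1e-12)
  expect_equal(res$sigma, 4, tolerance = 1e-12)
  expect_equal(res$score, 5, tolerance = 1e-12)
})

test_that("failed runs are dropped pairwise with bookkeeping", {
  d <- morris_distributions()[1:3, ]
  des <- morris_trajectories(d, r = 6, p = 4, seed = 7, oversample = 12)
  f <- as.numeric(des$points %*% c(1, 2, 3))
  f[c(2, 10)] <- NA
  res <- elementary_effects(des, f)
  expect_gt(attr(res, "n_dropped"), 0)
  expect_equal(res$mu_star, c(1, 2, 3), tolerance = 1e-10)

  # a parameter with no surviving pairs is an error
  f2 <- as.numeric(des$points %*% c(1, 2, 3))
  f2[des$points[, 1] > -1] <- f2[des$points[, 1] > -1]  # no-op
  bad <- f2
  bad[unique(c(des$pairs$i_from[des$pairs$coord == 1],
               des$pairs$i_to[des$pairs$coord == 1]))] <- NA
  expect_error(elementary_effects(des, bad), "missing")

  expect_error(elementary_effects(des, f[1:5]), "one response")
})

test_that("all-uniform robustness mode preserves a linear ranking", {
  dn <- morris_distributions()[1:5, ]
  du <- morris_distributions(all_uniform = TRUE)[1:5, ]
  a <- c(0.2, 5, 1, 3, 0.1)
  rank_of <- function(d) {
    des <- morris_trajectories(d, r = 12, p = 4, seed = 5, oversample = 24)
    res <- elementary_effects(des, as.numeric(des$points %*% a))
    res$name[order(res$rank)]
  }
  expect_identical(rank_of(dn), rank_of(du))
})

test_that("trajectory-count convergence loop stops and caps", {
  d <- morris_distributions()[1:6, ]
  lin <- function(X) {
    U <- t((t(X) - d$lower) / (d$upper - d$lower))
    as.numeric(U %*% c(6, 5, 4, 0.3, 0.2, 0.1))
  }
  out <- converge_r(d, lin, r_start = 4, r_step = 10, seed = 3,
                    r_cap = 40)
  expect_equal(out$r_final, 14)  # stable at the first comparison
  expect_setequal(out$result$name[order(out$result$rank)][1:3],
                  d$name[1:3])

  # an adversarial runner whose ranking never settles hits the cap
  flip <- local({
    k <- 0
    function(X) {
      k <<- k + 1
      a <- rep(0.1, 6); a[(k %% 6) + 1] <- 100
      as.numeric(X %*% a)
    }
  })
  expect_error(converge_r(d, flip, r_start = 4, r_step = 10, seed = 3,
                          r_cap = 20), "stabilise")
})
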