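# Morris elementary-effects screening: one-at-a-time trajectories on a
# p-level grid in normalized [0,1]^k space, mapped to physical values
# through each parameter's inverse CDF, summarized per parameter by
# mu* (mean absolute elementary effect), sigma (sd of elementary
# effects) and the combined score sqrt(mu*^2 + sigma^2).

#' Screening distributions for the 39 model parameters
#'
#' Materialises the distribution attached to each registry parameter:
#' uniform for the stenosis percentage and the subendocardial/subepicardial
#' volume ratio, truncated normal (mean +/- 2 sd) for the rest, with the
#' standard deviation defaulting to 25% of the mean where the registry
#' records none.  The all-uniform mode replaces every truncated normal by
#' a uniform over the same range, used as a robustness check on the
#' influence ranking.
#'
#' @param all_uniform Logical; replace truncated normals by uniforms over
#'   the same ranges.
#' @return data.frame with columns `name`, `family`, `mean`, `sd`,
#'   `lower`, `upper`, `units`; one row per registry parameter.
#' @export
#' @examples
#' d <- morris_distributions()
#' table(d$family)
morris_distributions <- function(all_uniform = FALSE) {
  reg <- param_registry()
  sd <- ifelse(is.na(reg$sd), 0.25 * abs(reg$default), reg$sd)
  d <- data.frame(name = reg$name, family = reg$family,
                  mean = reg$default, sd = sd,
                  lower = reg$lower, upper = reg$upper,
                  units = reg$units, stringsAsFactors = FALSE)
  tn <- d$family == "tnorm"
  d$lower[tn] <- d$mean[tn] - 2 * d$sd[tn]
  d$upper[tn] <- d$mean[tn] + 2 * d$sd[tn]
  d$sd[!tn] <- NA_real_
  d$mean[!tn] <- (d$lower[!tn] + d$upper[!tn]) / 2
  if (nrow(d) != nrow(reg)) stop("registry/distribution count mismatch")
  if (all_uniform) {
    d$family <- "uniform"
    d$sd <- NA_real_
  }
  d
}

#' Inverse-CDF map from normalized [0,1] to physical values
#'
#' Uniform entries map linearly onto `[lower, upper]`; truncated normals
#' use the renormalized truncated quantile function (not clipping, which
#' would pile probability mass on the bounds and bias elementary
#' effects).
#'
#' @param u Matrix or vector of normalized coordinates in `[0, 1]`
#'   (columns = parameters).
#' @param dists Distribution table as from [morris_distributions()].
#' @return Matrix of physical parameter values with named columns.
#' @export
map_to_physical <- function(u, dists) {
  u <- rbind(u)
  if (ncol(u) != nrow(dists)) stop("dimension mismatch", call. = FALSE)
  out <- u
  for (j in seq_len(nrow(dists))) {
    d <- dists[j, ]
    if (d$family == "uniform") {
      out[, j] <- d$lower + u[, j] * (d$upper - d$lower)
    } else {
      a <- (d$lower - d$mean) / d$sd
      b <- (d$upper - d$mean) / d$sd
      pa <- stats::pnorm(a); pb <- stats::pnorm(b)
      out[, j] <- d$mean + d$sd *
        stats::qnorm(pa + u[, j] * (pb - pa))
    }
  }
  colnames(out) <- dists$name
  out
}

# one random trajectory: (k+1) x k matrix on the p-level grid, consecutive
# rows differing in exactly one coordinate by +/- delta
one_trajectory <- function(k, p) {
  delta <- p / (2 * (p - 1))
  base_grid <- seq(0, 1 - delta, by = 1 / (p - 1))
  lo <- base_grid[sample.int(length(base_grid), k, replace = TRUE)]
  dir <- sample(c(-1, 1), k, replace = TRUE)   # -1: start high, step down
  start <- ifelse(dir > 0, lo, lo + delta)
  ord <- sample.int(k)
  pts <- matrix(rep(start, k + 1), nrow = k + 1, byrow = TRUE)
  for (m in seq_len(k)) {
    j <- ord[m]
    pts[(m + 1):(k + 1), j] <- start[j] + dir[j] * delta
  }
  list(points = pts, coord = ord, sign = dir[ord], delta = delta)
}

#' Build a Morris screening design
#'
#' Generates `oversample` candidate trajectories and keeps the `r` with
#' the greatest pairwise spread, selected greedily by max-min aggregate
#' Euclidean distance between trajectory point sets (an approximation,
#' with the same goal, of published spread-maximizing selection
#' strategies).  The design has `r * (k + 1)` evaluation points and is
#' deterministic for a given seed.
#'
#' @param dists Distribution table ([morris_distributions()]); only its
#'   row count (the input dimension `k`) matters for the design itself.
#' @param r Number of trajectories kept (>= 2 unless `oversample == r`).
#' @param p Number of grid levels (even; default 4).
#' @param seed Integer RNG seed.
#' @param oversample Candidate pool size (>= r; default 200).
#' @return Object of class `morris_design`: list with `points`
#'   (`r*(k+1) x k` normalized matrix), `pairs` (data.frame mapping each
#'   elementary-effect pair to its rows, coordinate and sign), `delta`,
#'   `p`, `r`, `k`.
#' @export
#' @examples
#' d <- morris_trajectories(morris_distributions(), r = 4, seed = 1,
#'                          oversample = 8)
#' nrow(d$points)  # 4 * 40
morris_trajectories <- function(dists, r, p = 4, seed = 1,
                                oversample = 200) {
  k <- nrow(dists)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  if (p %% 2 != 0) stop("p must be even", call. = FALSE)
  if (oversample < r) stop("oversample must be >= r", call. = FALSE)
  set.seed(seed)
  cand <- replicate(oversample, one_trajectory(k, p), simplify = FALSE)
  keep <- if (oversample == r) seq_len(r) else {
    select_spread(lapply(cand, `[[`, "points"), r)
  }
  cand <- cand[keep]

  pts <- do.call(rbind, lapply(cand, `[[`, "points"))
  pairs <- do.call(rbind, lapply(seq_along(cand), function(i) {
    off <- (i - 1) * (k + 1)
    data.frame(traj = i, i_from = off + seq_len(k),
               i_to = off + seq_len(k) + 1,
               coord = cand[[i]]$coord, sign = cand[[i]]$sign)
  }))
  out <- list(points = pts, pairs = pairs,
              delta = p / (2 * (p - 1)), p = p, r = r, k = k,
              names = dists$name)
  class(out) <- "morris_design"
  out
}

# Greedy max-min selection of r trajectories from a candidate list.  The
# trajectory-pair distance is the root-sum-of-squares of all point-pair
# Euclidean distances, which collapses to a closed form in the per-
# trajectory point sums, so the full pairwise matrix costs O(n^2 k).
select_spread <- function(traj_pts, r) {
  n <- length(traj_pts)
  m <- nrow(traj_pts[[1]])
  s2 <- vapply(traj_pts, function(x) sum(x^2), numeric(1))
  S <- t(vapply(traj_pts, colSums, numeric(ncol(traj_pts[[1]]))))
  D <- m * outer(s2, s2, "+") - 2 * tcrossprod(S)
  D <- sqrt(pmax(D, 0))
  sel <- as.integer(arrayInd(which.max(D), dim(D)))
  while (length(sel) < r) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(c) min(D[c, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  sort(sel[seq_len(r)])
}

#' Elementary effects from a Morris design and its responses
#'
#' For each one-coordinate step of the design,
#' `EE = (f(x + delta e_i) - f(x)) / (delta * sign)` in normalized
#' coordinates.  Pairs with a non-finite response at either end (failed
#' model runs) are dropped pairwise and counted.  Per parameter the
#' result reports `mu_star = mean(|EE|)`, `sigma = sd(EE)` and the
#' combined influence score `sqrt(mu_star^2 + sigma^2)`, plus the rank by
#' that score.
#'
#' @param design A `morris_design`.
#' @param responses Numeric vector, one response per design point (row of
#'   `design$points`).
#' @return Object of class `morris_result`: data.frame `name`, `mu_star`,
#'   `sigma`, `score`, `rank`, with attributes `n_dropped` and `n_pairs`.
#' @export
elementary_effects <- function(design, responses) {
  stopifnot(inherits(design, "morris_design"))
  if (length(responses) != nrow(design$points)) {
    stop("one response per design point required", call. = FALSE)
  }
  pr <- design$pairs
  f1 <- responses[pr$i_from]; f2 <- responses[pr$i_to]
  ok <- is.finite(f1) & is.finite(f2)
  ee <- (f2[ok] - f1[ok]) / (design$delta * pr$sign[ok])
  coord <- pr$coord[ok]
  res <- data.frame(name = design$names,
                    mu_star = NA_real_, sigma = NA_real_)
  for (j in seq_len(design$k)) {
    e <- ee[coord == j]
    if (length(e) == 0) {
      stop("all elementary effects missing for parameter ",
           design$names[j], call. = FALSE)
    }
    res$mu_star[j] <- mean(abs(e))
    res$sigma[j] <- if (length(e) > 1) stats::sd(e) else 0
  }
  res$score <- sqrt(res$mu_star^2 + res$sigma^2)
  res$rank <- rank(-res$score, ties.method = "first")
  attr(res, "n_dropped") <- sum(!ok)
  attr(res, "n_pairs") <- sum(ok)
  class(res) <- c("morris_result", "data.frame")
  res
}

#' @export
print.morris_result <- function(x, n = 8, ...) {
  cat("<morris_result>", attr(x, "n_pairs"), "elementary-effect pairs (",
      attr(x, "n_dropped"), "dropped )\n")
  print.data.frame(utils::head(x[order(x$rank), ], n), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Trajectory-count convergence loop
#'
#' Increases the number of trajectories in steps until the identity of the
#' `top_n` most influential parameters (by combined score) is unchanged
#' between successive designs, the stopping rule used to size screening
#' studies.
#'
#' @param dists Distribution table.
#' @param runner Function mapping a physical parameter matrix (rows =
#'   evaluation points) to a numeric response vector.
#' @param r_start Initial trajectory count.
#' @param r_step Increment (default 10).
#' @param top_n Size of the ranking that must stabilise (default 3).
#' @param r_cap Maximum trajectory count before declaring instability.
#' @param p,seed,oversample Passed to [morris_trajectories()]; each
#'   iteration derives its own seed from `seed` and `r`.
#' @return List with `r_final`, `result` (a `morris_result`) and `history`
#'   (top-`top_n` sets per r).
#' @export
converge_r <- function(dists, runner, r_start = 10, r_step = 10,
                       top_n = 3, r_cap = 100, p = 4, seed = 1,
                       oversample = NULL) {
  run_at <- function(r) {
    os <- if (is.null(oversample)) max(2 * r, 20) else max(oversample, r)
    des <- morris_trajectories(dists, r = r, p = p, seed = seed + r,
                               oversample = os)
    X <- map_to_physical(des$points, dists)
    elementary_effects(des, runner(X))
  }
  top_set <- function(res) res$name[order(res$rank)][seq_len(top_n)]
  r <- r_start
  res <- run_at(r)
  history <- list(stats::setNames(list(top_set(res)), as.character(r)))
  repeat {
    r_next <- r + r_step
    if (r_next > r_cap) {
      stop("top-", top_n, " ranking did not stabilise below r = ", r_cap,
           call. = FALSE)
    }
    res_next <- run_at(r_next)
    history <- c(history, stats::setNames(list(top_set(res_next)),
                                          as.character(r_next)))
    if (setequal(top_set(res), top_set(res_next))) {
      return(list(r_final = r_next, result = res_next, history = history))
    }
    r <- r_next
    res <- res_next
  }
}

#' Run the Morris screening stage on the 0D model
#'
#' Builds the design over all registry parameters, runs one simulation per
#' design point, extracts the four response metrics (Q_mean, PI,
#' D/S-ratio, DRI) and computes elementary effects per metric.  Failed or
#' non-converged runs yield NA responses and are dropped pairwise.
#'
#' @param r,p,seed,oversample Design settings (see
#'   [morris_trajectories()]).
#' @param dists Distribution table (default [morris_distributions()]).
#' @param n_beats,dt Simulation settings passed to each run.
#' @return List with `results` (named list of `morris_result`, one per
#'   metric), `ranking` (combined ranking data.frame), `design`,
#'   `n_failed`.
#' @export
run_morris_stage <- function(r = 50, p = 4, seed = 1, oversample = 200,
                             dists = morris_distributions(),
                             n_beats = 8, dt = NULL) {
  des <- morris_trajectories(dists, r = r, p = p, seed = seed,
                             oversample = oversample)
  X <- map_to_physical(des$points, dists)
  resp <- run_model_batch(X, n_beats = n_beats, dt = dt)
  metrics <- colnames(resp)
  results <- lapply(metrics, function(m) elementary_effects(des, resp[, m]))
  names(results) <- metrics
  ranking <- combine_rankings(results)
  list(results = results, ranking = ranking, design = des,
       n_failed = sum(!stats::complete.cases(resp)))
}

# run the 0D model at each row of a physical parameter matrix and return
# the across-beat-median metrics (NA row on failure)
run_model_batch <- function(X, n_beats = 8, dt = NULL) {
  out <- matrix(NA_real_, nrow = nrow(X), ncol = 4,
                dimnames = list(NULL, c("Q_mean", "PI", "DS_ratio", "DRI")))
  for (i in seq_len(nrow(X))) {
    out[i, ] <- tryCatch({
      pars <- default_parameters(as.list(X[i, ]))
      sim <- simulate_graftflow(pars, n_beats = n_beats, dt = dt)
      m <- sim_metrics(sim)$median
      m[c("Q_mean", "PI", "DS_ratio", "DRI")]
    }, error = function(e) rep(NA_real_, 4))
  }
  out
}

# combined cross-metric ranking: per-metric scores normalized by their
# maximum, then averaged; used only to order parameters for stage wiring
combine_rankings <- function(results) {
  scores <- sapply(results, function(r) r$score / max(r$score))
  comb <- rowMeans(scores)
  data.frame(name = results[[1]]$name, score = comb,
             rank = rank(-comb, ties.method = "first"))[order(-comb), ]
}
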