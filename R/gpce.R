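# Regression-based generalized polynomial chaos expansion (gPCE) over the
# 9-parameter uncertainty set, with 10-fold cross-validated order
# selection, unphysical-run filtering and Sobol index extraction from the
# expansion coefficients.

#' The 9-parameter uncertainty-quantification set
#'
#' Stenosis percentage (uniform on \[0, 75\]%) plus eight physiological
#' parameters with normal distributions truncated to mean +/- 1.96 sd.
#' Four entries are 0D lumped surrogates for vessel-geometry parameters
#' that only exist in a distributed model: systemic arterial compliance
#' and characteristic (aortic valve) resistance stand in for systemic
#' artery cross-section and wave speed, and the graft lumped resistance
#' and inertance for the graft cross-section and wave speed.  Surrogate
#' spreads are mapped through the physical relation rather than copied:
#' the graft resistance carries a 50%-of-mean standard deviation because
#' resistance inherits twice the relative variance of the cross-sectional
#' area it surrogates (R ~ A^-2), while the lumped arterial compliance
#' carries 15% because the surrogated quantity is a single segment's
#' cross-section and that segment holds only part (roughly 60%) of the
#' aggregated compliance the lumped element represents.  All values are
#' user-overridable.
#'
#' @return data.frame with columns `name`, `family`, `mean`, `sd`,
#'   `lower`, `upper`; 9 rows.
#' @export
uq_parameter_set <- function() {
  reg <- param_registry()
  pick <- function(n) reg$default[reg$name == n]
  tn <- function(name, mean, rel_sd = 0.25, sd = rel_sd * abs(mean)) {
    data.frame(name = name, family = "tnorm", mean = mean, sd = sd,
               lower = mean - 1.96 * sd, upper = mean + 1.96 * sd,
               stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(name = "pct_s", family = "uniform", mean = 37.5,
               sd = NA_real_, lower = 0, upper = 75,
               stringsAsFactors = FALSE),
    tn("R0_svb", pick("R0_svb")),
    tn("C_sa", pick("C_sa"), rel_sd = 0.15),
    tn("R_av", pick("R_av")),
    tn("R_graft", pick("R_graft"), rel_sd = 0.5),
    tn("L_graft", pick("L_graft")),
    tn("C1", pick("C1")),
    tn("V0_1", pick("V0_1")),
    tn("T", pick("T"), sd = 0.12)
  )
}

#' Draw an input sample matrix for the UQ stage
#'
#' Independent draws per parameter; truncated normals are sampled by
#' rejection (redraw outside the bounds), uniforms directly.  The matrix
#' is deterministic for a given seed.
#'
#' @param uq Parameter table as from [uq_parameter_set()].
#' @param n Number of samples.
#' @param seed Integer RNG seed.
#' @return `n x nrow(uq)` matrix with named columns.
#' @export
sample_inputs <- function(uq, n, seed = 1) {
  set.seed(seed)
  X <- matrix(NA_real_, n, nrow(uq), dimnames = list(NULL, uq$name))
  for (j in seq_len(nrow(uq))) {
    d <- uq[j, ]
    if (d$family == "uniform") {
      if (!(d$upper > d$lower)) stop("degenerate distribution: ", d$name,
                                     call. = FALSE)
      X[, j] <- stats::runif(n, d$lower, d$upper)
    } else {
      if (!is.finite(d$sd) || d$sd <= 0) {
        stop("degenerate distribution: ", d$name, call. = FALSE)
      }
      x <- stats::rnorm(n, d$mean, d$sd)
      bad <- x < d$lower | x > d$upper
      while (any(bad)) {
        x[bad] <- stats::rnorm(sum(bad), d$mean, d$sd)
        bad <- x < d$lower | x > d$upper
      }
      X[, j] <- x
    }
  }
  X
}

#' Regression sample count for a total-degree PCE
#'
#' `collocation_factor * choose(d + order, order)`: the number of
#' least-squares samples needed for a total-degree-`order` expansion in
#' `d` dimensions at the given collocation factor.
#'
#' @param d Input dimension.
#' @param order Total polynomial degree.
#' @param collocation_factor Samples per basis term (default 2).
#' @return Integer sample count.
#' @export
#' @examples
#' required_sample_count(9, 2, 2)  # 110
required_sample_count <- function(d, order, collocation_factor = 2) {
  if (d < 1 || order < 0) stop("d >= 1 and order >= 0 required",
                               call. = FALSE)
  as.integer(round(collocation_factor * choose(d + order, order)))
}

# total-degree multi-indices: all alpha in N^d with sum(alpha) <= order
multi_indices <- function(d, order) {
  grow <- function(prefix, remaining, dims_left) {
    if (dims_left == 0) return(matrix(prefix, nrow = 1))
    do.call(rbind, lapply(0:remaining, function(a) {
      grow(c(prefix, a), remaining - a, dims_left - 1)
    }))
  }
  idx <- grow(integer(0), order, d)
  idx[order(rowSums(idx)), , drop = FALSE]
}

# orthonormal Legendre values: length(z) x (order+1), column k+1 = phi_k(z),
# orthonormal w.r.t. the uniform density on [-1, 1]
legendre_orthonormal <- function(z, order) {
  out <- matrix(0, length(z), order + 1)
  out[, 1] <- 1
  if (order >= 1) out[, 2] <- z
  if (order >= 2) {
    for (k in 1:(order - 1)) {
      out[, k + 2] <- ((2 * k + 1) * z * out[, k + 1] - k * out[, k]) /
        (k + 1)
    }
  }
  sweep(out, 2, sqrt(2 * (0:order) + 1), `*`)
}

# basis matrix for sample matrix X given per-dimension bounds
pce_basis <- function(X, indices, bounds) {
  X <- rbind(X)
  d <- ncol(X)
  Z <- sapply(seq_len(d), function(j) {
    2 * (X[, j] - bounds[j, 1]) / (bounds[j, 2] - bounds[j, 1]) - 1
  })
  Z <- rbind(Z)
  max_ord <- max(indices)
  legs <- lapply(seq_len(d), function(j) legendre_orthonormal(Z[, j], max_ord))
  B <- matrix(1, nrow(X), nrow(indices))
  for (b in seq_len(nrow(indices))) {
    for (j in seq_len(d)) {
      o <- indices[b, j]
      if (o > 0) B[, b] <- B[, b] * legs[[j]][, o + 1]
    }
  }
  B
}

#' Fit a polynomial chaos expansion by least squares
#'
#' Total-degree expansion on a tensorised orthonormal Legendre basis over
#' each input's bounded range (uniform inputs exactly; truncated normals
#' are treated over their truncation range, a deliberate
#' weight-orthogonality approximation — see the package vignette — whose
#' Sobol consequences are cross-checked by Monte-Carlo pick-freeze on the
#' fitted surrogate).
#'
#' @param samples `n x d` input matrix (named columns).
#' @param responses Numeric vector or `n x m` matrix of responses.
#' @param order Total polynomial degree.
#' @param bounds `d x 2` matrix of input ranges; defaults to the column
#'   ranges of `samples`.
#' @return Object of class `pce_model`: list with `indices`, `coef`,
#'   `bounds`, `order`, `names`, `rmse`.
#' @export
fit_pce <- function(samples, responses, order, bounds = NULL) {
  samples <- rbind(samples)
  responses <- cbind(responses)
  if (nrow(samples) != nrow(responses)) {
    stop("responses must align with samples", call. = FALSE)
  }
  d <- ncol(samples)
  if (is.null(bounds)) {
    bounds <- cbind(apply(samples, 2, min), apply(samples, 2, max))
  }
  indices <- multi_indices(d, order)
  if (nrow(samples) < nrow(indices)) {
    stop("need at least ", nrow(indices), " samples for order ", order,
         "; increase the sample count", call. = FALSE)
  }
  B <- pce_basis(samples, indices, bounds)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    stop("rank-deficient regression system; more (or better spread) ",
         "samples are needed", call. = FALSE)
  }
  coef <- qr.coef(qrB, responses)
  fit <- B %*% coef
  model <- list(indices = indices, coef = coef, bounds = bounds,
                order = order,
                names = colnames(samples),
                rmse = sqrt(colMeans((responses - fit)^2)))
  class(model) <- "pce_model"
  model
}

#' Evaluate a fitted PCE at new inputs
#'
#' @param model A `pce_model`.
#' @param X Input matrix (or vector for a single point).
#' @return Matrix of predictions (columns = responses).
#' @export
pce_predict <- function(model, X) {
  pce_basis(rbind(X), model$indices, model$bounds) %*% model$coef
}

#' Select the PCE order by k-fold cross-validation
#'
#' Computes the k-fold CV RMSE for every candidate total degree in
#' `1:max_order` and returns the minimiser; on ties the lower order wins.
#' Folds are assigned by a seeded permutation.
#'
#' @param samples,responses Input matrix and response vector.
#' @param max_order Largest candidate degree (default 2).
#' @param k Number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param bounds Optional input bounds (see [fit_pce()]).
#' @return List with `order` (selected) and `cv` (data.frame `order`,
#'   `rmse`).
#' @export
select_order_by_cv <- function(samples, responses, max_order = 2, k = 10,
                               seed = 1, bounds = NULL) {
  samples <- rbind(samples)
  n <- nrow(samples)
  if (k > n) stop("k must not exceed the sample count", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  # candidate orders must be fittable on every training fold
  min_train <- n - max(table(fold))
  d <- ncol(samples)
  fittable <- vapply(seq_len(max_order), function(ord) {
    choose(d + ord, ord) <= min_train
  }, logical(1))
  if (!any(fittable)) {
    stop("too few samples for any candidate order under ", k,
         "-fold CV", call. = FALSE)
  }
  orders <- seq_len(max_order)[fittable]
  rmse <- vapply(orders, function(ord) {
    se <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- fit_pce(samples[tr, , drop = FALSE], responses[tr], ord,
                   bounds = bounds)
      pred <- pce_predict(m, samples[!tr, , drop = FALSE])
      se <- se + sum((responses[!tr] - pred)^2)
    }
    sqrt(se / n)
  }, numeric(1))
  list(order = orders[which.min(rmse)],
       cv = data.frame(order = orders, rmse = rmse))
}

#' Sobol indices from a fitted PCE
#'
#' Variance decomposition read directly off the orthonormal expansion:
#' the main index of input `i` is the variance of all terms involving
#' only `i` over the total variance, the total index that of all terms
#' involving `i` at all.  For an order-1 expansion the two coincide
#' exactly.
#'
#' @param model A `pce_model` (single-response coefficients, or pass
#'   `response` to pick a column).
#' @param response Response column index (default 1).
#' @return Object of class `sobol_indices`: data.frame `name`, `main`,
#'   `total`, with attribute `variance`.
#' @export
sobol_from_pce <- function(model, response = 1) {
  stopifnot(inherits(model, "pce_model"))
  co <- model$coef[, response]
  idx <- model$indices
  active <- idx > 0
  nonconst <- rowSums(idx) > 0
  total_var <- sum(co[nonconst]^2)
  # a numerically constant response has no variance to decompose
  if (total_var <= (1e-10 * max(1, abs(co[1])))^2) {
    stop("zero total variance; Sobol indices undefined", call. = FALSE)
  }
  d <- ncol(idx)
  main <- total <- numeric(d)
  for (i in seq_len(d)) {
    only_i <- active[, i] & rowSums(active) == 1
    any_i <- active[, i]
    main[i] <- sum(co[only_i]^2) / total_var
    total[i] <- sum(co[any_i]^2) / total_var
  }
  out <- data.frame(name = model$names %||% paste0("x", seq_len(d)),
                    main = main, total = total)
  attr(out, "variance") <- total_var
  class(out) <- c("sobol_indices", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo pick-freeze Sobol estimate on a surrogate
#'
#' Saltelli-style pick-freeze estimator of the main Sobol indices of a
#' fitted surrogate under the actual sampling distribution; used as an
#' independent cross-check of the coefficient-based indices, whose
#' derivation assumes weight orthogonality.
#'
#' @param model A `pce_model`.
#' @param uq Distribution table used to sample inputs.
#' @param n Monte-Carlo sample size per matrix.
#' @param seed RNG seed.
#' @param response Response column.
#' @return Named vector of main-index estimates.
#' @export
pick_freeze_sobol <- function(model, uq, n = 4000, seed = 1, response = 1) {
  A <- sample_inputs(uq, n, seed = seed)
  B <- sample_inputs(uq, n, seed = seed + 1)
  fA <- pce_predict(model, A)[, response]
  fB <- pce_predict(model, B)[, response]
  v <- stats::var(c(fA, fB))
  s <- numeric(ncol(A))
  for (i in seq_len(ncol(A))) {
    ABi <- A; ABi[, i] <- B[, i]
    fABi <- pce_predict(model, ABi)[, response]
    s[i] <- mean(fB * (fABi - fA)) / v
  }
  stats::setNames(s, colnames(A))
}

#' Does the aortic pressure peak fall in diastole?
#'
#' Rule used to flag obviously unphysical runs: over the last complete
#' beat, locate the aortic-pressure maximum and test whether it lies in
#' the diastolic interval.
#'
#' @param sim A `graft_sim` object.
#' @return Logical.
#' @export
peak_in_diastole <- function(sim) {
  seg <- segment_beats(sim)
  b <- seg[nrow(seg), ]
  i <- sim$time >= b$t_start & sim$time < b$t_end
  t_peak <- sim$time[i][which.max(sim$signals$p_ao[i])]
  t_peak > b$t_sys_end
}

#' Remove runs with an unphysical pressure waveform
#'
#' Splits a list of simulation runs into kept and removed sets, removing
#' every run whose aortic-pressure maximum over the last complete beat
#' falls inside diastole.  Idempotent: filtering the kept set again
#' removes nothing.
#'
#' @param runs List of `graft_sim` objects.
#' @param ids Optional run identifiers (default: positional index).
#' @return List with `kept` (runs), `kept_ids`, `removed` (data.frame of
#'   `id`), `fraction_removed`.
#' @export
filter_unphysical <- function(runs, ids = seq_along(runs)) {
  flags <- vapply(runs, function(s) {
    if (!inherits(s, "graft_sim")) {
      stop("filter_unphysical expects graft_sim runs", call. = FALSE)
    }
    peak_in_diastole(s)
  }, logical(1))
  list(kept = runs[!flags], kept_ids = ids[!flags],
       removed = data.frame(id = ids[flags]),
       fraction_removed = mean(flags))
}

# map one row of the UQ sample matrix onto a full model parameter set
apply_uq_row <- function(x) {
  default_parameters(as.list(x), stenosis_enabled = TRUE)
}

#' Run the full uncertainty-quantification stage
#'
#' Samples the 9-parameter set, runs the 0D model (or a supplied
#' surrogate) at every sample, extracts the patency metrics, removes
#' failed and unphysical runs, selects the expansion order per metric by
#' 10-fold cross-validation, fits the PCE and reports Sobol indices per
#' metric.  Aborts when more than half the runs are lost to failure or
#' filtering.
#'
#' @param n Sample count; default
#'   `required_sample_count(9, max_order, collocation_factor)`.
#' @param seed RNG seed (drives sampling and CV folds).
#' @param max_order Largest candidate degree (default 2).
#' @param collocation_factor Regression oversampling factor (default 2).
#' @param uq Parameter table (default [uq_parameter_set()]).
#' @param runner Function mapping one named parameter vector (a sample
#'   row) to a list with `metrics` (named numeric vector) and `unphysical`
#'   (logical); defaults to running the 0D model.
#' @param n_beats,dt Simulation settings for the default runner.
#' @return Object of class `uq_report`: list with `sobol` (long
#'   data.frame `metric`, `name`, `main`, `total`), `orders`, `cv`,
#'   `removed` (ids and fraction), `n`, `n_kept`, `seed`, `samples`,
#'   `responses`.
#' @export
run_uq_stage <- function(n = NULL, seed = 1, max_order = 2,
                         collocation_factor = 2,
                         uq = uq_parameter_set(), runner = NULL,
                         n_beats = 8, dt = NULL) {
  d <- nrow(uq)
  if (is.null(n)) n <- required_sample_count(d, max_order, collocation_factor)
  if (is.null(runner)) {
    runner <- function(x) {
      sim <- simulate_graftflow(apply_uq_row(x), n_beats = n_beats, dt = dt)
      list(metrics = sim_metrics(sim)$median[c("Q_mean", "PI",
                                               "DS_ratio", "DRI")],
           unphysical = peak_in_diastole(sim))
    }
  }
  X <- sample_inputs(uq, n, seed = seed)
  resp <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("Q_mean", "PI", "DS_ratio", "DRI")))
  unphys <- rep(FALSE, n)
  for (i in seq_len(n)) {
    out <- tryCatch(runner(X[i, ]), error = function(e) NULL)
    if (is.null(out)) next
    resp[i, names(out$metrics)] <- out$metrics
    unphys[i] <- isTRUE(out$unphysical)
  }
  failed <- !stats::complete.cases(resp)
  keep <- !failed & !unphys
  if (mean(!keep) > 0.5) {
    stop(sprintf("%.0f%% of runs failed or were filtered; aborting",
                 100 * mean(!keep)), call. = FALSE)
  }
  Xk <- X[keep, , drop = FALSE]
  bounds <- cbind(uq$lower, uq$upper)
  sobol <- list(); orders <- integer(0); cvs <- list()
  for (m in colnames(resp)) {
    y <- resp[keep, m]
    sel <- select_order_by_cv(Xk, y, max_order = max_order, k = 10,
                              seed = seed, bounds = bounds)
    model <- fit_pce(Xk, y, sel$order, bounds = bounds)
    si <- sobol_from_pce(model)
    sobol[[m]] <- data.frame(metric = m, si)
    orders[m] <- sel$order
    cvs[[m]] <- sel$cv
  }
  out <- list(sobol = do.call(rbind, sobol), orders = orders, cv = cvs,
              removed = list(failed_ids = which(failed),
                             unphysical_ids = which(unphys & !failed),
                             fraction = mean(!keep)),
              n = n, n_kept = sum(keep), seed = seed,
              samples = Xk, responses = resp[keep, , drop = FALSE])
  class(out) <- "uq_report"
  out
}

#' @export
print.uq_report <- function(x, ...) {
  cat(sprintf("<uq_report> %d/%d runs kept (seed %d)\n",
              x$n_kept, x$n, x$seed))
  for (m in unique(x$sobol$metric)) {
    s <- x$sobol[x$sobol$metric == m, ]
    top <- s[which.max(s$main), ]
    cat(sprintf("  %-8s order %d, top Sobol: %s (%.2f)\n", m, x$orders[m],
                top$name, top$main))
  }
  invisible(x)
}
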