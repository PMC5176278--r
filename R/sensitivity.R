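# Global sensitivity analysis: Latin hypercube sampling over parameter
# ranges, one proliferation run per sample, and partial rank correlation
# coefficients of the day-60 tumor radius.

.default_sensitivity_params <- c("lam_E", "lam_M", "lam_A", "lam_MA",
                                 "lam_T", "lam_P", "lam_Ap", "lam_Ec",
                                 "lam_m1", "lam_m2", "d_Ec")

#' Sensitivity design
#'
#' Defines the sampled parameters, their ranges (default: half to twice
#' the value in `p`), the sample count and the RNG seed.
#'
#' @param p a `parameter_set` supplying the default range centres.
#' @param parameters character vector of parameter symbols.
#' @param ranges optional named list of `c(low, high)` ranges overriding
#'   the defaults.
#' @param n number of samples (>= 10).
#' @param seed integer RNG seed.
#' @return object of class `sensitivity_design`.
#' @export
sensitivity_design <- function(p, parameters = .default_sensitivity_params,
                               ranges = NULL, n = 1000, seed = 42) {
  if (n < 10) stop("n must be at least 10")
  bad <- setdiff(parameters, setdiff(names(p), "steady"))
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  rng <- lapply(setNames(parameters, parameters), function(nm) {
    v <- p[[nm]]
    c(v / 2, 2 * v)
  })
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), parameters)
    if (length(bad) > 0) {
      stop("range given for unsampled parameter(s): ",
           paste(bad, collapse = ", "))
    }
    rng[names(ranges)] <- ranges
  }
  for (nm in names(rng)) {
    if (rng[[nm]][1] >= rng[[nm]][2]) {
      stop("range for ", nm, " must satisfy low < high")
    }
  }
  structure(list(parameters = parameters, ranges = rng, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "sensitivity_design")
}

#' Latin hypercube sample
#'
#' Draws an n-by-k Latin hypercube: each column contains exactly one
#' uniform draw per equal-probability stratum of its range, in random
#' order. Reproducible from the design seed.
#'
#' @param design a [sensitivity_design()].
#' @return n-by-k matrix with parameter names as columns.
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"))
  k <- length(design$parameters)
  set.seed(design$seed)
  u <- lhs::randomLHS(design$n, k)
  X <- sapply(seq_len(k), function(j) {
    r <- design$ranges[[j]]
    r[1] + u[, j] * (r[2] - r[1])
  })
  X <- matrix(X, nrow = design$n, ncol = k,
              dimnames = list(NULL, design$parameters))
  X
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms inputs and output (average ranks on ties); the PRCC of
#' parameter j is the Pearson correlation of the residuals of rank-y and
#' rank-X_j after linear regression of each on all other rank-columns.
#' P-values come from the t statistic
#' `prcc * sqrt((n - 2 - (k - 1)) / (1 - prcc^2))`.
#'
#' @param X n-by-k matrix of sampled parameter values.
#' @param y length-n model outputs.
#' @return data frame with columns `parameter`, `prcc`, `p_value`.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (n <= k + 2) stop("need n > k + 2 samples")
  if (any(apply(X, 2, function(col) diff(range(col)) == 0))) {
    bad <- colnames(X)[apply(X, 2, function(col) diff(range(col)) == 0)]
    stop("degenerate (constant) design column(s): ",
         paste(bad, collapse = ", "))
  }
  Xr <- apply(X, 2, rank, ties.method = "average")
  yr <- rank(y, ties.method = "average")
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  df <- n - 2 - (k - 1)
  out <- data.frame(parameter = nms, prcc = NA_real_, p_value = NA_real_)
  for (j in seq_len(k)) {
    Z <- cbind(1, Xr[, -j, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      stop("singular regression: collinear rank columns among ",
           paste(nms[-j], collapse = ", "))
    }
    rx <- qr.resid(qz, Xr[, j])
    ry <- qr.resid(qz, yr)
    r <- cor(rx, ry)
    out$prcc[j] <- r
    tstat <- r * sqrt(df / (1 - r^2))
    out$p_value[j] <- 2 * pt(-abs(tstat), df)
  }
  out
}

#' Run the global sensitivity analysis
#'
#' One proliferation run per Latin hypercube sample (coarser solver
#' settings than the production runs), collecting the day-`t_end` tumor
#' radius, then PRCC with p-values. Failed runs are dropped with a
#' warning when they are fewer than 5% of the samples.
#'
#' @param p a `parameter_set` (proliferation phase).
#' @param design a [sensitivity_design()].
#' @param tau solver time step in days (default 5e-3, coarser than the
#'   production default).
#' @param n_nodes radial mesh nodes for the sensitivity runs.
#' @param t_end output day for the tumor radius.
#' @return object of class `sensitivity_result` with elements `design`,
#'   `samples` (n-by-k matrix), `radius` (day-`t_end` radii, cm, NA for
#'   failed runs), and `prcc` (the [prcc()] table).
#' @export
run_sensitivity <- function(p, design, tau = 5e-3, n_nodes = 51,
                            t_end = 60) {
  stopifnot(inherits(design, "sensitivity_design"))
  X <- lhs_sample(design)
  radius <- rep(NA_real_, design$n)
  for (i in seq_len(design$n)) {
    p_i <- p
    for (nm in design$parameters) p_i[[nm]] <- X[i, nm]
    attr(p_i, "modified") <- unique(c(attr(p_i, "modified"),
                                      design$parameters))
    radius[i] <- tryCatch({
      res <- run_proliferation(p_i, t_end = t_end, tau = tau,
                               n_nodes = n_nodes,
                               record_times = c(0, t_end))
      m <- res$metrics
      m$radius_cm[m$time == t_end]
    }, error = function(e) NA_real_)
  }
  ok <- is.finite(radius)
  n_fail <- sum(!ok)
  if (n_fail > 0.05 * design$n) {
    stop(n_fail, " of ", design$n, " sensitivity runs failed")
  }
  if (n_fail > 0) {
    warning(n_fail, " sensitivity run(s) failed and were excluded")
  }
  tab <- prcc(X[ok, , drop = FALSE], radius[ok])
  structure(list(design = design, samples = X, radius = radius,
                 prcc = tab),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> n =", x$design$n, "samples, seed",
      x$design$seed, "\n")
  tab <- x$prcc[order(-abs(x$prcc$prcc)), ]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}
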