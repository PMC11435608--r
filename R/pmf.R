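#' Per-cell measurement uncertainties
#'
#' Builds the n x m uncertainty matrix used to weight the factorization.
#' Cells at or below the method detection limit (including censored
#' cells) get `u = (5/6) * MDL`; above the limit,
#' `u = sqrt((EF * x)^2 + (0.5 * MDL)^2)` where `EF` is the analyte's
#' error fraction and `x` the working concentration.
#'
#' @param table a [conc_table()]; censored cells are substituted at MDL/2
#'   first if they have not been already.
#' @return A positive numeric matrix the same shape as the concentration
#'   matrix, in ug/L.
#' @export
#' @examples
#' fx <- make_worked_fixtures()
#' u <- build_uncertainty(fx$table)
#' stopifnot(all(u > 0))
build_uncertainty <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  if (!table$substituted) table <- substitute_censored(table)
  X <- table$conc
  mdl <- table$analytes$mdl
  ef <- table$analytes$error_fraction
  if (anyNA(mdl) || anyNA(ef)) {
    bad <- table$analytes$name[is.na(mdl) | is.na(ef)]
    stop("missing MDL or error fraction for: ", paste(bad, collapse = ", "))
  }
  MDL <- matrix(mdl, nrow(X), ncol(X), byrow = TRUE)
  EF <- matrix(ef, nrow(X), ncol(X), byrow = TRUE)
  below <- X <= MDL
  u <- sqrt((EF * X)^2 + (0.5 * MDL)^2)
  u[below] <- (5 / 6) * MDL[below]
  dimnames(u) <- dimnames(X)
  u
}

pmf_init <- function(X, n, m, p) {
  G <- matrix(stats::runif(n * p), n, p)
  G <- sweep(G, 2, colMeans(G), "/")
  scale_j <- pmax(colMeans(X), .Machine$double.eps)
  F_ <- matrix(stats::runif(p * m), p, m) *
    matrix(2 * scale_j / p, p, m, byrow = TRUE)
  list(G = G, F = F_)
}

# One weighted-HALS pass: exact coordinate minimization of each G column
# then each F row under non-negativity, so Q never increases.
pmf_sweep <- function(X, W, G, F_) {
  p <- ncol(G)
  R <- X - G %*% F_
  for (k in seq_len(p)) {
    fk <- F_[k, ]
    num <- (W * R) %*% fk + G[, k] * (W %*% (fk^2))
    den <- W %*% (fk^2)
    gk <- ifelse(den > 0, pmax(0, num / den), G[, k])
    R <- R - (gk - G[, k]) %*% t(fk)
    G[, k] <- gk
  }
  for (k in seq_len(p)) {
    gk <- G[, k]
    num <- crossprod(W * R, gk) + F_[k, ] * crossprod(W, gk^2)
    den <- crossprod(W, gk^2)
    fk <- ifelse(den > 0, pmax(0, num / den), F_[k, ])
    R <- R - gk %*% t(fk - F_[k, ])
    F_[k, ] <- fk
  }
  list(G = G, F = F_, R = R)
}

# Rotational-ambiguity resolution: transformations G -> G A, F -> A^-1 F
# that keep both factors non-negative leave G %*% F -- and hence Q --
# exactly unchanged, so the minimizer is an equivalence class, not a
# point, and the representative a multi-start search returns is
# arbitrary. The polish deterministically selects the simplest
# (sparsest-profile) representative: each profile row is repeatedly
# reduced by the largest multiple of every other row it can shed while
# staying essentially non-negative (a robust low quantile of the
# entrywise ratio, so isolated zero entries do not block the move, with
# the corresponding exact transfer G_k += delta * G_l), and short plain
# sweeps after each round repair the clipped entries. Block-sparse
# profile sets -- distinct source signatures -- are fixed points of the
# map.
pmf_polish <- function(X, W, G, F_, rounds = 30, ratio_quantile = 0.1,
                       inner = 10, n_post = 100) {
  p <- nrow(F_)
  shed <- function(l, k) {
    ok <- F_[k, ] > 1e-9 * max(F_[k, ])
    if (!any(ok)) return(0)
    stats::quantile(F_[l, ok] / F_[k, ok], ratio_quantile, names = FALSE)
  }
  for (r in seq_len(rounds)) {
    moved <- FALSE
    for (l in seq_len(p)) for (k in seq_len(p)) if (k != l) {
      d <- shed(l, k)
      if (d > 1e-4) {
        F_[l, ] <- pmax(F_[l, ] - d * F_[k, ], 0)
        G[, k] <- G[, k] + d * G[, l]
        moved <- TRUE
      }
    }
    for (i in seq_len(inner)) {
      st <- pmf_sweep(X, W, G, F_)
      G <- st$G; F_ <- st$F
    }
    if (!moved) break
  }
  for (i in seq_len(n_post)) {
    st <- pmf_sweep(X, W, G, F_)
    G <- st$G; F_ <- st$F
  }
  list(G = G, F = F_)
}

pmf_run <- function(X, W, G, F_, max_iter, rel_tol, robust) {
  q_tr <- numeric(0)
  Q_prev <- sum(W * (X - G %*% F_)^2)
  streak <- 0L
  converged <- FALSE
  Weff <- W
  for (it in seq_len(max_iter)) {
    st <- pmf_sweep(X, Weff, G, F_)
    G <- st$G; F_ <- st$F
    if (robust) {
      # EPA-style down-weighting of outlying scaled residuals (|r| > 4)
      r <- st$R * sqrt(W)
      fac <- pmax(1, abs(r) / 4)
      Weff <- W / fac
    }
    Q <- sum(Weff * st$R^2)
    q_tr <- c(q_tr, Q)
    rel <- (Q_prev - Q) / max(Q_prev, .Machine$double.xmin)
    streak <- if (abs(rel) < rel_tol) streak + 1L else 0L
    Q_prev <- Q
    if (streak >= 20L) { converged <- TRUE; break }
  }
  list(G = G, F = F_, Q = Q_prev, q_trajectory = q_tr,
       converged = converged, iterations = length(q_tr))
}

#' Uncertainty-weighted positive matrix factorization
#'
#' Decomposes a non-negative sample-by-analyte concentration matrix X
#' into `p` non-negative source contributions G (n x p) and source
#' profiles F (p x m), X = G F + E, by minimizing the scaled-residual
#' objective Q = sum((E_ij / u_ij)^2) where u is the per-cell
#' measurement uncertainty. The optimizer alternates exact non-negative
#' weighted least-squares updates of the columns of G and rows of F
#' (weights 1/u^2), so Q is non-increasing within a run; `n_starts`
#' random initializations are tried and the lowest-Q solution kept.
#' After convergence each column of G is rescaled to mean 1 with the
#' scale absorbed into F, the usual receptor-modelling normalization.
#'
#' @param x a [conc_table()] (uncertainties are then built with
#'   [build_uncertainty()]) or a non-negative numeric matrix.
#' @param p number of factors, `1 <= p <= min(n, m) - 1`.
#' @param u positive uncertainty matrix, required when `x` is a matrix.
#' @param n_starts random starts (default 20).
#' @param max_iter iteration cap per start (default 5000).
#' @param rel_tol convergence: relative Q change below this for 20
#'   consecutive iterations (default 1e-9).
#' @param seed integer seed making the multi-start search reproducible.
#' @param robust down-weight scaled residuals beyond 4 (default `FALSE`).
#' @param simplify resolve the rotational ambiguity of the factorization
#'   by reporting the simplest (sparsest-profile) member of the winning
#'   solution's equivalence class (default `TRUE`). Transformations
#'   `G A, A^-1 F` that keep both matrices non-negative leave `G %*% F`
#'   -- and therefore Q -- unchanged, so without a convention the
#'   returned profiles are an arbitrary member of that class; the
#'   polish is a deterministic choice and does not alter the fit.
#'
#' @return An object of class `pmf`: matrices `G`, `F`, `E`, scalar `Q`,
#'   `q_expected` = nm - p(n + m), `factor_percent` (share of total
#'   reconstructed mass per factor, summing to 100), `profile_percent`
#'   (per-analyte share across factors, columns summing to 100),
#'   `converged`, `start_index`, `q_trajectory` of the winning run.
#' @seealso [factor_summaries()], [match_factors()], [pmf_scan_p()]
#' @export
#' @examples
#' syn <- generate_synthetic(synth_spec(n_surface = 20, m = 8, p = 2),
#'                           seed = 1)
#' fit <- pmf(syn$table, p = 2, n_starts = 5, seed = 1)
#' print(fit)
pmf <- function(x, p, u = NULL, n_starts = 20, max_iter = 5000,
                rel_tol = 1e-9, seed = NULL, robust = FALSE,
                simplify = TRUE) {
  if (inherits(x, "conc_table")) {
    x <- substitute_censored(x)
    if (is.null(u)) u <- build_uncertainty(x)
    X <- x$conc
  } else {
    X <- as.matrix(x)
    if (is.null(u)) stop("supply an uncertainty matrix 'u' with matrix input")
  }
  u <- as.matrix(u)
  n <- nrow(X); m <- ncol(X)
  if (!all(is.finite(X)) || !all(is.finite(u)))
    stop("non-finite entries in X or u")
  if (any(X < 0)) stop("X must be non-negative")
  if (any(u <= 0)) stop("uncertainties must be strictly positive")
  if (!identical(dim(u), dim(X))) stop("X and u shapes differ")
  p <- as.integer(p)
  if (p < 1 || p > min(n, m) - 1)
    stop("p must satisfy 1 <= p <= min(n, m) - 1 = ", min(n, m) - 1)
  stopifnot(n_starts >= 1, max_iter >= 1, rel_tol > 0)
  if (!is.null(seed)) set.seed(seed)

  W <- 1 / u^2
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- pmf_init(X, n, m, p)
    run <- pmf_run(X, W, init$G, init$F, max_iter, rel_tol, robust)
    if (is.null(best) || run$Q < best$Q) { best <- run; best$start <- s }
  }
  if (!best$converged)
    warning("no start converged within max_iter; returning best Q found")

  G <- best$G; F_ <- best$F
  if (simplify && p > 1) {
    # the polish only re-expresses the solution, so it is accepted only
    # when Q is preserved (within 0.1% relative); on solutions whose
    # equivalence class is narrow the shedding can overshoot, and the
    # original representative is kept instead
    po <- pmf_polish(X, W, G, F_)
    Qp <- sum(W * (X - po$G %*% po$F)^2)
    if (Qp <= best$Q * (1 + 1e-3) + 1e-10 * sum(W * X^2)) {
      G <- po$G; F_ <- po$F; best$Q <- Qp
    }
  }
  # normalize G columns to mean 1, scale absorbed into F
  d <- colMeans(G)
  pos <- d > 0
  G[, pos] <- sweep(G[, pos, drop = FALSE], 2, d[pos], "/")
  F_[pos, ] <- sweep(F_[pos, , drop = FALSE], 1, d[pos], "*")
  dimnames(G) <- list(rownames(X), paste0("Factor", seq_len(p)))
  dimnames(F_) <- list(paste0("Factor", seq_len(p)), colnames(X))
  E <- X - G %*% F_
  fs <- factor_summaries_impl(G, F_)
  structure(list(
    G = G, F = F_, E = E,
    Q = best$Q, q_expected = n * m - p * (n + m),
    converged = best$converged, start_index = best$start,
    iterations = best$iterations, q_trajectory = best$q_trajectory,
    factor_percent = fs$factor_percent,
    profile_percent = fs$profile_percent,
    X = X, u = u, p = p, n_starts = n_starts, robust = robust,
    call = match.call()
  ), class = "pmf")
}

factor_summaries_impl <- function(G, F_) {
  p <- ncol(G)
  mass <- vapply(seq_len(p),
                 function(k) sum(G[, k] %o% F_[k, ]), numeric(1))
  tot <- sum(mass)
  if (tot <= 0) stop("all-zero reconstruction; factor shares undefined")
  colsum <- colSums(F_)
  pp <- sweep(F_, 2, ifelse(colsum > 0, colsum, NA_real_), "/") * 100
  list(factor_percent = 100 * mass / tot, profile_percent = pp)
}

#' Factor contribution and profile shares
#'
#' `factor_percent[k]` is the share (in %) of the total reconstructed
#' mass `sum(G %*% F)` attributed to factor k; shares sum to 100.
#' `profile_percent[k, j]` is analyte j's share across factors,
#' `100 * F[k, j] / sum_k F[k, j]`; each column sums to 100.
#'
#' @param sol a fitted [pmf()] object.
#' @return list with `factor_percent` and `profile_percent`.
#' @export
factor_summaries <- function(sol) {
  stopifnot(inherits(sol, "pmf"))
  factor_summaries_impl(sol$G, sol$F)
}

#' Match recovered factor profiles to a reference
#'
#' Exhaustive search over row permutations (p <= 8) for the alignment of
#' `F_hat` to `F_true` maximizing mean cosine similarity; rows are
#' unit-normalized first, so the match is scale-invariant.
#'
#' @param F_hat p x m recovered profile matrix.
#' @param F_true p x m reference profile matrix.
#' @return list with `permutation` (row k of `F_true` matches row
#'   `permutation[k]` of `F_hat`), `mean_cosine`, and per-factor
#'   `cosines`.
#' @export
match_factors <- function(F_hat, F_true) {
  F_hat <- as.matrix(F_hat); F_true <- as.matrix(F_true)
  stopifnot(identical(dim(F_hat), dim(F_true)))
  p <- nrow(F_hat)
  if (p > 8)
    stop("exhaustive matching supports p <= 8; use a greedy heuristic ",
         "for larger p")
  unit <- function(M) {
    nrm <- sqrt(rowSums(M^2))
    sweep(M, 1, ifelse(nrm > 0, nrm, 1), "/")
  }
  C <- unit(F_true) %*% t(unit(F_hat))   # C[a, b] = cos(true a, hat b)
  perms <- all_perms(p)
  scores <- vapply(perms, function(pr)
    mean(C[cbind(seq_len(p), pr)]), numeric(1))
  best <- which.max(scores)
  pr <- perms[[best]]
  list(permutation = pr, mean_cosine = scores[best],
       cosines = C[cbind(seq_len(p), pr)])
}

all_perms <- function(p) {
  if (p == 1) return(list(1L))
  sub <- all_perms(p - 1L)
  out <- list()
  for (s in sub) for (pos in seq_len(p)) {
    v <- integer(p)
    v[pos] <- p
    v[-pos] <- s
    out[[length(out) + 1L]] <- v
  }
  out
}

#' Scan candidate factor counts
#'
#' Fits the factorization over a range of `p` and reports `Q/Q_expected`
#' (near 1 when the uncertainty model matches the residual noise) to
#' assist the choice of the number of sources.
#'
#' @param x,u,... as in [pmf()].
#' @param p_range integer vector of candidate factor counts.
#' @return data frame: `p`, `Q`, `q_expected`, `q_ratio`, `converged`.
#' @export
pmf_scan_p <- function(x, p_range, u = NULL, ...) {
  rows <- lapply(p_range, function(p) {
    fit <- pmf(x, p = p, u = u, ...)
    data.frame(p = p, Q = fit$Q, q_expected = fit$q_expected,
               q_ratio = fit$Q / fit$q_expected,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("Uncertainty-weighted PMF: %d samples x %d analytes, p = %d\n",
              nrow(x$G), ncol(x$F), x$p))
  cat(sprintf("  Q = %.6g (Q/Q_expected = %.3g), %s after %d iterations (start %d of %d)\n",
              x$Q, x$Q / x$q_expected,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$start_index, x$n_starts))
  cat("  factor shares (%):",
      paste(sprintf("%.1f", x$factor_percent), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pmf <- function(object, ...) {
  structure(list(
    p = object$p, Q = object$Q, q_expected = object$q_expected,
    q_ratio = object$Q / object$q_expected,
    converged = object$converged,
    factor_percent = object$factor_percent,
    profile_percent = object$profile_percent,
    scaled_residual_range = range(object$E / object$u)
  ), class = "summary.pmf")
}

#' @export
print.summary.pmf <- function(x, ...) {
  cat(sprintf("PMF solution with %d factors\n", x$p))
  cat(sprintf("  Q = %.6g, Q_expected = %g, ratio = %.3g, converged = %s\n",
              x$Q, x$q_expected, x$q_ratio, x$converged))
  cat(sprintf("  scaled residuals in [%.3g, %.3g]\n",
              x$scaled_residual_range[1], x$scaled_residual_range[2]))
  cat("Factor shares of reconstructed mass (%):\n")
  print(round(x$factor_percent, 2))
  cat("Profile shares per analyte (%, columns sum to 100):\n")
  print(round(x$profile_percent, 1))
  invisible(x)
}

#' @export
coef.pmf <- function(object, which = c("profiles", "contributions"), ...) {
  which <- match.arg(which)
  if (which == "profiles") object$F else object$G
}

#' @export
fitted.pmf <- function(object, ...) object$G %*% object$F

#' @export
residuals.pmf <- function(object, scaled = FALSE, ...) {
  if (scaled) object$E / object$u else object$E
}

#' Predict factor contributions for new samples
#'
#' Holds the fitted profiles F fixed and solves the non-negative
#' weighted least-squares problem for each new sample's contributions.
#'
#' @param object a fitted [pmf()] object.
#' @param newdata matrix of concentrations (columns as in the fit), or a
#'   [conc_table()]; defaults to the training data.
#' @param newu matching uncertainty matrix; built from the table when
#'   `newdata` is a [conc_table()].
#' @param ... unused.
#' @return Non-negative contribution matrix with one row per new sample.
#' @export
predict.pmf <- function(object, newdata = NULL, newu = NULL, ...) {
  if (is.null(newdata)) return(object$G)
  if (inherits(newdata, "conc_table")) {
    newdata <- substitute_censored(newdata)
    if (is.null(newu)) newu <- build_uncertainty(newdata)
    newdata <- newdata$conc
  }
  X <- as.matrix(newdata)
  if (is.null(newu)) stop("supply uncertainties 'newu' with matrix input")
  W <- 1 / as.matrix(newu)^2
  stopifnot(ncol(X) == ncol(object$F))
  G <- matrix(1, nrow(X), object$p)
  F_ <- object$F
  for (it in 1:500) {
    G_old <- G
    R <- X - G %*% F_
    for (k in seq_len(object$p)) {
      fk <- F_[k, ]
      num <- (W * R) %*% fk + G[, k] * (W %*% (fk^2))
      den <- W %*% (fk^2)
      gk <- ifelse(den > 0, pmax(0, num / den), G[, k])
      R <- R - (gk - G[, k]) %*% t(fk)
      G[, k] <- gk
    }
    if (max(abs(G - G_old)) < 1e-12 * max(1, max(abs(G)))) break
  }
  dimnames(G) <- list(rownames(X), rownames(F_))
  G
}

#' Plot a PMF solution
#'
#' Stacked-bar view of `profile_percent` (per-analyte share across
#' factors) or of per-sample factor contributions.
#'
#' @param x a fitted [pmf()] object.
#' @param which `"profiles"` or `"contributions"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.pmf <- function(x, which = c("profiles", "contributions"), ...) {
  which <- match.arg(which)
  if (which == "profiles") {
    graphics::barplot(x$profile_percent, legend.text = rownames(x$F),
                      ylab = "share of analyte (%)", las = 2, ...)
  } else {
    graphics::barplot(t(x$G), legend.text = rownames(x$F),
                      ylab = "factor contribution (G)", las = 2, ...)
  }
  invisible(x)
}
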