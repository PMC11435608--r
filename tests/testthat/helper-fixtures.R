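# shared tiny fixtures, built in code

tiny_config <- function() {
  analyte_config(c("Fe", "Mn", "Hg"),
                 mdl = c(10, 1, 0.04),
                 error_fraction = c(0.1, 0.1, 0.15),
                 drinking_limit = c(300, 100, 1))
}

tiny_table <- function() {
  X <- rbind(c(350, 20, 0.5),
             c(120, 50, 0.04),
             c(80, 110, 0.2))
  colnames(X) <- c("Fe", "Mn", "Hg")
  cens <- matrix(FALSE, 3, 3)
  cens[2, 3] <- TRUE
  conc_table(X, tiny_config(), censored = cens)
}

# brute-force Q minimum over the rank-1 non-negative cone: dense grid
# over unit profile directions in the positive octant (m = 3), optimal
# contributions in closed form per direction, refined by zooming the
# grid around the running argmin
rank1_grid_q <- function(X, U, n_theta = 400, zooms = 4) {
  W <- 1 / U^2
  qconst <- sum(W * X^2)
  eval_grid <- function(th, ph) {
    grid <- expand.grid(th = th, ph = ph)
    Fg <- cbind(sin(grid$th) * cos(grid$ph),
                sin(grid$th) * sin(grid$ph),
                cos(grid$th))                    # K x 3 unit profiles
    num <- (W * X) %*% t(Fg)                     # n x K
    den <- W %*% t(Fg^2)
    Gopt <- pmax(num / den, 0)
    # Q(f) = const - 2 sum_i g* num + sum_i g*^2 den, with g* >= 0
    qk <- qconst - colSums(2 * Gopt * num - Gopt^2 * den)
    k <- which.min(qk)
    list(q = qk[k], th = grid$th[k], ph = grid$ph[k])
  }
  lo <- c(0, 0); hi <- c(pi / 2, pi / 2)
  best <- NULL
  for (z in seq_len(zooms)) {
    th <- seq(lo[1], hi[1], length.out = n_theta)
    ph <- seq(lo[2], hi[2], length.out = n_theta)
    best <- eval_grid(th, ph)
    step <- c(th[2] - th[1], ph[2] - ph[1])
    lo <- pmax(c(best$th, best$ph) - 2 * step, 0)
    hi <- pmin(c(best$th, best$ph) + 2 * step, pi / 2)
  }
  best$q
}
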