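#' Configuration for a per-transition hazard model
#'
#' The covariate effect is \eqn{g(x, t)} entering a Cox-type cause-specific
#' hazard \eqn{\lambda_0(t) \exp g(x, t)}. Its architecture is a linear term
#' plus (optionally) a small tanh hidden layer added as a residual, and
#' (optionally) piecewise time-bin interaction offsets giving
#' non-proportional effects. With `hidden_width = 0` and
#' `time_interactions = FALSE` the model is exactly a linear Cox predictor.
#'
#' @param time_interactions logical; per-time-bin interaction offsets.
#' @param n_time_bins number of time bins per phase clock (default 4); bins
#'   are event-time quantiles of the transition being fitted.
#' @param hidden_width hidden layer width (default 0 = disabled; 16 is the
#'   flexible default used by the full model).
#' @param l2 ridge penalty on all weights (default 1e-4).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param maxit,reltol BFGS control.
#' @param init_sd standard deviation of the seeded hidden-weight
#'   initialization.
#' @param seed integer seed controlling initialization (fits are
#'   deterministic given the seed).
#' @return list of class `coxnp_config`.
#' @export
coxnp_config <- function(time_interactions = FALSE, n_time_bins = 4L,
                         hidden_width = 0L, l2 = 1e-4,
                         ties = c("efron", "breslow"),
                         maxit = 300L, reltol = 1e-10,
                         init_sd = 0.1, seed = 1L) {
  structure(list(time_interactions = time_interactions,
                 n_time_bins = if (time_interactions) as.integer(n_time_bins) else 1L,
                 hidden_width = as.integer(hidden_width),
                 l2 = l2, ties = match.arg(ties),
                 maxit = maxit, reltol = reltol,
                 init_sd = init_sd, seed = as.integer(seed)),
            class = "coxnp_config")
}

# risk-set / death-set index structure shared by likelihood and baseline
.risk_structure <- function(start, stop, status) {
  ev <- sort(unique(stop[status == 1]))
  list(
    times = ev,
    deaths = lapply(ev, function(t) which(stop == t & status == 1)),
    risks = lapply(ev, function(t) which(start < t & stop >= t))
  )
}

# Efron/Breslow partial log-likelihood and d(PLL)/dg for g given as an
# n x B matrix (one column per time bin). Returns list(value, U).
.pll_engine <- function(G, rs, event_bins, ties, want_grad = TRUE) {
  n <- nrow(G)
  B <- ncol(G)
  U <- if (want_grad) matrix(0, n, B) else NULL
  val <- 0
  for (e in seq_along(rs$times)) {
    b <- event_bins[e]
    R <- rs$risks[[e]]
    D <- rs$deaths[[e]]
    if (!length(R)) stop("empty risk set at event time ", rs$times[e])
    gR <- G[R, b]
    m <- max(gR)
    w <- exp(gR - m)
    SR <- sum(w)
    d <- length(D)
    gD <- G[D, b]
    wD <- exp(gD - m)
    if (ties == "efron" && d > 1L) {
      SD <- sum(wD)
      l <- seq_len(d) - 1
      den <- SR - (l / d) * SD
      val <- val + sum(gD) - sum(m + log(den))
      if (want_grad) {
        s1 <- sum(1 / den)
        s2 <- sum((l / d) / den)
        U[R, b] <- U[R, b] - w * s1
        U[D, b] <- U[D, b] + 1 + wD * s2
      }
    } else {
      val <- val + sum(gD) - d * (m + log(SR))
      if (want_grad) {
        U[R, b] <- U[R, b] - w * (d / SR)
        U[D, b] <- U[D, b] + 1
      }
    }
  }
  list(value = val, U = U)
}

.par_template <- function(p, B, W, init_sd, seed) {
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  list(beta = rep(0, p),
       gamma = if (B > 1L) matrix(0, p, B - 1L) else NULL,
       W1 = if (W > 0L) matrix(stats::rnorm(W * p, 0, init_sd), W, p) else NULL,
       b1 = if (W > 0L) rep(0, W) else NULL,
       w2 = if (W > 0L) rep(0, W) else NULL,
       dW2 = if (W > 0L && B > 1L) matrix(0, W, B - 1L) else NULL)
}

.pack <- function(par) unlist(par, use.names = FALSE)

.unpack <- function(theta, p, B, W) {
  out <- list(beta = theta[seq_len(p)])
  i <- p
  if (B > 1L) {
    out$gamma <- matrix(theta[i + seq_len(p * (B - 1L))], p, B - 1L)
    i <- i + p * (B - 1L)
  }
  if (W > 0L) {
    out$W1 <- matrix(theta[i + seq_len(W * p)], W, p); i <- i + W * p
    out$b1 <- theta[i + seq_len(W)]; i <- i + W
    out$w2 <- theta[i + seq_len(W)]; i <- i + W
    if (B > 1L) out$dW2 <- matrix(theta[i + seq_len(W * (B - 1L))], W, B - 1L)
  }
  out
}

# n x B matrix of g(x, bin) for parameters `par`
.g_matrix <- function(par, X, B) {
  n <- nrow(X)
  lin <- drop(X %*% par$beta)
  G <- matrix(lin, n, B)
  if (!is.null(par$gamma))
    G[, -1L] <- G[, -1L] + X %*% par$gamma
  if (!is.null(par$W1)) {
    H <- tanh(sweep(X %*% t(par$W1), 2L, par$b1, `+`))
    G <- G + matrix(drop(H %*% par$w2), n, B)
    if (!is.null(par$dW2)) G[, -1L] <- G[, -1L] + H %*% par$dW2
    attr(G, "H") <- H
  }
  G
}

.param_grad <- function(par, X, U, H) {
  g <- list(beta = drop(crossprod(X, rowSums(U))))
  if (!is.null(par$gamma))
    g$gamma <- crossprod(X, U[, -1L, drop = FALSE])
  if (!is.null(par$W1)) {
    Wd <- nrow(par$W1)
    B <- ncol(U)
    g$w2 <- drop(crossprod(H, rowSums(U)))
    if (!is.null(par$dW2)) g$dW2 <- crossprod(H, U[, -1L, drop = FALSE])
    # back-prop through tanh pre-activations
    V <- matrix(rep(par$w2, B), B, Wd, byrow = TRUE)
    if (!is.null(par$dW2)) V[-1L, ] <- V[-1L, ] + t(par$dW2)
    Delta <- (U %*% V) * (1 - H^2)
    g$W1 <- crossprod(Delta, X)
    g$b1 <- colSums(Delta)
  }
  g[names(par)[!vapply(par, is.null, TRUE)]]
}

#' Cox partial log-likelihood for counting-process data
#'
#' Evaluates the cause-specific Cox partial log-likelihood for given linear
#' predictor values, with Efron or Breslow handling of tied event times and
#' delayed-entry (start, stop] risk sets.
#'
#' @param g numeric vector of per-row log relative hazards.
#' @param start,stop interval endpoints on the transition clock.
#' @param status 1 for the transition event, 0 for censoring/competing exit.
#' @param ties `"efron"` or `"breslow"`.
#' @return the partial log-likelihood (0 when there are no events).
#' @export
cox_partial_loglik <- function(g, start, stop, status,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!sum(status)) return(0)
  rs <- .risk_structure(start, stop, status)
  G <- matrix(g, length(g), 1L)
  .pll_engine(G, rs, rep(1L, length(rs$times)), ties, want_grad = FALSE)$value
}

#' Fit one transition hazard model
#'
#' Maximizes the (penalized) partial likelihood by BFGS with analytic
#' gradients, then stores the Efron/Breslow baseline cumulative-hazard
#' increments at the fitted parameters. A transition with zero events yields a
#' degenerate model (hazard identically zero) with a warning.
#'
#' @param X numeric covariate matrix (rows align with `data`).
#' @param data data.frame with `start`, `stop`, `status` on the transition's
#'   phase clock.
#' @param config a [coxnp_config()].
#' @return object of class `coxnp_fit` with elements `par`, `breaks`,
#'   `baseline` (time, dH0, bin), `loglik`, `loglik0`, `n_events`,
#'   `coefnames`, `config`, `degenerate`.
#' @export
coxnp_fit <- function(X, data, config = coxnp_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(data))
  p <- ncol(X)
  B <- config$n_time_bins
  W <- config$hidden_width
  n_events <- sum(data$status)
  if (n_events == 0L) {
    warning("transition has zero events; model degenerate (hazard 0)")
    return(structure(list(par = .par_template(p, B, W, config$init_sd, config$seed),
                          breaks = numeric(0),
                          baseline = data.frame(time = numeric(0),
                                                dH0 = numeric(0), bin = integer(0)),
                          loglik = 0, loglik0 = 0, n_events = 0L,
                          coefnames = colnames(X), config = config,
                          degenerate = TRUE),
                     class = "coxnp_fit"))
  }
  rs <- .risk_structure(data$start, data$stop, data$status)
  if (B > 1L) {
    breaks <- unique(stats::quantile(rs$times, probs = seq(0, 1, length.out = B + 1L),
                                     names = FALSE, type = 1L))
    breaks <- breaks[-c(1L, length(breaks))]
  } else breaks <- numeric(0)
  event_bins <- findInterval(rs$times, breaks) + 1L
  B_eff <- B

  par0 <- .par_template(p, B_eff, W, config$init_sd, config$seed)
  theta0 <- .pack(par0)
  scale <- n_events

  obj <- function(theta) {
    par <- .unpack(theta, p, B_eff, W)
    G <- .g_matrix(par, X, B_eff)
    r <- .pll_engine(G, rs, event_bins, config$ties, want_grad = FALSE)
    -r$value / scale + config$l2 * sum(theta^2)
  }
  grd <- function(theta) {
    par <- .unpack(theta, p, B_eff, W)
    G <- .g_matrix(par, X, B_eff)
    r <- .pll_engine(G, rs, event_bins, config$ties, want_grad = TRUE)
    gp <- .param_grad(par, X, r$U, attr(G, "H"))
    -.pack(gp) / scale + 2 * config$l2 * theta
  }
  opt <- stats::optim(theta0, obj, grd, method = "BFGS",
                      control = list(maxit = config$maxit,
                                     reltol = config$reltol))
  par <- .unpack(opt$par, p, B_eff, W)
  G <- .g_matrix(par, X, B_eff)
  loglik <- .pll_engine(G, rs, event_bins, config$ties, FALSE)$value
  G0 <- .g_matrix(par0, X, B_eff)
  loglik0 <- .pll_engine(G0, rs, event_bins, config$ties, FALSE)$value

  # baseline cumulative-hazard increments at fitted parameters
  dH0 <- numeric(length(rs$times))
  for (e in seq_along(rs$times)) {
    b <- event_bins[e]
    R <- rs$risks[[e]]
    D <- rs$deaths[[e]]
    w <- exp(G[R, b])
    SR <- sum(w)
    d <- length(D)
    if (config$ties == "efron" && d > 1L) {
      SD <- sum(exp(G[D, b]))
      l <- seq_len(d) - 1
      dH0[e] <- sum(1 / (SR - (l / d) * SD))
    } else dH0[e] <- d / SR
  }
  structure(list(par = par, breaks = breaks,
                 baseline = data.frame(time = rs$times, dH0 = dH0,
                                       bin = event_bins),
                 loglik = loglik, loglik0 = loglik0,
                 n_events = n_events, coefnames = colnames(X),
                 config = config, degenerate = FALSE),
            class = "coxnp_fit")
}

#' @export
print.coxnp_fit <- function(x, ...) {
  cat("coxnp_fit:", length(x$par$beta), "covariates,", x$n_events, "events",
      if (x$degenerate) "(degenerate)" else "",
      "\n  bins:", length(x$breaks) + 1L,
      " hidden width:", x$config$hidden_width,
      " loglik:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Linear-predictor matrix for new data
#' @param object fitted `coxnp_fit`.
#' @param newdata covariate matrix with the training column layout.
#' @param ... unused.
#' @return n x B matrix of g(x, bin) values.
#' @export
predict.coxnp_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  G <- .g_matrix(object$par, X, length(object$breaks) + 1L)
  attr(G, "H") <- NULL
  G
}

#' Coefficients of the linear part
#' @param object a `coxnp_fit`.
#' @param ... unused.
#' @export
coef.coxnp_fit <- function(object, ...)
  stats::setNames(object$par$beta, object$coefnames)

# per-grid-step expected hazard increments for new covariates
# returns a T x n matrix; grid has T+1 points
.edge_hazard_increments <- function(fit, X, grid) {
  Tn <- length(grid) - 1L
  n <- nrow(X)
  if (fit$degenerate || !nrow(fit$baseline)) return(matrix(0, Tn, n))
  bl <- fit$baseline
  keep <- bl$time > grid[1L] & bl$time <= grid[length(grid)]
  bl <- bl[keep, , drop = FALSE]
  B <- length(fit$breaks) + 1L
  Wm <- matrix(0, Tn, B)
  if (nrow(bl)) {
    step <- findInterval(bl$time, grid, left.open = TRUE)
    step[step < 1L] <- 1L
    for (i in seq_len(nrow(bl)))
      Wm[step[i], bl$bin[i]] <- Wm[step[i], bl$bin[i]] + bl$dH0[i]
  }
  G <- predict(fit, X)
  Wm %*% t(exp(G))
}
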