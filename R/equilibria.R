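# Equilibria of the model at constant overdose death rate: disorder-free
# and endemic points, stability, polynomial reductions, saddle-node folds
# and stability-region maps.

# A constant death rate for equilibrium analysis: either explicit or read
# off a constant schedule.
.constant_delta <- function(params, delta = NULL) {
  if (!is.null(delta)) {
    stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
    return(delta)
  }
  p <- params$delta$pieces
  if (nrow(p) == 1L && p[1, "slope"] == 0) return(unname(p[1, "intercept"]))
  stop("parameter set has a time-varying delta; pass an explicit constant `delta`")
}

# Reconstruct (S, T, R, N) from a candidate endemic I at the steady-state
# population N = (Lambda - delta I)/mu, and the residual of the reduced
# I-equation. T solves its quadratic balance (unique nonnegative root).
.ee_components <- function(I, params, dlt) {
  with(params, {
    N <- (Lambda - dlt * I) / mu
    if (N <= 0) return(NULL)
    S <- Lambda * N / (beta * I + mu * N)
    d <- alpha1 + mu + alpha2 * I / N
    A <- (kappa + rho + mu) * epsilon
    B <- (kappa + rho + mu) - I * eta2 * rho / (N * d)
    C <- -I * (eta1 + eta3 * S / N + eta2 * omega * I / (N * d))
    T_ <- if (A > 0) {
      (-B + sqrt(B * B - 4 * A * C)) / (2 * A)
    } else {
      if (B <= 0) return(NULL)
      -C / B
    }
    R <- (omega * I + rho * T_) / d
    resid <- beta * S * I / N + alpha1 * R + alpha2 * R * I / N -
      (rho + mu) * T_ - (omega + mu + dlt) * I
    list(S = S, I = I, T = T_, R = R, N = N, resid = resid)
  })
}

#' Scalar endemic-equilibrium residual
#'
#' For a candidate endemic level `I`, eliminates S, T and R through the
#' steady-state relations (with the total population at its limit
#' `N = (Lambda - delta I)/mu`) and returns the residual of the remaining
#' I-balance. Endemic equilibria are exactly the positive roots.
#'
#' @param I candidate disorder-class size (persons), vectorized
#' @param params an [ioud_params()] object
#' @param delta constant overdose death rate (1/year); defaults to the
#'   schedule's constant value
#' @return residual (persons/year); NA where the reduction is undefined
#' @export
equilibrium_residual <- function(I, params, delta = NULL) {
  dlt <- .constant_delta(params, delta)
  vapply(I, function(Ii) {
    cc <- .ee_components(Ii, params, dlt)
    if (is.null(cc)) NA_real_ else cc$resid
  }, 0)
}

#' Jacobian of the model at a state
#'
#' Central finite differences of the four-compartment right-hand side at
#' fixed delta.
#'
#' @inheritParams equilibrium_residual
#' @param state numeric (S, I, T, R)
#' @return 4x4 Jacobian matrix (1/year)
#' @export
ioud_jacobian <- function(state, params, delta = NULL) {
  dlt <- .constant_delta(params, delta)
  f <- function(y) .ioud_rhs_raw(y, params, dlt)
  J <- matrix(0, 4, 4, dimnames = list(c("S", "I", "T", "R"), c("S", "I", "T", "R")))
  for (j in 1:4) {
    h <- max(1e-6, 1e-7 * abs(state[j]))
    yp <- state; yp[j] <- yp[j] + h
    ym <- state; ym[j] <- ym[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

.classify <- function(state, params, dlt, tol = 1e-8) {
  ev <- eigen(ioud_jacobian(state, params, delta = dlt), only.values = TRUE)$values
  lead <- max(Re(ev))
  stab <- if (lead < -tol) "stable" else if (lead > tol) "unstable" else "nonhyperbolic"
  list(stability = stab, leading_eigenvalue_real_part = lead)
}

.equilibrium_point <- function(state, params, dlt) {
  cl <- .classify(state, params, dlt)
  structure(list(state = stats::setNames(as.numeric(state), c("S", "I", "T", "R")),
                 stability = cl$stability,
                 leading_eigenvalue_real_part = cl$leading_eigenvalue_real_part,
                 delta = dlt),
            class = "ioud_equilibrium")
}

#' @export
print.ioud_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium (%s, leading Re(eig) = %.3g):\n", x$stability,
              x$leading_eigenvalue_real_part))
  print(round(x$state, 4))
  invisible(x)
}

#' Disorder-free equilibrium
#'
#' The steady state `(Lambda/mu, 0, 0, 0)`; stability is established from
#' the Jacobian eigenvalues (locally stable exactly when R0 < 1).
#'
#' @inheritParams equilibrium_residual
#' @return an `ioud_equilibrium`
#' @export
disorder_free_equilibrium <- function(params, delta = NULL) {
  dlt <- .constant_delta(params, delta)
  .equilibrium_point(c(params$Lambda / params$mu, 0, 0, 0), params, dlt)
}

# admissible I-range for endemic roots
.ee_imax <- function(params, dlt) {
  if (dlt > 0) params$Lambda / dlt else 10 * params$Lambda / params$mu
}

.ee_roots <- function(params, dlt, grid_n = 1500) {
  Imax <- .ee_imax(params, dlt)
  grid <- unique(sort(c(Imax * exp(seq(log(1e-9), log(1 - 1e-9), length.out = grid_n)),
                        seq(Imax * 1e-6, Imax * (1 - 1e-9), length.out = grid_n %/% 3))))
  h <- vapply(grid, function(I) {
    cc <- .ee_components(I, params, dlt)
    if (is.null(cc)) NA_real_ else cc$resid / I
  }, 0)
  ok <- which(!is.na(h[-length(h)]) & !is.na(h[-1]) &
                sign(h[-length(h)]) * sign(h[-1]) < 0)
  roots <- numeric(0)
  for (i in ok) {
    r <- try(stats::uniroot(function(I) {
      cc <- .ee_components(I, params, dlt)
      if (is.null(cc)) return(NA_real_)
      cc$resid / I
    }, c(grid[i], grid[i + 1]), tol = 1e-12 * Imax)$root, silent = TRUE)
    if (!inherits(r, "try-error")) roots <- c(roots, r)
  }
  if (length(roots) > 1) {
    roots <- sort(roots)
    roots <- roots[c(TRUE, diff(roots) > 1e-7 * Imax)]
  }
  roots
}

#' Endemic equilibria
#'
#' Finds all biologically admissible endemic equilibria (every compartment
#' nonnegative, `I < Lambda/delta`) by scanning the scalar reduced
#' equation for sign changes and polishing each root, reconstructing the
#' full state, and classifying stability via the Jacobian of the full
#' four-compartment system.
#'
#' @inheritParams equilibrium_residual
#' @param classify compute stability (default TRUE; set FALSE for fast
#'   existence counts)
#' @param grid_n scan resolution
#' @return list of `ioud_equilibrium` (possibly empty); with
#'   `classify = FALSE`, a numeric vector of endemic I values
#' @export
endemic_equilibria <- function(params, delta = NULL, classify = TRUE,
                               grid_n = 1500) {
  dlt <- .constant_delta(params, delta)
  roots <- .ee_roots(params, dlt, grid_n = grid_n)
  keep <- vapply(roots, function(r) {
    cc <- .ee_components(r, params, dlt)
    !is.null(cc) && all(c(cc$S, cc$T, cc$R) >= 0)
  }, TRUE)
  roots <- roots[keep]
  if (!classify) return(roots)
  lapply(roots, function(r) {
    cc <- .ee_components(r, params, dlt)
    .equilibrium_point(c(cc$S, cc$I, cc$T, cc$R), params, dlt)
  })
}

# Newton iteration on the full 4-d right-hand side from a given start;
# independent multistart oracle for the reduced-equation root finder.
.newton_equilibrium <- function(start, params, dlt, maxit = 200) {
  y <- as.numeric(start)
  for (k in seq_len(maxit)) {
    fy <- .ioud_rhs_raw(y, params, dlt)
    if (max(abs(fy)) < 1e-10) return(y)
    J <- ioud_jacobian(y, params, delta = dlt)
    step <- try(solve(J, fy), silent = TRUE)
    if (inherits(step, "try-error")) return(NULL)
    y <- y - step
    if (any(!is.finite(y)) || sum(y) <= 0) return(NULL)
  }
  NULL
}

#' Coefficients of the no-saturation cubic reduction
#'
#' With `epsilon = eta2 = 0` the endemic condition reduces to
#' `I [a I^2 + b I + c] = 0` where `a`, `b`, `c` are the printed
#' polynomial expressions in the rates and the steady population `N*`
#' (`a` is N*-free, `b` is linear and `c` quadratic in `N*`). Eliminating
#' `N* = (Lambda - delta I)/mu` turns the bracket into an effective
#' quadratic in `I` whose positive roots are the candidate endemic levels.
#'
#' @inheritParams equilibrium_residual
#' @param Nstar population scale at which `b_coeff` and `c` are reported
#'   (default `Lambda/mu`); signs do not depend on it
#' @return list with `a`, `b_coeff`, `c` (at `Nstar`), the factor `Kb`
#'   (`b = -mu N* Kb`), `Kc` (`c = mu N*^2 Kc (R0 - 1)`), `R0`, and
#'   `quadratic = c(A0, A1, A2)`, the effective quadratic after
#'   eliminating `N*`
#' @export
cubic_coefficients_no_saturation <- function(params, delta = NULL, Nstar = NULL) {
  if (params$epsilon != 0 || params$eta2 != 0)
    stop("the cubic reduction requires epsilon = 0 and eta2 = 0")
  dlt <- .constant_delta(params, delta)
  if (is.null(Nstar)) Nstar <- params$Lambda / params$mu
  R0 <- r0_closed_form(params, delta = dlt)
  with(params, {
    a <- -mu * alpha2 * (beta * eta1 + beta * kappa + beta * mu + beta * rho +
                           dlt * eta3)
    Kb <- alpha1 * beta * eta1 + alpha1 * beta * kappa + alpha1 * beta * mu +
      alpha1 * beta * rho + alpha1 * dlt * eta3 - alpha2 * beta * kappa -
      alpha2 * beta * mu - alpha2 * beta * rho + alpha2 * dlt * kappa +
      alpha2 * dlt * mu + alpha2 * dlt * rho + alpha2 * eta1 * mu +
      alpha2 * eta3 * mu + alpha2 * kappa * mu + alpha2 * mu^2 +
      alpha2 * mu * rho + beta * eta1 * mu + beta * eta1 * rho +
      beta * kappa * mu + beta * kappa * omega + beta * mu^2 +
      beta * mu * omega + beta * mu * rho + beta * omega * rho +
      dlt * eta3 * mu + dlt * eta3 * rho
    Kc <- alpha1 * dlt * kappa + alpha1 * dlt * mu + alpha1 * dlt * rho +
      alpha1 * eta1 * mu + alpha1 * eta3 * mu + alpha1 * kappa * mu +
      alpha1 * mu^2 + alpha1 * mu * rho + dlt * kappa * mu + dlt * mu^2 +
      dlt * mu * rho + eta1 * mu^2 + eta1 * mu * rho + eta3 * mu^2 +
      eta3 * mu * rho + kappa * mu^2 + kappa * mu * omega + mu^3 +
      mu^2 * omega + mu^2 * rho + mu * omega * rho
    n0 <- Lambda / mu
    n1 <- -dlt / mu
    A2 <- a + (-mu * Kb) * n1 + mu * Kc * (R0 - 1) * n1^2
    A1 <- (-mu * Kb) * n0 + 2 * mu * Kc * (R0 - 1) * n0 * n1
    A0 <- mu * Kc * (R0 - 1) * n0^2
    list(a = a, b_coeff = -mu * Nstar * Kb, c = mu * Nstar^2 * Kc * (R0 - 1),
         Kb = Kb, Kc = Kc, R0 = R0, quadratic = c(A0 = A0, A1 = A1, A2 = A2))
  })
}

# two positive real roots of the effective quadratic?
.quad_two_positive <- function(q) {
  A0 <- q[["A0"]]; A1 <- q[["A1"]]; A2 <- q[["A2"]]
  if (A2 == 0) return(FALSE)
  disc <- A1^2 - 4 * A0 * A2
  if (disc < 0) return(FALSE)
  r <- (-A1 + c(-1, 1) * sqrt(disc)) / (2 * A2)
  all(r > 0)
}

#' Critical contact-driven relapse rate for a backward bifurcation
#'
#' In the no-saturation model (`epsilon = eta2 = 0`) with R0 < 1, finds by
#' bisection the smallest `alpha2` at which the quadratic factor of the
#' cubic reduction acquires two positive real roots (the backward
#' bifurcation threshold).
#'
#' @inheritParams equilibrium_residual
#' @param bracket search interval for alpha2 (1/year)
#' @param tol_rel relative bisection tolerance (default 0.1%)
#' @return the critical alpha2 (1/year)
#' @export
critical_alpha2 <- function(params, delta = NULL, bracket = c(0, 1e5),
                            tol_rel = 1e-3) {
  dlt <- .constant_delta(params, delta)
  if (r0_closed_form(params, delta = dlt) >= 1)
    stop("precondition violated: R0 >= 1 at this delta (backward bifurcation moot)")
  ind <- function(a2) {
    q <- cubic_coefficients_no_saturation(update_params(params, alpha2 = a2),
                                          delta = dlt)$quadratic
    .quad_two_positive(q)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (ind(lo)) stop("two positive roots already at the lower bracket")
  if (!ind(hi)) stop("no backward-bifurcation threshold in the search bracket")
  while ((hi - lo) > tol_rel * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (ind(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# ---- quintic reduction -------------------------------------------------

# polynomial numerator of the eliminated endemic condition, in the scaled
# variable x = I * delta / Lambda; returns ascending coefficients.
.elim_poly <- function(dlt, epsilon, beta, params) {
  bb <- beta; ee <- epsilon # protect the arguments from masking by `with`
  with(params, {
    s <- Lambda / dlt
    nx <- c(Lambda, -Lambda)                    # Lambda - delta s x
    L1 <- c(Lambda, (bb - dlt) * s)             # beta I + mu N
    D_A <- .padd(nx * (alpha1 + mu), c(0, mu * alpha2 * s))
    numA <- .padd(nx * alpha1, c(0, mu * alpha2 * s))
    w1 <- .padd(.padd(.pmul(D_A, L1) * (omega + mu + dlt),
                      .pmul(numA, L1) * (-omega)),
                D_A * (-bb * Lambda))
    w2 <- .padd(numA * rho, D_A * (-(rho + mu)))
    D <- .pmul(D_A, .pmul(.pmul(L1, L1), .pmul(w2, w2)))
    t1 <- .pmul(c(0, s), D) * eta1
    t2 <- .pmul(.pmul(c(0, 0, s^2), .padd(.pmul(L1, w2) * omega, w1 * rho)),
                .pmul(L1, w2)) * (eta2 * mu)
    t3 <- .pmul(c(0, s), .pmul(D_A, .pmul(L1, .pmul(w2, w2)))) * (eta3 * Lambda)
    t4a <- .pmul(c(0, s), .pmul(w1, .pmul(D_A, .pmul(L1, w2)))) * (kappa + rho + mu)
    t4b <- .pmul(c(0, 0, s^2), .pmul(.pmul(w1, w1), D_A)) * (ee * (kappa + rho + mu))
    g <- .padd(.padd(t1, t2), .padd(t3, -.padd(t4a, t4b)))
    list(g = g, D_A = D_A, L1 = L1, w2 = w2, s = s)
  })
}

#' Quintic coefficients of the saturated endemic reduction
#'
#' With saturation the endemic condition reduces to
#' `0 = I [nu6 I^5 + nu5 I^4 + ... + nu2 I + nu1]` once S, T, R and the
#' limiting population are eliminated. The coefficients are obtained by
#' exact polynomial elimination (the shared linear factor in the cleared
#' numerator is divided out); a floating-point interpolation of the same
#' scalar function at Chebyshev nodes provides an independent consistency
#' route (`interp_max_rel_diff`).
#'
#' @param delta,epsilon,beta the three free parameters (others from
#'   `params`)
#' @param params baseline [ioud_params()] supplying the frozen rates
#' @return list with `nu` (named nu1..nu6, ascending powers of I; trailing
#'   entries are exactly 0 when the degree collapses), `nu_scaled` (in the
#'   scaled variable x = I delta / Lambda), `scale` s = Lambda/delta, and
#'   `interp_max_rel_diff`
#' @export
quintic_coefficients <- function(delta, epsilon, beta, params = ioud_params()) {
  stopifnot(delta > 0)
  ep <- .elim_poly(delta, epsilon, beta, params)
  g <- ep$g
  scale <- max(abs(g))
  if (abs(g[1]) > 1e-8 * scale) stop("constant term does not vanish; elimination failed")
  g <- g[-1] # deflate the I = 0 factor
  dv <- .pdivlin(g, ep$D_A[1], ep$D_A[2])
  if (abs(dv$remainder) > 1e-7 * scale)
    stop("shared linear factor does not divide the cleared numerator")
  q <- .pstrip(dv$quotient)
  if (length(q) > 6) stop("unexpected degree ", length(q) - 1, " after reduction")
  nu_scaled <- c(q, numeric(6 - length(q)))
  s <- ep$s
  nu <- nu_scaled / s^(0:5)
  names(nu) <- names(nu_scaled) <- paste0("nu", 1:6)

  # dual route: scalar evaluation + polynomial interpolation at 7 nodes
  nodes <- 0.5 + 0.45 * cos(pi * (2 * (1:7) - 1) / 14)
  vals <- vapply(nodes, function(x) {
    gx <- .peval(ep$g, x)
    gx / (x * .peval(ep$D_A, x))
  }, 0)
  V <- outer(nodes, 0:5, `^`)
  coef_fit <- qr.solve(V, vals)
  denom <- max(abs(nu_scaled))
  interp_diff <- max(abs(coef_fit - nu_scaled)) / denom
  list(nu = nu, nu_scaled = nu_scaled, scale = s,
       interp_max_rel_diff = interp_diff)
}

#' Admissible roots of the quintic reduction
#'
#' Real roots of the quintic factor lying in `(0, Lambda/delta)` whose
#' reconstructed state is biologically admissible (the treatment balance
#' has a unique nonnegative solution, which the root must match).
#'
#' @inheritParams quintic_coefficients
#' @return numeric vector of endemic I values
#' @export
quintic_admissible_roots <- function(delta, epsilon, beta, params = ioud_params()) {
  qc <- quintic_coefficients(delta, epsilon, beta, params)
  co <- .pstrip(qc$nu_scaled)
  if (length(co) < 2) return(numeric(0))
  r <- polyroot(co)
  x <- Re(r[abs(Im(r)) < 1e-8 * (1 + Mod(r))])
  x <- x[x > 0 & x < 1]
  I <- x * qc$scale
  p2 <- update_params(params, epsilon = epsilon, beta = beta)
  keep <- vapply(I, function(Ii) {
    cc <- .ee_components(Ii, p2, delta)
    !is.null(cc) && all(c(cc$S, cc$T, cc$R) >= 0) &&
      abs(cc$resid) < 1e-5 * max(1, Ii)
  }, TRUE)
  sort(I[keep])
}

# ---- saddle-node folds and regions ------------------------------------

.n_endemic <- function(params, dlt, grid_n = 1200) {
  length(endemic_equilibria(params, delta = dlt, classify = FALSE,
                            grid_n = grid_n))
}

.params_at <- function(vary, value, params, dlt) {
  switch(vary,
         delta = list(params = params, dlt = value),
         beta = list(params = update_params(params, beta = value), dlt = dlt),
         epsilon = list(params = update_params(params, epsilon = value), dlt = dlt))
}

#' Saddle-node fold of the endemic branch
#'
#' Sweeps one of (delta, beta, epsilon) over a bracket, locates the
#' parameter value at which the admissible endemic equilibria vanish (the
#' fold, where the stable and unstable branches coalesce), refines the
#' fold point by Newton iteration on the reduced equation and its
#' I-derivative, and reports the effective reproduction number at the
#' fold (computed with the equilibrium's own S*/N*).
#'
#' @param vary which parameter moves: "delta", "beta" or "epsilon"
#' @param params an [ioud_params()] object holding the fixed parameters
#' @param delta the constant death rate when it is not the swept parameter
#' @param bracket sweep interval for the varied parameter; equilibria must
#'   exist at one end and not the other
#' @param n_grid sweep resolution used to bracket the fold
#' @return list with `found`, `parameter` (fold value), `I_star`, `R_eff`,
#'   `state` (full equilibrium at the fold)
#' @export
saddle_node_locus <- function(vary = c("delta", "beta", "epsilon"), params,
                              delta = NULL, bracket, n_grid = 200) {
  vary <- match.arg(vary)
  dlt0 <- if (vary == "delta") NA_real_ else .constant_delta(params, delta)
  count_at <- function(v) {
    pa <- .params_at(vary, v, params, dlt0)
    .n_endemic(pa$params, pa$dlt)
  }
  grid <- seq(bracket[1], bracket[2], length.out = n_grid)
  cnt <- vapply(grid, count_at, 0L)
  drop <- which((cnt[-length(cnt)] > 0) != (cnt[-1] > 0))
  if (length(drop) == 0)
    return(list(found = FALSE, parameter = NA_real_, I_star = NA_real_,
                R_eff = NA_real_, state = NULL))
  i <- drop[length(drop)] # outermost existence boundary
  lo <- grid[i]; hi <- grid[i + 1]
  lo_has <- cnt[i] > 0
  # bisect only until the fold is localized; close to the fold the
  # coalescing roots fall below scan resolution, so precision comes from
  # the Newton refinement below, not from the bisection
  width_tol <- 1e-4 * (bracket[2] - bracket[1])
  while (abs(hi - lo) > width_tol) {
    mid <- (lo + hi) / 2
    mh <- count_at(mid) > 0
    if (mh == lo_has) lo <- mid else hi <- mid
  }
  inside <- if (lo_has) lo else hi
  pa <- .params_at(vary, inside, params, dlt0)
  roots <- endemic_equilibria(pa$params, delta = pa$dlt, classify = FALSE,
                              grid_n = 4000)
  I0 <- if (length(roots) >= 2) {
    d <- diff(roots)
    mean(roots[which.min(d) + 0:1])
  } else if (length(roots) == 1) roots else return(
    list(found = FALSE, parameter = NA_real_, I_star = NA_real_,
         R_eff = NA_real_, state = NULL))

  # Newton refinement of (g = 0, dg/dI = 0) in (I, parameter)
  gfun <- function(I, v) {
    pa <- .params_at(vary, v, params, dlt0)
    cc <- .ee_components(I, pa$params, pa$dlt)
    if (is.null(cc)) NA_real_ else cc$resid
  }
  th <- c(I0, inside)
  for (k in 1:12) {
    hI <- max(1e-6, 1e-6 * abs(th[1])); hv <- max(1e-10, 1e-7 * abs(th[2]))
    g0 <- gfun(th[1], th[2])
    gI <- (gfun(th[1] + hI, th[2]) - gfun(th[1] - hI, th[2])) / (2 * hI)
    F1 <- g0; F2 <- gI
    gII <- (gfun(th[1] + hI, th[2]) - 2 * g0 + gfun(th[1] - hI, th[2])) / hI^2
    gv <- (gfun(th[1], th[2] + hv) - gfun(th[1], th[2] - hv)) / (2 * hv)
    gIv <- ((gfun(th[1] + hI, th[2] + hv) - gfun(th[1] - hI, th[2] + hv)) -
              (gfun(th[1] + hI, th[2] - hv) - gfun(th[1] - hI, th[2] - hv))) /
      (4 * hI * hv)
    J <- matrix(c(gI, gv, gII, gIv), 2, 2, byrow = TRUE)
    step <- try(solve(J, c(F1, F2)), silent = TRUE)
    if (inherits(step, "try-error") || any(!is.finite(step))) break
    thn <- th - step
    if (!is.finite(gfun(thn[1], thn[2]))) break
    th <- thn
    if (max(abs(step) / pmax(abs(th), 1e-8)) < 1e-12) break
  }
  pa <- .params_at(vary, th[2], params, dlt0)
  cc <- .ee_components(th[1], pa$params, pa$dlt)
  reff <- r0_closed_form(pa$params, delta = pa$dlt) * cc$S / cc$N
  list(found = TRUE, parameter = th[2], I_star = th[1], R_eff = reff,
       state = c(S = cc$S, I = cc$I, T = cc$T, R = cc$R))
}

#' Critical saturation coefficient for bi-stability
#'
#' With R0 < 1 at the given (delta, beta), finds by bisection the smallest
#' saturation coefficient epsilon at which admissible endemic equilibria
#' (hence bi-stability with the stable disorder-free state) appear.
#'
#' @param delta constant overdose death rate (1/year)
#' @param beta transmission rate (1/year)
#' @param params baseline parameters for the remaining rates
#' @param bracket search interval for epsilon (1/person)
#' @param tol_rel relative bisection tolerance (default 1%)
#' @return critical epsilon (1/person); NA with attribute
#'   `"above_bracket"` if no fold exists inside the bracket
#' @export
critical_epsilon <- function(delta, beta, params = ioud_params(),
                             bracket = c(0, 1), tol_rel = 0.01) {
  p0 <- update_params(params, beta = beta)
  if (r0_closed_form(p0, delta = delta) >= 1)
    stop("precondition violated: R0 >= 1 at (delta, beta)")
  ind <- function(eps) .n_endemic(update_params(p0, epsilon = eps), delta) >= 1
  lo <- bracket[1]; hi <- bracket[2]
  if (ind(lo)) stop("endemic equilibria already exist at the lower bracket")
  if (!ind(hi)) {
    out <- NA_real_
    attr(out, "above_bracket") <- TRUE
    return(out)
  }
  while ((hi - lo) > tol_rel * max(hi, 1e-12)) {
    mid <- (lo + hi) / 2
    if (ind(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' First year without an endemic equilibrium
#'
#' Walks integer years, evaluating the extrapolated death-rate trend, and
#' returns the first year at which no admissible endemic equilibrium
#' exists (all other parameters fixed).
#'
#' @param fit an `ioud_delta_fit` with positive late-branch slope
#' @param params an [ioud_params()] object
#' @param years candidate years (default 2020:2060)
#' @return the first year with no endemic equilibrium; NA with a warning
#'   if the endemic state persists across the horizon
#' @export
ee_disappearance_year <- function(fit = delta_fit_paper(), params = ioud_params(),
                                  years = 2020:2060) {
  stopifnot(inherits(fit, "ioud_delta_fit"))
  if (fit$m <= 0) stop("late-branch slope must be positive")
  for (Y in years) {
    if (.n_endemic(params, delta_at(fit, Y)) == 0) return(Y)
  }
  warning("endemic equilibrium persists across the search horizon")
  NA_integer_
}

#' Stability-region map
#'
#' Classifies a grid in one of the (delta, epsilon, beta) coordinate
#' planes into `EE` (R0 > 1: endemic state stable, disorder-free state
#' unstable), `BI` (R0 < 1 but admissible endemic equilibria exist:
#' bi-stability) and `DFE` (R0 < 1, no endemic state).
#'
#' @param plane "delta-epsilon", "delta-beta" or "epsilon-beta"
#' @param x_range,y_range ranges of the two plane coordinates (first and
#'   second name of the plane)
#' @param fixed value of the remaining third parameter
#' @param params baseline parameters for the frozen rates
#' @param n grid resolution per axis
#' @return data.frame with the two coordinates, `R0` and `label`
#' @export
stability_regions <- function(plane = c("delta-epsilon", "delta-beta",
                                        "epsilon-beta"),
                              x_range, y_range, fixed, params = ioud_params(),
                              n = 15) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "-")[[1]]
  xs <- seq(x_range[1], x_range[2], length.out = n)
  ys <- seq(y_range[1], y_range[2], length.out = n)
  gr <- expand.grid(x = xs, y = ys)
  third <- setdiff(c("delta", "epsilon", "beta"), ax)
  lab <- character(nrow(gr)); r0v <- numeric(nrow(gr))
  for (i in seq_len(nrow(gr))) {
    v <- stats::setNames(list(gr$x[i], gr$y[i], fixed), c(ax, third))
    p <- update_params(params, beta = v$beta, epsilon = v$epsilon)
    r0v[i] <- r0_closed_form(p, delta = v$delta)
    lab[i] <- if (r0v[i] > 1) "EE"
    else if (.n_endemic(p, v$delta, grid_n = 600) >= 1) "BI"
    else "DFE"
  }
  out <- data.frame(gr$x, gr$y, R0 = r0v, label = lab)
  names(out)[1:2] <- ax
  out
}
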