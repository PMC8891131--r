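# Basic and effective reproduction numbers, by three independent routes.

#' Heuristic multiple-pass basic reproduction number
#'
#' Builds R0 from the mean untreated sojourn in the disorder class and the
#' geometric series over return cycles (disorder -> treatment -> disorder,
#' disorder -> recovered -> disorder, disorder -> treatment -> recovered
#' -> disorder). The saturation coefficient, contact-driven relapse and
#' recovered-contact treatment entry play no role at the disorder-free
#' equilibrium and are absent.
#'
#' @param params an [ioud_params()] object; a constant `delta` is read
#'   from its schedule at `t`
#' @param t time at which a time-varying delta is evaluated (default 0,
#'   irrelevant for constant schedules)
#' @return an `ioud_r0` breakdown: list with `U0` (mean untreated sojourn,
#'   years), `U1`, `W1` (survival fractions to treatment / recovered),
#'   `U2`, `W2` (return fractions), `r1`, `r2`, `r3` (per-cycle return
#'   probabilities) and `R0`
#' @export
r0_heuristic <- function(params, t = 0) {
  stopifnot(inherits(params, "ioud_params"))
  dlt <- param_delta(params, t)
  with(params, {
    denI <- mu + dlt + eta1 + eta3 + omega
    U0 <- 1 / denI
    U1 <- (eta1 + eta3) / denI
    W1 <- omega / denI
    U2 <- kappa / (mu + kappa + rho)
    W2 <- alpha1 / (mu + alpha1)
    r1 <- U1 * U2
    r2 <- W1 * W2
    r3 <- U1 * (rho / (kappa + mu + rho)) * W2
    if (r1 + r2 + r3 >= 1) stop("return probabilities sum to >= 1; geometric series diverges")
    structure(list(U0 = U0, U1 = U1, W1 = W1, U2 = U2, W2 = W2,
                   r1 = r1, r2 = r2, r3 = r3,
                   R0 = beta * U0 / (1 - r1 - r2 - r3)),
              class = "ioud_r0")
  })
}

#' @export
print.ioud_r0 <- function(x, ...) {
  cat(sprintf("R0 = %.6f  (U0 = %.4f yr; r1 = %.4f, r2 = %.4f, r3 = %.4f)\n",
              x$R0, x$U0, x$r1, x$r2, x$r3))
  invisible(x)
}

#' Closed-form basic reproduction number
#'
#' Evaluates the rational closed form
#' `beta (kappa + rho + mu)(alpha1 + mu) / D` with `D` the 21-term
#' denominator polynomial in the rates. `epsilon`, `alpha2` and `eta2` do
#' not appear.
#'
#' @inheritParams r0_heuristic
#' @param delta optional overdose death rate overriding the schedule
#' @return R0 (dimensionless)
#' @export
r0_closed_form <- function(params, t = 0, delta = NULL) {
  stopifnot(inherits(params, "ioud_params"))
  dlt <- if (is.null(delta)) param_delta(params, t) else delta
  with(params, {
    num <- beta * (kappa + rho + mu) * (alpha1 + mu)
    den <- alpha1 * dlt * kappa + alpha1 * dlt * mu + alpha1 * dlt * rho +
      alpha1 * eta1 * mu + alpha1 * eta3 * mu + alpha1 * kappa * mu +
      alpha1 * mu^2 + alpha1 * mu * rho + dlt * kappa * mu + dlt * mu^2 +
      dlt * mu * rho + eta1 * mu^2 + eta1 * mu * rho + eta3 * mu^2 +
      eta3 * mu * rho + kappa * mu^2 + kappa * mu * omega + mu^3 +
      mu^2 * omega + mu^2 * rho + mu * omega * rho
    if (den <= 0) stop("denominator of the closed form is not positive")
    num / den
  })
}

#' Next-generation matrices at the disorder-free equilibrium
#'
#' Infected set (I, T, R); the new-infection matrix F has the single entry
#' `beta * Lambda / (mu * N)` at (I, I), evaluated with the equilibrium
#' population `N = Lambda / mu` so the entry is `beta`.
#'
#' @inheritParams r0_closed_form
#' @return list with matrices `F` and `V`
#' @export
next_generation_matrices <- function(params, t = 0, delta = NULL) {
  stopifnot(inherits(params, "ioud_params"))
  dlt <- if (is.null(delta)) param_delta(params, t) else delta
  with(params, {
    Fm <- matrix(0, 3, 3, dimnames = list(c("I", "T", "R"), c("I", "T", "R")))
    Fm["I", "I"] <- beta # beta*Lambda/(mu*N) at N = Lambda/mu
    # eta3 * Lambda / (mu * N) likewise reduces to eta3
    V <- matrix(c(eta1 + eta3 + omega + mu + dlt, -alpha1, -kappa,
                  -omega, alpha1 + mu, -rho,
                  -eta1 - eta3, 0, kappa + rho + mu),
                3, 3, byrow = TRUE,
                dimnames = list(c("I", "R", "T"), c("I", "R", "T")))
    list(F = Fm, V = V)
  })
}

#' Basic reproduction number via the next-generation matrix
#'
#' Spectral radius of `F V^{-1}`; `F V^{-1}` has exactly one nonzero
#' eigenvalue, which equals the closed form.
#'
#' @inheritParams r0_closed_form
#' @return R0 (dimensionless)
#' @export
r0_next_generation <- function(params, t = 0, delta = NULL) {
  m <- next_generation_matrices(params, t = t, delta = delta)
  K <- m$F %*% solve(m$V)
  max(Mod(eigen(K, only.values = TRUE)$values))
}

#' Effective reproduction number
#'
#' `R_eff = R0 * S / N` with S and N taken from `state`. At the
#' disorder-free equilibrium S = N, so `R_eff = R0`. (An alternative
#' normalization by the initial population N0 is available; on baseline
#' runs the two coincide to plotting accuracy since N varies by < 0.2%.)
#'
#' @inheritParams r0_closed_form
#' @param state numeric (S, I, T, R)
#' @param N0 optional fixed reference population replacing N = sum(state)
#' @return R_eff (dimensionless)
#' @export
effective_reproduction <- function(params, state, t = 0, delta = NULL, N0 = NULL) {
  S <- state[[1]]
  N <- if (is.null(N0)) sum(state[1:4]) else N0
  if (N <= 0) stop("population must be positive")
  r0_closed_form(params, t = t, delta = delta) * S / N
}

#' Overdose death rate at which R0 crosses 1
#'
#' Solves the closed form `R0(delta) = 1` for delta with all other
#' parameters fixed, by root bracketing.
#'
#' @param params an [ioud_params()] object
#' @param interval search bracket for delta (1/year)
#' @return the critical delta (1/year)
#' @export
delta_at_r0_one <- function(params, interval = c(1e-6, 1)) {
  f <- function(d) r0_closed_form(params, delta = d) - 1
  if (f(interval[1]) * f(interval[2]) > 0) stop("R0 - 1 does not change sign in the bracket")
  stats::uniroot(f, interval, tol = 1e-12)$root
}
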