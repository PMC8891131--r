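#' Model parameter set
#'
#' Construct and validate the full rate set of the illicit opioid use
#' disorder (IOUD) compartmental model. All rates are per year except
#' `Lambda` (persons/year) and `epsilon` (1/person). The defaults are the
#' baseline values obtained from literature estimates and parameter
#' estimation against 2002--2019 national surveillance data scaled to a
#' city of 200,000.
#'
#' @param Lambda recruitment rate into the susceptible class (persons/year)
#' @param mu natural death rate (1/year)
#' @param beta transmission rate of disorder through contact (1/year)
#' @param eta1 rate of self-referral from the disorder class into
#'   specialty treatment (1/year)
#' @param eta2 treatment-entry rate through contact with recovered
#'   individuals (1/year)
#' @param eta3 treatment-entry rate through contact with susceptible
#'   individuals (1/year)
#' @param omega direct disorder-to-recovered rate ("quitting cold turkey"
#'   or non-specialty treatment; 1/year)
#' @param rho treatment completion rate (1/year)
#' @param kappa treatment relapse rate back to the disorder class (1/year)
#' @param alpha1 spontaneous relapse rate from recovered (1/year)
#' @param alpha2 contact-driven relapse rate from recovered (1/year)
#' @param epsilon treatment saturation coefficient (1/person); entry into
#'   treatment is throttled by the factor `1/(1 + epsilon * T)`
#' @param delta overdose death rate of the disorder class: either a single
#'   nonnegative number (constant rate) or a schedule created by
#'   [delta_constant()], [as_delta_schedule()] or
#'   [delta_extrapolation_schedule()]
#' @return an object of class `ioud_params` (a named list)
#' @export
#' @examples
#' p <- ioud_params()
#' p$beta
ioud_params <- function(Lambda = 2500, mu = 0.0125, beta = 0.09,
                        eta1 = 0.5, eta2 = 0.1, eta3 = 0.17,
                        omega = 0.04, rho = 0.1, kappa = 0.4,
                        alpha1 = 0.2, alpha2 = 0.01,
                        epsilon = 0.0313, delta = 0.03002) {
  rates <- list(Lambda = Lambda, mu = mu, beta = beta, eta1 = eta1,
                eta2 = eta2, eta3 = eta3, omega = omega, rho = rho,
                kappa = kappa, alpha1 = alpha1, alpha2 = alpha2,
                epsilon = epsilon)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single nonnegative number")
  }
  if (mu <= 0) stop("mu must be strictly positive")
  if (is.numeric(delta)) {
    if (length(delta) != 1L || is.na(delta) || delta < 0)
      stop("constant delta must be a single nonnegative number")
    rates$delta <- delta_constant(delta)
  } else if (inherits(delta, "ioud_delta_schedule")) {
    rates$delta <- delta
  } else if (inherits(delta, "ioud_delta_fit")) {
    rates$delta <- as_delta_schedule(delta)
  } else {
    stop("delta must be a number, an 'ioud_delta_fit' or an 'ioud_delta_schedule'")
  }
  structure(rates, class = "ioud_params")
}

#' @export
print.ioud_params <- function(x, ...) {
  cat("IOUD model parameters (per year unless noted):\n")
  flat <- unlist(x[setdiff(names(x), "delta")])
  print(flat)
  cat("delta schedule:\n")
  print(x$delta)
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named entries replaced, re-running
#' validation.
#'
#' @param params an [ioud_params()] object
#' @param ... named replacements, e.g. `beta = 0.1` or `delta = 0.06`
#' @return an `ioud_params` object
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "ioud_params"))
  repl <- list(...)
  args <- params
  class(args) <- NULL
  for (nm in names(repl)) args[[nm]] <- repl[[nm]]
  do.call(ioud_params, args)
}

#' Evaluate the overdose death rate of a parameter set at time t
#' @param params an [ioud_params()] object
#' @param t calendar time (years), vectorized
#' @return delta(t) in 1/year
#' @export
param_delta <- function(params, t) delta_schedule_at(params$delta, t)

#' Read model parameters from a JSON or YAML-like config file
#'
#' The file must contain top-level numeric entries keyed by the ASCII
#' parameter names (Lambda, mu, beta, eta1, eta2, eta3, omega, rho, kappa,
#' alpha1, alpha2, epsilon, delta). JSON is parsed with jsonlite; a
#' minimal `key: value` YAML subset is also accepted.
#'
#' @param path file path
#' @return an `ioud_params` object
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  vals <- if (grepl("^\\s*\\{", joined)) {
    jsonlite::fromJSON(joined)
  } else {
    lines <- grep("^\\s*[A-Za-z0-9_]+\\s*:", txt, value = TRUE)
    kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.+?)\\s*$", lines))
    out <- lapply(kv, function(m) suppressWarnings(as.numeric(m[3])))
    names(out) <- vapply(kv, function(m) m[2], "")
    out[!vapply(out, is.na, TRUE)]
  }
  known <- c("Lambda", "mu", "beta", "eta1", "eta2", "eta3", "omega", "rho",
             "kappa", "alpha1", "alpha2", "epsilon", "delta")
  do.call(ioud_params, vals[intersect(names(vals), known)])
}

#' Baseline initial state
#'
#' The 2002 initial condition used for all baseline runs against the
#' scaled national data: S = 199500, I = 102, T = 95, R = 100.
#' @return named numeric vector (S, I, T, R)
#' @export
baseline_init <- function() c(S = 199500, I = 102, T = 95, R = 100)
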