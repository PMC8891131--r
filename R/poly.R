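# Minimal dense-polynomial helpers (coefficient vectors, ascending powers).
# Used by the equilibrium elimination; not exported.

.pmul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

.padd <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

.pstrip <- function(a, rel = 1e-10) {
  m <- max(abs(a))
  if (m == 0) return(0)
  k <- max(which(abs(a) > rel * m))
  a[seq_len(k)]
}

# divide polynomial a by linear divisor (d0 + d1 x); returns quotient and
# remainder (a scalar)
.pdivlin <- function(a, d0, d1) {
  stopifnot(d1 != 0)
  n <- length(a)
  q <- numeric(n - 1L)
  r <- a[n]
  for (k in seq(n - 1L, 1L)) {
    q[k] <- r / d1
    r <- a[k] - q[k] * d0
  }
  list(quotient = q, remainder = r)
}

.peval <- function(a, x) {
  out <- 0
  for (k in rev(seq_along(a))) out <- out * x + a[k]
  out
}
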