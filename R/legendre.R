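#' Normalized associated Legendre polynomial at the equator
#'
#' Evaluates \eqn{N_{lq} P_{lq}(0)}, the spherical-harmonic-normalized
#' associated Legendre polynomial at the equator (argument 0), where
#' \eqn{N_{lq} = \sqrt{(2l+1)/(4\pi) \cdot (l-q)!/(l+q)!}}. This is the
#' angular factor that maps a spherical-harmonic surface mode \eqn{(l, q)}
#' onto the \eqn{q}-th Fourier mode of an equatorial cross-section.
#' Computed in log-space (lgamma) so it is stable well beyond \eqn{l = 75}.
#'
#' The value is exactly 0 whenever \eqn{l + q} is odd (parity of the
#' Legendre functions).
#'
#' @param l degree, integer \eqn{\ge 0} (vectorized).
#' @param q order, integer with \eqn{0 \le q \le l} (vectorized).
#' @return numeric vector of \eqn{N_{lq} P_{lq}(0)}.
#' @examples
#' equatorial_legendre(2, 2)  # 3*sqrt(5/(96*pi))
#' equatorial_legendre(3, 2)  # 0 by parity
#' @export
equatorial_legendre <- function(l, q) {
  n <- max(length(l), length(q))
  l <- rep_len(as.integer(l), n)
  q <- rep_len(as.integer(q), n)
  if (any(q > l)) stop("require q <= l")
  if (any(q < 0) || any(l < 0)) stop("require l >= 0 and q >= 0")
  out <- numeric(n)
  even <- (l + q) %% 2L == 0L
  if (any(even)) {
    le <- l[even]; qe <- q[even]
    # P_l^q(0) = (-1)^((l+q)/2) (l+q-1)!! / (l-q)!!  for l + q even,
    # with (2k-1)!! = (2k)!/(2^k k!) and (2k)!! = 2^k k!
    kp <- (le + qe) / 2  # (l+q-1)!! = (l+q)!/(2^kp kp!)
    km <- (le - qe) / 2  # (l-q)!!   = 2^km km!
    logdf_num <- lgamma(le + qe + 1) - kp * log(2) - lgamma(kp + 1)
    logdf_den <- km * log(2) + lgamma(km + 1)
    logN <- 0.5 * (log(2 * le + 1) - log(4 * pi) +
                     lgamma(le - qe + 1) - lgamma(le + qe + 1))
    out[even] <- (-1)^kp * exp(logN + logdf_num - logdf_den)
  }
  out
}

# Normalized associated Legendre values N_lm P_lm(x) for all
# 0 <= m <= l <= l_max at a single |x| < 1, by the standard stable
# three-term recurrence on the fully normalized functions.
# Returns an (l_max+1) x (l_max+1) matrix indexed [l+1, m+1] (0 above
# the diagonal).
legendre_normalized_table <- function(l_max, x) {
  stopifnot(l_max >= 0, abs(x) <= 1)
  P <- matrix(0, l_max + 1, l_max + 1)
  sx <- sqrt(pmax(0, 1 - x^2))
  P[1, 1] <- sqrt(1 / (4 * pi))
  if (l_max == 0) return(P)
  for (m in 1:l_max) {
    # diagonal: P_mm = -sqrt((2m+1)/(2m)) * sx * P_{m-1,m-1}
    P[m + 1, m + 1] <- -sqrt((2 * m + 1) / (2 * m)) * sx * P[m, m]
  }
  for (m in 0:(l_max - 1)) {
    P[m + 2, m + 1] <- x * sqrt(2 * m + 3) * P[m + 1, m + 1]
    if (m + 2 <= l_max) {
      for (l in (m + 2):l_max) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[l + 1, m + 1] <- a * (x * P[l, m + 1] - b * P[l - 1, m + 1])
      }
    }
  }
  P
}
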