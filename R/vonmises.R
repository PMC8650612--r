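# Circular statistics: sampling and maximum-likelihood fitting of the
# von Mises distribution f(theta) = exp(kappa*cos(theta-mu)) / (2*pi*I0(kappa)).

VM_KAPPA_CAP <- 500

#' Draw von Mises deviates
#'
#' Best--Fisher rejection sampler; `kappa = 0` falls back to the uniform
#' circular distribution. `kappa` is capped at 500; at or beyond the cap the
#' distribution is treated as a point mass at `mu` (the concentration
#' limit), which keeps the sampler finite.
#'
#' @param n number of deviates.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa >= VM_KAPPA_CAP) {
    out <- rep(mu, n)
    out <- out - 2 * pi * floor((out + pi) / (2 * pi))
    out[out <= -pi] <- pi
    return(out)
  }
  if (kappa < 1e-10) {
    theta <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      m <- length(todo)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      th <- sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1))
      theta[todo[ok]] <- th[ok]
      todo <- todo[!ok]
    }
  }
  out <- theta + mu
  # wrap to (-pi, pi]
  out <- out - 2 * pi * floor((out + pi) / (2 * pi))
  out[out <= -pi] <- pi
  out
}

# Solve A1(kappa) = target on [0, cap] by bracketed bisection.
solve_kappa <- function(target, tol = 1e-8) {
  if (target <= 0) return(0)
  if (target >= vm_a1(VM_KAPPA_CAP)) return(VM_KAPPA_CAP)
  lo <- 0; hi <- VM_KAPPA_CAP
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (vm_a1(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maximum-likelihood von Mises fit
#'
#' Fits mean direction and concentration to a sample of angles. With free
#' `mu`, the estimate is the circular mean and `kappa` solves
#' `A1(kappa) = Rbar` (mean resultant length). With `fix_mu` supplied, `kappa`
#' solves `A1(kappa) = mean(cos(theta - mu))` when that mean cosine is
#' positive and is 0 otherwise (the boundary MLE). Root finding is bracketed
#' bisection to 1e-8; `kappa` is capped at 500 and the cap is flagged.
#'
#' @param angles angles (rad); at least 5 required.
#' @param fix_mu fixed mean direction (rad), or `NULL` to estimate it.
#' @return an object of class `vonmises_fit`: list with `mu`, `kappa`, `n`,
#'   `loglik`, `mu_fixed`, `at_cap`.
#' @examples
#' set.seed(1)
#' th <- rvonmises(2000, mu = 0, kappa = 2)
#' vonmises_fit(th, fix_mu = 0)
#' @export
vonmises_fit <- function(angles, fix_mu = NULL) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 5) stop("vonmises_fit: need at least 5 angles, got ", n, call. = FALSE)
  if (is.null(fix_mu)) {
    S <- mean(sin(angles)); C <- mean(cos(angles))
    mu <- atan2(S, C)
    rbar <- sqrt(S^2 + C^2)
    kappa <- solve_kappa(rbar)
    mu_fixed <- FALSE
  } else {
    mu <- fix_mu
    mc <- mean(cos(angles - mu))
    kappa <- if (mc > 0) solve_kappa(mc) else 0
    mu_fixed <- TRUE
  }
  at_cap <- kappa >= VM_KAPPA_CAP
  ll <- kappa * sum(cos(angles - mu)) -
    n * (log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
  structure(list(mu = mu, kappa = kappa, n = n, loglik = ll,
                 mu_fixed = mu_fixed, at_cap = at_cap),
            class = "vonmises_fit")
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf("<vonmises_fit> mu = %.4f rad%s, kappa = %.4f%s, n = %d, logLik = %.2f\n",
              x$mu, if (x$mu_fixed) " (fixed)" else "",
              x$kappa, if (x$at_cap) " (at cap)" else "", x$n, x$loglik))
  invisible(x)
}
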