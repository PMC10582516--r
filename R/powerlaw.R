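# Discrete power-law machinery. The pmf on {xmin, xmin+1, ...} is
# p(k) = k^(-alpha) / zeta(alpha, xmin), with zeta the Hurwitz zeta
# function; alpha is estimated by maximum likelihood and xmin by minimising
# the Kolmogorov-Smirnov distance between the empirical and fitted tail
# CDFs.

# Hurwitz zeta: direct sum of the first `nterms` terms plus an
# Euler-Maclaurin tail correction. Accurate to well below 1e-10 for
# alpha > 1, q >= 1 with the default settings.
hurwitz_zeta <- function(alpha, q, nterms = 400L) {
  stopifnot(alpha > 1, q > 0)
  k <- 0:(nterms - 1L)
  s <- sum((q + k)^(-alpha))
  nq <- q + nterms
  s + nq^(1 - alpha) / (alpha - 1) + 0.5 * nq^(-alpha) +
    alpha * nq^(-alpha - 1) / 12 -
    alpha * (alpha + 1) * (alpha + 2) * nq^(-alpha - 3) / 720
}

plaw_loglik <- function(alpha, tail, xmin) {
  -length(tail) * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(tail))
}

plaw_alpha_mle <- function(tail, xmin) {
  stats::optimize(function(a) plaw_loglik(a, tail, xmin),
                  interval = c(1.01, 25), maximum = TRUE)$maximum
}

# KS distance between the empirical CDF of the tail sample and the fitted
# discrete power-law CDF. Both CDFs are right-continuous step functions
# with jumps on the same integer support, so the supremum is attained at an
# observed support point and no left-limit comparison is needed (that would
# inflate the distance by the jump heights).
plaw_ks <- function(tail, alpha, xmin) {
  ks <- sort(unique(tail))
  n <- length(tail)
  ecdf_hi <- cumsum(tabulate(factor(tail, levels = ks))) / n
  z0 <- hurwitz_zeta(alpha, xmin)
  theo <- vapply(ks, function(k) 1 - hurwitz_zeta(alpha, k + 1) / z0, numeric(1L))
  max(abs(ecdf_hi - theo))
}

#' Fit a discrete power law to a degree distribution
#'
#' Estimates the scaling exponent `alpha` and lower bound `xmin` of a
#' discrete power law from a sample of positive integers (typically a
#' network degree sequence). For every candidate `xmin`, `alpha` is fitted
#' by maximum likelihood under the Hurwitz-zeta-normalised pmf, and the
#' `xmin` minimising the Kolmogorov-Smirnov distance between empirical and
#' fitted tail CDFs is selected (goodness-of-fit approach). An optional
#' semi-parametric bootstrap yields a plausibility p-value.
#'
#' @param degrees Vector of positive integers (zeros are dropped).
#' @param bootstrap_reps Number of bootstrap replicates for `p_boot`
#'   (0 = skip, the default; the bootstrap is expensive).
#' @param min_tail Smallest admissible tail size when scanning `xmin`
#'   (default 10, so fits are never vacuous).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `powerlaw_fit` with elements `alpha`, `xmin`,
#'   `ks_stat`, `n_tail`, `p_boot`, `degrees`. Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
fit_powerlaw <- function(degrees, bootstrap_reps = 0L, min_tail = 10L,
                         seed = NULL) {
  degrees <- as.integer(degrees)
  degrees <- degrees[!is.na(degrees) & degrees > 0L]
  if (length(degrees) < 2L) stop("need at least 2 positive degrees", call. = FALSE)
  if (length(unique(degrees)) == 1L) {
    stop("degenerate degree distribution", call. = FALSE)
  }
  cand <- sort(unique(degrees))
  tail_sizes <- vapply(cand, function(x) sum(degrees >= x), integer(1L))
  cand <- cand[tail_sizes >= max(2L, min_tail)]
  if (length(cand) == 0L) cand <- sort(unique(degrees))[1L]
  fits <- lapply(cand, function(x) {
    tl <- degrees[degrees >= x]
    a <- plaw_alpha_mle(tl, x)
    list(xmin = x, alpha = a, ks = plaw_ks(tl, a, x), n_tail = length(tl))
  })
  ks_all <- vapply(fits, `[[`, numeric(1L), "ks")
  best <- fits[[which.min(ks_all)]] # ties resolved at the smallest xmin
  p_boot <- NA_real_
  if (bootstrap_reps > 0L) {
    n <- length(degrees)
    body <- degrees[degrees < best$xmin]
    p_tail <- best$n_tail / n
    exceed <- local_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(b) {
        take_tail <- stats::runif(n) < p_tail
        syn <- integer(n)
        if (any(!take_tail) && length(body) > 0L) {
          syn[!take_tail] <- sample(body, sum(!take_tail), replace = TRUE)
        } else {
          take_tail[] <- TRUE
        }
        if (any(take_tail)) {
          syn[take_tail] <- power_law_degree_sample(best$alpha, best$xmin,
                                                    sum(take_tail), seed = NULL)
        }
        refit <- fit_powerlaw(syn, bootstrap_reps = 0L, min_tail = min_tail)
        refit$ks_stat >= best$ks
      }, logical(1L))
    })
    p_boot <- mean(exceed)
  }
  structure(
    list(alpha = best$alpha, xmin = best$xmin, ks_stat = best$ks,
         n_tail = best$n_tail, p_boot = p_boot, degrees = degrees),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Discrete power-law fit: alpha = %.3f, xmin = %d, KS = %.4f (n_tail = %d)\n",
              x$alpha, x$xmin, x$ks_stat, x$n_tail))
  if (!is.na(x$p_boot)) cat(sprintf("  bootstrap plausibility p = %.3f\n", x$p_boot))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Inverse-CDF sampling from the Hurwitz-zeta-normalised discrete power law
#' on `{xmin, xmin + 1, ...}`. Used both as a fixture generator and as the
#' independent oracle for parameter-recovery tests of [fit_powerlaw()].
#'
#' @param alpha Scaling exponent (> 1).
#' @param xmin Integer lower bound (>= 1).
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return An integer vector of length `n`, all values `>= xmin`.
#' @export
power_law_degree_sample <- function(alpha, xmin = 1L, n = 1L, seed = NULL) {
  if (alpha <= 1) stop("alpha must exceed 1", call. = FALSE)
  xmin <- as.integer(xmin)
  stopifnot(xmin >= 1L, n >= 1L)
  z0 <- hurwitz_zeta(alpha, xmin)
  cap <- 100000L
  ks <- xmin:(xmin + cap - 1L)
  cdf <- cumsum(ks^(-alpha) / z0)
  local_seed(seed, {
    u <- stats::runif(n)
    idx <- findInterval(u, cdf) # number of CDF values strictly below u
    out <- xmin + idx
    over <- which(u > cdf[cap])
    for (i in over) { # exceedingly rare deep-tail draws: exact search
      k <- ks[cap]
      while (1 - hurwitz_zeta(alpha, k + 1) / z0 < u[i]) k <- k * 2L
      lo <- ks[cap]; hi <- k
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (1 - hurwitz_zeta(alpha, mid + 1) / z0 >= u[i]) hi <- mid else lo <- mid + 1L
      }
      out[i] <- lo
    }
    as.integer(out)
  })
}
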