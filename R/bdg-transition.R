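# Transition probabilities of the linear birth-death-immigration chain on
# family size: up-rate kappa + n*lambda, down-rate n*mu, truncated to {0..M}.

bdgGenerator <- function(kappa, lambda, mu, M) {
  n <- 0:M
  up <- kappa + n * lambda
  down <- n * mu
  Q <- matrix(0, M + 1, M + 1)
  Q[cbind(1:M, 2:(M + 1))] <- up[1:M]
  Q[cbind(2:(M + 1), 1:M)] <- down[2:(M + 1)]
  # diagonal carries the full exit rate, so the up transition out of state M
  # leaks probability: the row-sum deficit of the resulting P is exactly the
  # truncation mass
  diag(Q) <- -(up + down)
  Q
}

#' Transition matrix of the birth-death-gain chain
#'
#' Computes \eqn{P_t(n \to m)} for the continuous-time Markov chain on family
#' sizes \eqn{\{0, \dots, M\}} with up-rate \eqn{\kappa + n\lambda} and
#' down-rate \eqn{n\mu}, by uniformization of the truncated tridiagonal
#' generator. The chain is truncated by letting the up transition out of state
#' M leak, so each row sums to at most 1 and the deficit is the truncation
#' mass.
#'
#' @param rates a [BDGRates-class] or a numeric vector `c(kappa, lambda, mu)`
#' @param t branch length (>= 0); `t = 0` returns the identity
#' @param M truncation bound (>= 1)
#' @param checkStates optional integer vector of start states (0-based) whose
#'   truncation mass must stay below `truncTol`; violation raises an error of
#'   class `dfxTruncationError` asking for a larger M
#' @param truncTol tolerance on the truncation mass for `checkStates`
#' @return an (M+1) x (M+1) matrix of transition probabilities
#' @examples
#' P <- transitionMatrix(c(0, 0, 1), t = log(2), M = 5)
#' P[3, 1]  # P(2 -> 0) = 0.25: two independent survivals at prob 1/2
#' @export
transitionMatrix <- function(rates, t, M, checkStates = NULL, truncTol = 1e-9) {
  if (is(rates, "BDGRates")) rates <- c(rates@kappa, rates@lambda, rates@mu)
  stopifnot(length(rates) == 3, all(rates >= 0), t >= 0, M >= 1)
  M <- as.integer(M)
  P <- if (t == 0) {
    diag(M + 1)
  } else {
    Q <- bdgGenerator(rates[1], rates[2], rates[3], M)
    q <- max(-diag(Q))
    if (q == 0) {
      diag(M + 1)
    } else {
      A <- diag(M + 1) + Q / q
      qt <- q * t
      K <- as.integer(max(stats::qpois(1e-14, qt, lower.tail = FALSE), 10L)) + 5L
      w <- stats::dpois(0:K, qt)
      P <- w[1] * diag(M + 1)
      Ak <- diag(M + 1)
      for (k in seq_len(K)) {
        Ak <- Ak %*% A
        if (w[k + 1] > 0) P <- P + w[k + 1] * Ak
        # remaining Poisson mass bounds the truncation error of the series
        if (stats::ppois(k, qt, lower.tail = FALSE) < 1e-15) break
      }
      P
    }
  }
  dimnames(P) <- list(0:M, 0:M)
  if (!is.null(checkStates)) {
    deficit <- 1 - rowSums(P)[checkStates + 1L]
    if (any(deficit > truncTol)) {
      stop(structure(class = c("dfxTruncationError", "error", "condition"),
                     list(message = sprintf(
                       "truncation mass %.3g exceeds tolerance %.3g at M = %d; increase M",
                       max(deficit), truncTol, M), call = NULL)))
    }
  }
  P
}

#' Stationary root prior of the birth-death-gain chain
#'
#' The long-run distribution of family size: negative binomial with size
#' \eqn{\kappa/\lambda} and success probability \eqn{\lambda/\mu} when
#' \eqn{\lambda > 0}, Poisson with mean \eqn{\kappa/\mu} when
#' \eqn{\lambda = 0}; truncated to \eqn{\{0..M\}} and renormalized. Requires
#' \eqn{\lambda < \mu}.
#'
#' @inheritParams transitionMatrix
#' @return a probability vector of length M + 1 summing to 1
#' @examples
#' rootPrior(c(2, 0, 1), M = 30)[1]  # Poisson(2) mass at zero, exp(-2)
#' @export
rootPrior <- function(rates, M) {
  if (is(rates, "BDGRates")) rates <- c(rates@kappa, rates@lambda, rates@mu)
  kappa <- rates[1]; lambda <- rates[2]; mu <- rates[3]
  if (mu <= 0) stop("mu must be positive for a stationary root prior")
  if (lambda >= mu)
    stop("no stationary distribution: effective lambda must be < mu")
  n <- 0:M
  p <- if (lambda > 0) {
    dnbinom(n, size = kappa / lambda, prob = 1 - lambda / mu)
  } else {
    dpois(n, kappa / mu)
  }
  p / sum(p)
}
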