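## Scaled conjugate gradient (Moller 1993): conjugate directions with a
## second-order estimate obtained by a finite difference along the search
## direction and Levenberg-style damping; no line search. A step is accepted
## only when the comparison ratio indicates an actual loss decrease, so the
## trace of accepted losses is non-increasing. Shared by the autoencoder
## (reconstruction MSE) and the softmax classifier (binary cross-entropy).

#' Minimize a smooth loss by scaled conjugate gradient
#'
#' @param par numeric start vector.
#' @param fn loss function of the parameter vector; must return a scalar.
#' @param gr gradient function of the parameter vector.
#' @param maxIter iteration cap (accepted + rejected steps).
#' @param tol relative loss-change stopping tolerance: stop once the relative
#'   decrease stays below \code{tol} for \code{tolIter} consecutive accepted
#'   iterations.
#' @param tolIter accepted iterations the tolerance must hold for.
#' @param sigma0 finite-difference constant for the curvature estimate.
#' @param lambda0 initial damping.
#' @return list with \code{par} (the minimizer found), \code{value} (its
#'   loss) and \code{trace} (an \linkS4class{ScgTrace}).
#' @references Moller, M. F. (1993) A scaled conjugate gradient algorithm for
#'   fast supervised learning. Neural Networks 6(4), 525-533.
#' @export
scgOptimize <- function(par, fn, gr, maxIter = 1000L, tol = 1e-8,
                        tolIter = 5L, sigma0 = 1e-4, lambda0 = 1e-6) {
    stopifnot(maxIter >= 1, tol > 0)
    w <- par
    np <- length(w)
    E <- fn(w)
    if (!is.finite(E))
        stop("divergence: non-finite loss at iteration 0")
    g <- gr(w)
    r <- -g
    p <- r
    lambda <- lambda0
    lambdabar <- 0
    success <- TRUE
    losses <- E
    flat <- 0L
    k <- 0L
    termination <- "max_iter"
    delta <- 0; pnorm2 <- sum(p * p)
    while (k < maxIter) {
        k <- k + 1L
        if (success) {
            pnorm2 <- sum(p * p)
            if (pnorm2 < .Machine$double.eps^2) {
                termination <- "grad_underflow"; break
            }
            sigma <- sigma0 / sqrt(pnorm2)
            s <- (gr(w + sigma * p) - g) / sigma
            delta <- sum(p * s)
        }
        delta2 <- delta + (lambda - lambdabar) * pnorm2
        if (delta2 <= 0) {                     # make the Hessian estimate PD
            lambdabar <- 2 * (lambda - delta2 / pnorm2)
            delta2 <- -delta2 + lambda * pnorm2
            lambda <- lambdabar
        }
        mu <- sum(p * r)
        alpha <- mu / delta2
        Enew <- fn(w + alpha * p)
        Delta <- if (is.finite(Enew)) 2 * delta2 * (E - Enew) / mu^2 else -Inf
        if (Delta >= 0) {                      # accepted step
            w <- w + alpha * p
            E <- Enew
            gnew <- gr(w)
            rnew <- -gnew
            lambdabar <- 0
            success <- TRUE
            if (k %% np == 0L) {
                p <- rnew                      # periodic restart
            } else {
                beta <- (sum(rnew * rnew) - sum(rnew * r)) / mu
                p <- rnew + beta * p
            }
            g <- gnew
            r <- rnew
            if (Delta >= 0.75) lambda <- lambda / 4
            prev <- losses[length(losses)]
            losses <- c(losses, E)
            rel <- abs(prev - E) / max(abs(prev), .Machine$double.eps)
            flat <- if (rel < tol) flat + 1L else 0L
            if (flat >= tolIter) { termination <- "tol"; break }
            if (sqrt(sum(r * r)) < 1e-12) {
                termination <- "grad_underflow"; break
            }
        } else {
            lambdabar <- lambda
            success <- FALSE
        }
        if (Delta < 0.25)
            lambda <- lambda + delta2 * (1 - Delta) / pnorm2
        if (!is.finite(lambda) || lambda > 1e60) {
            if (!is.finite(Enew) && !is.finite(E))
                stop("divergence: non-finite loss at iteration ", k)
            termination <- "tol"               # no further decrease possible
            break
        }
    }
    list(par = w, value = E,
         trace = new("ScgTrace", loss = losses, iterations = k,
                     termination = termination))
}
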