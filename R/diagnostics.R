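#' Deviance information criterion from stored Gibbs draws
#'
#' Spiegelhalter form: \code{DIC = Dbar + pD} with \code{pD = Dbar - Dhat},
#' where \code{Dbar} is the posterior mean of the per-draw conditional
#' deviance (Gaussian likelihood of y given all effects) and \code{Dhat} the
#' deviance at the posterior means of the parameters. Lower is better; values
#' are comparable only between fits of the same data with the same likelihood.
#'
#' @param fit a [gibbs_fit()] object, or any list with a \code{draws} data
#'   frame containing a \code{deviance} column and a \code{deviance_at_mean}
#'   scalar.
#' @return list of class \code{dic}: \code{dic}, \code{dbar}, \code{dhat},
#'   \code{pd}.
#' @export
compute_dic <- function(fit) {
  dev <- fit$draws$deviance
  if (is.null(dev) || length(dev) < 2)
    stop("compute_dic: fewer than 2 stored deviance draws")
  dbar <- mean(dev)
  dhat <- fit$deviance_at_mean
  pd <- dbar - dhat
  structure(list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd),
            class = "dic")
}

#' @export
print.dic <- function(x, ...) {
  cat(sprintf("DIC %.2f (Dbar %.2f, pD %.2f)\n", x$dic, x$dbar, x$pd))
  invisible(x)
}

#' Raftery-Lewis run-length diagnostic
#'
#' Two-state Markov-chain construction on the indicator of exceeding the
#' empirical q-quantile: the indicator sequence is thinned until a first-order
#' Markov chain is preferred over a second-order one by BIC, the thinned
#' chain's transition probabilities (alpha, beta) are estimated, and the
#' required burn-in, required chain length and the dependence factor
#' I = (M + N) / Nmin are derived from them.
#'
#' @param chain numeric vector of (scalar) posterior draws.
#' @param q quantile of interest (default 0.025).
#' @param r required precision of the estimated cumulative probability
#'   (default 0.005).
#' @param s probability of attaining that precision (default 0.95).
#' @param converge_eps convergence tolerance for the burn-in bound.
#' @return list of class \code{raftery_lewis}: \code{burnin} (M), \code{n}
#'   (N), \code{nmin}, \code{thin} (k), \code{dependence_factor}; or, when the
#'   chain is shorter than the pilot minimum or constant, a list with
#'   \code{insufficient = TRUE} / \code{constant = TRUE} and a message.
#' @export
raftery_lewis <- function(chain, q = 0.025, r = 0.005, s = 0.95,
                          converge_eps = 0.001) {
  stopifnot(is.numeric(chain), q > 0, q < 1, r > 0, s > 0, s < 1)
  phi <- qnorm(0.5 * (1 + s))
  nmin <- ceiling(q * (1 - q) * phi^2 / r^2)
  if (length(unique(chain)) == 1)
    return(structure(list(constant = TRUE, nmin = nmin,
                          message = "constant chain: diagnostic undefined"),
                     class = "raftery_lewis"))
  if (length(chain) < nmin)
    return(structure(list(insufficient = TRUE, nmin = nmin,
                          message = sprintf(
                            "chain length %d below pilot minimum %d",
                            length(chain), nmin)),
                     class = "raftery_lewis"))
  cutoff <- quantile(chain, probs = q, names = FALSE)
  dichot <- as.integer(chain <= cutoff)
  niter <- length(dichot)
  kthin <- 0
  bic <- 1
  while (bic >= 0) {
    kthin <- kthin + 1
    test <- dichot[seq(1, niter, by = kthin)]
    nd <- length(test)
    if (nd < 3) break
    tran <- array(0, c(2, 2, 2))
    for (i in 3:nd)
      tran[test[i - 2] + 1, test[i - 1] + 1, test[i] + 1] <-
        tran[test[i - 2] + 1, test[i - 1] + 1, test[i] + 1] + 1
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      if (tran[i1, i2, i3] != 0) {
        fitted <- sum(tran[i1, i2, ]) * sum(tran[, i2, i3]) / sum(tran[, i2, ])
        g2 <- g2 + 2 * tran[i1, i2, i3] * log(tran[i1, i2, i3] / fitted)
      }
    }
    bic <- g2 - 2 * log(nd - 2)
  }
  test <- dichot[seq(1, niter, by = kthin)]
  nd <- length(test)
  final <- matrix(0, 2, 2)
  for (i in 2:nd)
    final[test[i - 1] + 1, test[i] + 1] <- final[test[i - 1] + 1, test[i] + 1] + 1
  alpha <- final[1, 2] / (final[1, 1] + final[1, 2])
  beta <- final[2, 1] / (final[2, 1] + final[2, 2])
  tempburn <- log(converge_eps * (alpha + beta) / max(alpha, beta)) /
    log(abs(1 - alpha - beta))
  nburn <- ceiling(tempburn) * kthin
  tempprec <- (2 - alpha - beta) * alpha * beta * phi^2 /
    ((alpha + beta)^3 * r^2)
  nkeep <- ceiling(tempprec) * kthin
  structure(list(burnin = nburn, n = nkeep, nmin = nmin, thin = kthin,
                 dependence_factor = (nburn + nkeep) / nmin),
            class = "raftery_lewis")
}

#' @export
print.raftery_lewis <- function(x, ...) {
  if (isTRUE(x$constant) || isTRUE(x$insufficient)) cat(x$message, "\n")
  else cat(sprintf(
    "Raftery-Lewis: burn-in %d, required N %d (Nmin %d), thin %d, I = %.2f\n",
    x$burnin, x$n, x$nmin, x$thin, x$dependence_factor))
  invisible(x)
}
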