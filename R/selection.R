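#' Backward elimination of fixed factors
#'
#' Iteratively fits the fixed-effects-only linear model by least squares,
#' computes each candidate factor's marginal (partial) F-test, removes the
#' least significant factor with P >= alpha, and repeats until every remaining
#' factor is significant at alpha.
#'
#' @param data phenotype table (single trait) with a \code{value} column and
#'   the candidate factor columns.
#' @param candidate_factors character vector of factor column names.
#' @param alpha significance level (default 0.05).
#' @param covariate optional numeric covariate column kept in every model
#'   (not subject to elimination).
#' @return list of class \code{backward_elimination}: \code{retained}
#'   (character vector), \code{trace} (data frame with one row per
#'   elimination step: factor dropped, F, P), \code{anova} (final marginal
#'   F-table).
#' @export
backward_eliminate <- function(data, candidate_factors, alpha = 0.05,
                               covariate = NULL) {
  stopifnot("value" %in% names(data), length(candidate_factors) >= 1)
  d <- data
  for (f in candidate_factors) {
    if (!f %in% names(d)) stop("backward_eliminate: column not found: ", f)
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2)
      stop("backward_eliminate: factor ", f, " has fewer than 2 observed levels")
  }
  current <- candidate_factors
  trace <- data.frame(dropped = character(), F = numeric(), P = numeric(),
                      stringsAsFactors = FALSE)
  marginal_f <- function(factors) {
    rhs <- paste(c("1", covariate, factors), collapse = " + ")
    fit <- lm(as.formula(paste("value ~", rhs)), data = d)
    tab <- drop1(fit, scope = as.formula(paste("~", paste(factors, collapse = "+"))),
                 test = "F")
    tab <- tab[factors, , drop = FALSE]
    data.frame(factor = factors, F = tab[["F value"]], P = tab[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  }
  repeat {
    if (length(current) == 0) break
    ft <- marginal_f(current)
    if (any(!is.finite(ft$P))) {
      # non-estimable factor (aliased): drop it first
      worst <- which(!is.finite(ft$P))[1]
    } else if (max(ft$P) >= alpha) {
      worst <- which.max(ft$P)
    } else break
    trace <- rbind(trace, data.frame(dropped = ft$factor[worst],
                                     F = ft$F[worst], P = ft$P[worst]))
    current <- setdiff(current, ft$factor[worst])
  }
  final <- if (length(current)) marginal_f(current) else
    data.frame(factor = character(), F = numeric(), P = numeric())
  structure(list(retained = current, trace = trace, anova = final),
            class = "backward_elimination")
}

#' @export
print.backward_elimination <- function(x, ...) {
  cat("retained factors:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  if (nrow(x$trace)) {
    cat("eliminated (in order):\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}
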