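#' Model specification for a single- or two-trait mixed model
#'
#' Declares the response trait(s), the fixed factors, an optional climate
#' covariate (linear or quadratic) and whether a permanent-environment term is
#' fitted. The additive genetic effect with covariance G is always included.
#'
#' @param traits character vector of 1 (univariate) or 2 (bivariate) trait
#'   names, matching the \code{trait} column of the data.
#' @param fixed character vector of factor column names, or a list of two such
#'   vectors (one per trait).
#' @param covariate NULL, a numeric column name, or a list of two (per trait).
#' @param degree 1 (linear) or 2 (quadratic) for the covariate, or a list.
#' @param pe logical: fit a permanent-environment effect; NULL (default)
#'   fits it iff the trait has repeated records; or a list of two.
#' @param additive fit the additive genomic effect (default TRUE; the models
#'   of interest always include it). \code{FALSE} gives a fixed-effects-only
#'   Gaussian model (univariate only), used to calibrate the residual-variance
#'   conditional against its conjugate closed form.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(traits, fixed = character(), covariate = NULL,
                       degree = 1, pe = NULL, additive = TRUE) {
  stopifnot(length(traits) %in% 1:2, is.character(traits))
  if (!additive && length(traits) > 1)
    stop("model_spec: additive = FALSE is univariate-only")
  per_trait <- function(x) {
    if (is.list(x)) {
      stopifnot(length(x) == length(traits))
      x
    } else rep(list(x), length(traits))
  }
  structure(list(traits = traits, fixed = per_trait(fixed),
                 covariate = per_trait(covariate),
                 degree = per_trait(degree), pe = per_trait(pe),
                 additive = additive),
            class = "model_spec")
}

#' Gibbs chain configuration
#'
#' The reference profile is a chain of 100,000 iterations with a burn-in of
#' 40,000 and thinning of 30; the desk profile (20,000 / 5,000 / 10) is used
#' for tests and scaled-down runs.
#'
#' @param chain total number of iterations.
#' @param burnin burn-in iterations (< chain).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed for the chain.
#' @param nu prior degrees-of-freedom offset for the scaled inverse
#'   chi-square variance conditionals; the default -2 is the flat-prior
#'   equivalent (posterior df = data df - 2).
#' @return object of class \code{gibbs_config}.
#' @export
gibbs_config <- function(chain = 20000, burnin = 5000, thin = 10, seed = 1,
                         nu = -2) {
  stopifnot(chain > 0, burnin >= 0, burnin < chain, thin >= 1)
  structure(list(chain = as.integer(chain), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed), nu = nu),
            class = "gibbs_config")
}

#' @rdname gibbs_config
#' @param profile \code{"paper"} (100,000 / 40,000 / 30) or \code{"desk"}
#'   (20,000 / 5,000 / 10).
#' @export
gibbs_profile <- function(profile = c("desk", "paper"), seed = 1) {
  profile <- match.arg(profile)
  if (profile == "paper") gibbs_config(100000, 40000, 30, seed = seed)
  else gibbs_config(20000, 5000, 10, seed = seed)
}

# Build a full-rank fixed-effects design matrix for one trait's records.
build_design <- function(d, fixed, covariate, degree) {
  n <- nrow(d)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (f in fixed) {
    if (!f %in% names(d)) stop("gibbs_fit: fixed factor column not found: ", f)
    fac <- factor(d[[f]])
    if (nlevels(fac) < 2) next
    mm <- model.matrix(~fac)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(fac)[-1])
    X <- cbind(X, mm)
  }
  if (!is.null(covariate)) {
    if (!covariate %in% names(d))
      stop("gibbs_fit: covariate column not found: ", covariate)
    cv <- d[[covariate]] - mean(d[[covariate]])
    X <- cbind(X, cv)
    colnames(X)[ncol(X)] <- covariate
    if (degree >= 2) {
      X <- cbind(X, cv^2)
      colnames(X)[ncol(X)] <- paste0(covariate, "^2")
    }
  }
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

# Inverse-Wishart draw: density |S|^(nu/2) |Sigma|^-((nu+k+1)/2) exp(-tr(S Sigma^-1)/2)
rinvwish <- function(nu, S) {
  k <- ncol(S)
  ridge <- 1e-10 * mean(diag(S)) + 1e-300
  W <- stats::rWishart(1, nu, solve(S + ridge * diag(k)))[, , 1]
  solve(W + 1e-300 * diag(k))
}

#' Fit a repeatability or animal model by Gibbs sampling
#'
#' Samples the full conditionals of a Gaussian mixed model
#' \deqn{y = X\beta + Z_a a + Z_{pe} pe + e,}
#' with \eqn{a \sim N(0, G\sigma^2_a)} (or matrix-normal with trait covariance
#' \eqn{\Sigma_a} in the bivariate case), \eqn{pe \sim N(0, I\sigma^2_{pe})}
#' and \eqn{e \sim N(0, I\sigma^2_e)} (2x2 residual covariance across traits
#' when record sets are paired; zero residual covariance otherwise). Effects
#' are updated in blocks; the additive block is sampled in the eigenbasis of
#' the blended G, which makes balanced designs O(q^2) per iteration. Variance
#' components are drawn from scaled inverse chi-square (inverse-Wishart)
#' conditionals with effectively flat priors. Per-draw deviance is stored for
#' DIC computation.
#'
#' @param data long-format phenotype table containing the spec's trait(s).
#' @param spec [model_spec()].
#' @param grm [vanraden_grm()] object (blended G is used) covering every
#'   animal in the data.
#' @param cfg [gibbs_config()].
#' @param verbose print progress.
#' @return object of class \code{gibbs_fit}: \code{draws} (data frame of
#'   thinned post-burn-in variance-component and deviance draws),
#'   \code{gebv} (per trait: posterior mean and SD of each animal's additive
#'   value), \code{beta} (posterior means of fixed-effect solutions),
#'   \code{deviance_at_mean}, \code{animals}, \code{spec}, \code{cfg},
#'   \code{n_records}.
#' @export
gibbs_fit <- function(data, spec, grm, cfg = gibbs_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "gibbs_config"),
            inherits(grm, "grm"))
  k <- length(spec$traits)
  dl <- lapply(spec$traits, function(tr) {
    d <- data[data$trait == tr & !is.na(data$value), , drop = FALSE]
    if (nrow(d) == 0) stop("gibbs_fit: no records for trait ", tr)
    d
  })
  animals <- sort(unique(unlist(lapply(dl, function(d) d$animal_id))))
  if (!all(animals %in% rownames(grm$G)))
    stop("gibbs_fit: animals in data missing from the GRM")
  G <- grm$G[animals, animals, drop = FALSE]
  q <- length(animals)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop("gibbs_fit: blended G is not positive definite")
  U <- eg$vectors
  lam <- eg$values

  ia <- lapply(dl, function(d) match(d$animal_id, animals))
  y <- lapply(dl, function(d) d$value)
  N <- vapply(y, length, 1L)
  counts <- lapply(ia, function(i) tabulate(i, q))
  additive <- !isFALSE(spec$additive)
  use_pe <- vapply(seq_len(k), function(t) {
    pe <- spec$pe[[t]]
    if (!additive) FALSE
    else if (is.null(pe)) any(counts[[t]] > 1) else isTRUE(pe)
  }, TRUE)
  X <- lapply(seq_len(k), function(t)
    build_design(dl[[t]], spec$fixed[[t]], spec$covariate[[t]],
                 spec$degree[[t]]))
  XtX_R <- lapply(X, function(x) chol(crossprod(x)))
  balanced <- vapply(seq_len(k), function(t) {
    ct <- counts[[t]][counts[[t]] > 0]
    length(unique(ct)) == 1 && all(counts[[t]] > 0)
  }, TRUE)

  # pairing for the bivariate residual: identical (animal, day, time) keys
  paired <- FALSE
  if (k == 2) {
    key <- lapply(dl, function(d) {
      day <- if ("day" %in% names(d)) d$day else 1
      tim <- if ("time" %in% names(d)) d$time else 1
      paste(d$animal_id, day, tim)
    })
    paired <- length(key[[1]]) == length(key[[2]]) &&
      !anyDuplicated(key[[1]]) && setequal(key[[1]], key[[2]])
    if (paired) {
      ord2 <- match(key[[1]], key[[2]])
      dl[[2]] <- dl[[2]][ord2, , drop = FALSE]
      ia[[2]] <- ia[[2]][ord2]
      y[[2]] <- y[[2]][ord2]
      X[[2]] <- X[[2]][ord2, , drop = FALSE]
      XtX_R[[2]] <- chol(crossprod(X[[2]]))
    }
  }
  fast <- all(balanced) && (k == 1 || !paired || identical(ia[[1]], ia[[2]]))
  Ginv <- if (!all(balanced)) U %*% (t(U) / lam) else NULL

  set.seed(cfg$seed)
  # initial values
  beta <- lapply(seq_len(k), function(t)
    qr.coef(qr(X[[t]]), y[[t]]))
  vy <- vapply(y, var, 1)
  sa <- vy / 4
  spe <- ifelse(use_pe, vy / 4, 0)
  se <- vy / 2
  Sa <- diag(sa, k); Se <- diag(se, k)
  astar <- matrix(0, q, k)
  a <- matrix(0, q, k)
  pe <- matrix(0, q, k)
  fitted_rec <- function(t) {
    drop(X[[t]] %*% beta[[t]]) + a[ia[[t]], t] +
      (if (use_pe[t]) pe[ia[[t]], t] else 0)
  }

  n_store <- (cfg$chain - cfg$burnin) %/% cfg$thin
  vc_names <- if (k == 1) {
    c(if (additive) "sigma_a", if (use_pe[1]) "sigma_pe", "sigma_e")
  } else {
    c("sigma_a1", "sigma_a2", "cov_a12",
      if (use_pe[1]) "sigma_pe1", if (use_pe[2]) "sigma_pe2",
      "sigma_e1", "sigma_e2", "cov_e12")
  }
  draws <- matrix(NA_real_, n_store, length(vc_names) + 1,
                  dimnames = list(NULL, c(vc_names, "deviance")))
  gebv_mean <- matrix(0, q, k); gebv_m2 <- matrix(0, q, k)
  beta_mean <- lapply(beta, function(b) 0 * b)
  pe_mean <- matrix(0, q, k)
  se_mean <- 0 * Se
  n_acc <- 0

  for (iter in seq_len(cfg$chain)) {
    if (k == 1) {
      ## -- fixed effects
      r <- y[[1]] - a[ia[[1]], 1] - (if (use_pe[1]) pe[ia[[1]], 1] else 0)
      bhat <- backsolve(XtX_R[[1]],
                        forwardsolve(t(XtX_R[[1]]), crossprod(X[[1]], r)))
      beta[[1]] <- drop(bhat) +
        sqrt(se[1]) * backsolve(XtX_R[[1]], rnorm(ncol(X[[1]])))
      xb <- drop(X[[1]] %*% beta[[1]])
      ## -- additive block in the eigenbasis of G
      if (additive) {
      r1 <- y[[1]] - xb - (if (use_pe[1]) pe[ia[[1]], 1] else 0)
      s <- drop(rowsum(r1, ia[[1]], reorder = TRUE))
      sfull <- numeric(q); sfull[sort(unique(ia[[1]]))] <- s
      if (fast) {
        rhs <- crossprod(U, sfull) / se[1]
        prec <- counts[[1]][1] / se[1] + 1 / (lam * sa[1])
        astar[, 1] <- rhs / prec + rnorm(q) / sqrt(prec)
        a[, 1] <- U %*% astar[, 1]
      } else {
        P <- Ginv / sa[1]
        diag(P) <- diag(P) + counts[[1]] / se[1]
        R <- chol(P)
        mu <- backsolve(R, forwardsolve(t(R), sfull / se[1]))
        a[, 1] <- mu + backsolve(R, rnorm(q))
        astar[, 1] <- crossprod(U, a[, 1])
      }
      ## -- permanent environment
      if (use_pe[1]) {
        r2 <- y[[1]] - xb - a[ia[[1]], 1]
        s2 <- numeric(q)
        s2[sort(unique(ia[[1]]))] <- drop(rowsum(r2, ia[[1]], reorder = TRUE))
        precpe <- counts[[1]] / se[1] + 1 / spe[1]
        pe[, 1] <- (s2 / se[1]) / precpe + rnorm(q) / sqrt(precpe)
      }
      }
      ## -- variance components
      if (additive) {
        ssa <- sum(astar[, 1]^2 / lam)
        sa[1] <- ssa / rchisq(1, q + cfg$nu)
      }
      if (use_pe[1]) spe[1] <- sum(pe[, 1]^2) / rchisq(1, q + cfg$nu)
      e <- y[[1]] - fitted_rec(1)
      sse <- sum(e^2)
      se[1] <- sse / rchisq(1, N[1] + cfg$nu)
      dev <- N[1] * log(2 * pi * se[1]) + sse / se[1]
    } else {
      Sa_inv <- solve(Sa)
      Se_inv <- if (paired) solve(Se) else diag(1 / diag(Se))
      for (t in 1:2) {
        o <- 3 - t
        if (paired) {
          e_o <- y[[o]] - fitted_rec(o)
          g_e <- Se[t, o] / Se[o, o]
          se_c <- max(Se[t, t] - Se[t, o]^2 / Se[o, o], 1e-12 * Se[t, t])
          yadj <- y[[t]] - g_e * e_o
        } else {
          se_c <- Se[t, t]
          yadj <- y[[t]]
        }
        ## fixed effects
        r <- yadj - a[ia[[t]], t] - (if (use_pe[t]) pe[ia[[t]], t] else 0)
        bhat <- backsolve(XtX_R[[t]],
                          forwardsolve(t(XtX_R[[t]]), crossprod(X[[t]], r)))
        beta[[t]] <- drop(bhat) +
          sqrt(se_c) * backsolve(XtX_R[[t]], rnorm(ncol(X[[t]])))
        ## permanent environment
        if (use_pe[t]) {
          r2 <- yadj - drop(X[[t]] %*% beta[[t]]) - a[ia[[t]], t]
          s2 <- numeric(q)
          s2[sort(unique(ia[[t]]))] <- drop(rowsum(r2, ia[[t]], reorder = TRUE))
          precpe <- counts[[t]] / se_c + 1 / spe[t]
          pe[, t] <- (s2 / se_c) / precpe + rnorm(q) / sqrt(precpe)
        }
      }
      ## additive blocks: joint per eigen-index when fast, else conditional
      if (fast && paired) {
        S2 <- sapply(1:2, function(t) {
          r1 <- y[[t]] - drop(X[[t]] %*% beta[[t]]) -
            (if (use_pe[t]) pe[ia[[t]], t] else 0)
          sfull <- numeric(q)
          sfull[sort(unique(ia[[t]]))] <- drop(rowsum(r1, ia[[t]], reorder = TRUE))
          sfull
        })
        RHS <- crossprod(U, S2 %*% Se_inv)       # q x 2
        m1 <- counts[[1]][1]
        p11 <- m1 * Se_inv[1, 1] + Sa_inv[1, 1] / lam
        p22 <- m1 * Se_inv[2, 2] + Sa_inv[2, 2] / lam
        p12 <- m1 * Se_inv[1, 2] + Sa_inv[1, 2] / lam
        det <- p11 * p22 - p12^2
        v11 <- p22 / det; v22 <- p11 / det; v12 <- -p12 / det
        mu1 <- v11 * RHS[, 1] + v12 * RHS[, 2]
        mu2 <- v12 * RHS[, 1] + v22 * RHS[, 2]
        l11 <- sqrt(v11); l21 <- v12 / l11
        l22 <- sqrt(pmax(v22 - l21^2, 1e-300))
        z1 <- rnorm(q); z2 <- rnorm(q)
        astar[, 1] <- mu1 + l11 * z1
        astar[, 2] <- mu2 + l21 * z1 + l22 * z2
        a <- U %*% astar
      } else {
        for (t in 1:2) {
          o <- 3 - t
          g_a <- Sa[t, o] / Sa[o, o]
          sa_c <- max(Sa[t, t] - Sa[t, o]^2 / Sa[o, o], 1e-12 * Sa[t, t])
          if (paired) {
            e_o <- y[[o]] - fitted_rec(o)
            g_e <- Se[t, o] / Se[o, o]
            se_c <- max(Se[t, t] - Se[t, o]^2 / Se[o, o], 1e-12 * Se[t, t])
            yadj <- y[[t]] - g_e * e_o
          } else {
            se_c <- Se[t, t]
            yadj <- y[[t]]
          }
          r1 <- yadj - drop(X[[t]] %*% beta[[t]]) -
            (if (use_pe[t]) pe[ia[[t]], t] else 0)
          sfull <- numeric(q)
          sfull[sort(unique(ia[[t]]))] <- drop(rowsum(r1, ia[[t]], reorder = TRUE))
          if (balanced[t]) {
            rhs <- crossprod(U, sfull) / se_c + g_a * astar[, o] / (lam * sa_c)
            prec <- counts[[t]][1] / se_c + 1 / (lam * sa_c)
            astar[, t] <- rhs / prec + rnorm(q) / sqrt(prec)
            a[, t] <- U %*% astar[, t]
          } else {
            P <- Ginv / sa_c
            diag(P) <- diag(P) + counts[[t]] / se_c
            R <- chol(P)
            rhs <- sfull / se_c + (Ginv %*% (g_a * a[, o])) / sa_c
            mu <- backsolve(R, forwardsolve(t(R), rhs))
            a[, t] <- mu + backsolve(R, rnorm(q))
            astar[, t] <- crossprod(U, a[, t])
          }
        }
      }
      ## variance components
      W <- astar / sqrt(lam)
      Sa <- rinvwish(q - 3, crossprod(W))
      for (t in 1:2) if (use_pe[t])
        spe[t] <- sum(pe[, t]^2) / rchisq(1, q + cfg$nu)
      E <- lapply(1:2, function(t) y[[t]] - fitted_rec(t))
      if (paired) {
        SSE <- crossprod(cbind(E[[1]], E[[2]]))
        Se <- rinvwish(N[1] - 3, SSE)
        dev <- N[1] * (2 * log(2 * pi) + determinant(Se)$modulus[1]) +
          sum(diag(solve(Se, SSE)))
      } else {
        dev <- 0
        Se[1, 2] <- Se[2, 1] <- 0
        for (t in 1:2) {
          sse_t <- sum(E[[t]]^2)
          Se[t, t] <- sse_t / rchisq(1, N[t] + cfg$nu)
          dev <- dev + N[t] * log(2 * pi * Se[t, t]) + sse_t / Se[t, t]
        }
      }
      sa <- diag(Sa)
    }
    if (!all(is.finite(c(sa, spe[use_pe], diag(Se), dev))) ||
        any(diag(Se) > 1e12 * max(vy)))
      stop("gibbs_fit: divergent chain at iteration ", iter,
           " (variance overflow)")
    ## -- store
    if (iter > cfg$burnin && (iter - cfg$burnin) %% cfg$thin == 0) {
      n_acc <- n_acc + 1
      vals <- if (k == 1) {
        c(if (additive) sa[1], if (use_pe[1]) spe[1], se[1])
      } else {
        c(Sa[1, 1], Sa[2, 2], Sa[1, 2],
          if (use_pe[1]) spe[1], if (use_pe[2]) spe[2],
          Se[1, 1], Se[2, 2], Se[1, 2])
      }
      draws[n_acc, ] <- c(vals, dev)
      delta <- a - gebv_mean
      gebv_mean <- gebv_mean + delta / n_acc
      gebv_m2 <- gebv_m2 + delta * (a - gebv_mean)
      for (t in seq_len(k))
        beta_mean[[t]] <- beta_mean[[t]] + (beta[[t]] - beta_mean[[t]]) / n_acc
      pe_mean <- pe_mean + (pe - pe_mean) / n_acc
      if (k == 1) se_mean <- se_mean + (se[1] - se_mean) / n_acc
      else se_mean <- se_mean + (Se - se_mean) / n_acc
    }
    if (verbose && iter %% 5000 == 0)
      message("  iter ", iter, "/", cfg$chain)
  }

  ## deviance at the posterior-mean parameters (for DIC)
  dhat <- 0
  Ebar <- lapply(seq_len(k), function(t) {
    y[[t]] - drop(X[[t]] %*% beta_mean[[t]]) - gebv_mean[ia[[t]], t] -
      (if (use_pe[t]) pe_mean[ia[[t]], t] else 0)
  })
  if (k == 1) {
    dhat <- N[1] * log(2 * pi * se_mean) + sum(Ebar[[1]]^2) / se_mean
  } else if (paired) {
    SSEbar <- crossprod(cbind(Ebar[[1]], Ebar[[2]]))
    dhat <- N[1] * (2 * log(2 * pi) + determinant(se_mean)$modulus[1]) +
      sum(diag(solve(se_mean, SSEbar)))
  } else {
    for (t in 1:2)
      dhat <- dhat + N[t] * log(2 * pi * se_mean[t, t]) +
        sum(Ebar[[t]]^2) / se_mean[t, t]
  }

  dhat <- drop(dhat)
  gebv_sd <- sqrt(gebv_m2 / max(n_acc - 1, 1))
  dimnames(gebv_mean) <- dimnames(gebv_sd) <- list(animals, spec$traits)
  structure(list(draws = as.data.frame(draws[seq_len(n_acc), , drop = FALSE]),
                 gebv = list(mean = gebv_mean, sd = gebv_sd),
                 beta = beta_mean, deviance_at_mean = dhat,
                 animals = animals, use_pe = use_pe, paired = paired,
                 spec = spec, cfg = cfg, n_records = N),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("gibbs_fit:", paste(x$spec$traits, collapse = " + "), "|",
      length(x$animals), "animals |", paste(x$n_records, collapse = "/"),
      "records |", nrow(x$draws), "stored draws\n")
  print(round(colMeans(x$draws), 5))
  invisible(x)
}
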