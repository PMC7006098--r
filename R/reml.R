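## Average-information REML for mixed models
##   y = X beta + sum_r u_r + e,  u_r ~ N(0, K_r s2_r),  e ~ N(0, I s2_e)
## The restricted log-likelihood is
##   logL = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
## with V = sum_r s2_r K_r + s2_e I and P = Vi - Vi X (X'Vi X)^-1 X'Vi.
## Two computational paths share one iteration driver: a dense path for any
## number of random terms, and an eigendecomposition path for a single
## random term where V is diagonal in the rotated basis (the standard
## single-GRM trick, O(n) per iteration after one O(n^3) decomposition).

## ---- iteration driver ------------------------------------------------------

## eval_full(theta) -> list(logL, score, ai, ypkpy, trpk) or NULL (V not PD)
## eval_logl(theta) -> scalar logL or -Inf
.reml_iterate <- function(theta, eval_full, eval_logl, floor_val,
                          maxit = 200, tol_logl = 1e-6, tol_par = 1e-4,
                          em_iter = 2) {
  k <- length(theta)
  theta <- pmax(theta, floor_val)
  cur <- eval_full(theta)
  it <- 0L
  converged <- FALSE
  while (is.null(cur) && it < 20L) {  # inflate residual until V is PD
    theta[k] <- max(theta[k] * 10, floor_val * 10)
    cur <- eval_full(theta)
    it <- it + 1L
  }
  if (is.null(cur)) stop("could not find a positive-definite starting value",
                         call. = FALSE)
  for (it in seq_len(maxit)) {
    em_step <- function() {
      ratio <- ifelse(cur$trpk > 0, cur$ypkpy / cur$trpk, 1)
      ratio[!is.finite(ratio)] <- 1
      pmax(theta * pmin(pmax(ratio, 0.1), 10), floor_val)
    }
    ## components pinned at the floor whose score pulls further down are
    ## held there and dropped from the AI system (active-set constraint)
    active <- !(theta <= floor_val * 1.01 & cur$score < 0)
    if (it <= em_iter) {
      theta_new <- em_step()
    } else if (!any(active)) {
      converged <- TRUE
      break
    } else {
      a <- which(active)
      ai_a <- cur$ai[a, a, drop = FALSE]
      delta <- tryCatch(solve(ai_a + diag(1e-10 * max(diag(ai_a)),
                                          length(a)),
                              cur$score[a]),
                        error = function(e) NULL)
      theta_new <- NULL
      if (!is.null(delta) && all(is.finite(delta))) {
        for (hh in 0:4) {
          cand <- theta
          cand[a] <- cand[a] + delta / 2^hh
          cand <- pmax(cand, floor_val)
          ll <- eval_logl(cand)
          if (is.finite(ll) && ll >= cur$logL - 1e-10) {
            theta_new <- cand
            break
          }
        }
      }
      if (is.null(theta_new)) theta_new <- em_step()
    }
    nxt <- eval_full(theta_new)
    if (is.null(nxt)) {  # proposed V not PD; retreat halfway
      theta_new <- (theta + theta_new) / 2
      nxt <- eval_full(theta_new)
      if (is.null(nxt)) break
    }
    dlog <- abs(nxt$logL - cur$logL)
    dpar <- max(abs(theta_new - theta) / pmax(theta, floor_val * 100))
    theta <- theta_new
    cur <- nxt
    if (it > em_iter && dlog < tol_logl && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, eval = cur, iterations = it, converged = converged,
       boundary = theta <= floor_val * 1.01)
}

## ---- dense path ------------------------------------------------------------

.reml_dense_eval <- function(theta, y, X, Ks, n, p, full = TRUE) {
  k <- length(theta)
  V <- diag(theta[k], n)
  for (i in seq_len(k - 1L)) V <- V + theta[i] * Ks[[i]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdetV <- 2 * sum(log(diag(R)))
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cXt <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXt)) return(NULL)
  logdetXtViX <- 2 * sum(log(diag(cXt)))
  C <- chol2inv(cXt)
  beta <- C %*% crossprod(ViX, y)
  r <- y - X %*% beta
  Py <- Vi %*% r
  yPy <- sum(y * Py)
  logL <- -0.5 * (logdetV + logdetXtViX + yPy + (n - p) * log(2 * pi))
  if (!full) return(logL)

  Pfun <- function(v) Vi %*% v - ViX %*% (C %*% crossprod(ViX, v))
  KPy <- vector("list", k)
  trpk <- ypkpy <- numeric(k)
  for (i in seq_len(k)) {
    Ki_ViX <- if (i < k) Ks[[i]] %*% ViX else ViX
    KPy[[i]] <- if (i < k) Ks[[i]] %*% Py else Py
    trVK <- if (i < k) sum(Vi * Ks[[i]]) else sum(diag(Vi))
    trpk[i] <- trVK - sum(C * crossprod(ViX, Ki_ViX))
    ypkpy[i] <- sum(Py * KPy[[i]])
  }
  score <- -0.5 * (trpk - ypkpy)
  PKPy <- lapply(KPy, Pfun)
  ai <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ai[i, j] <- ai[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }
  }
  list(logL = logL, score = score, ai = ai, trpk = trpk, ypkpy = ypkpy,
       beta = beta, beta_cov = C, Py = Py)
}

## ---- eigen path (single random term) ---------------------------------------

.reml_eigen_setup <- function(y, X, K) {
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(lam = lam, U = e$vectors,
       yst = crossprod(e$vectors, y), Xst = crossprod(e$vectors, X))
}

.reml_eigen_eval <- function(theta, setup, n, p, full = TRUE) {
  v <- theta[1L] * setup$lam + theta[2L]
  if (any(v <= 0)) return(NULL)
  w <- 1 / v
  Xst <- setup$Xst
  yst <- setup$yst
  Xw <- Xst * w
  XtViX <- crossprod(Xst, Xw)
  cXt <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXt)) return(NULL)
  C <- chol2inv(cXt)
  beta <- C %*% crossprod(Xw, yst)
  r <- yst - Xst %*% beta
  Py <- w * r
  yPy <- sum(yst * Py)
  logL <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cXt))) + yPy +
                    (n - p) * log(2 * pi))
  if (!full) return(logL)

  Pfun <- function(z) w * z - Xw %*% (C %*% crossprod(Xw, z))
  KPy <- list(setup$lam * Py, Py)
  trpk <- c(sum(w * setup$lam) - sum(C * crossprod(Xw, setup$lam * Xw)),
            sum(w) - sum(C * crossprod(Xw, Xw)))
  ypkpy <- c(sum(Py * KPy[[1L]]), sum(Py * KPy[[2L]]))
  score <- -0.5 * (trpk - ypkpy)
  PKPy <- lapply(KPy, Pfun)
  ai <- matrix(0, 2, 2)
  for (i in 1:2) for (j in i:2) {
    ai[i, j] <- ai[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
  }
  list(logL = logL, score = score, ai = ai, trpk = trpk, ypkpy = ypkpy,
       beta = beta, beta_cov = C, Py = Py)
}

## ---- rotated two-term path (polygenic + locus) ------------------------------
## Scan fits share one eigendecomposition of G per chromosome: in the
## rotated basis G is diagonal (lam) and the locus matrix is Dst = U'DU.
## tr(Vi G) and tr(Vi) come from diag(Vi) = rowSums(R^-1^2), and tr(Vi D)
## from the identity tr(Vi V) = n, so no full inverse is ever formed.

.reml_rot_eval <- function(theta, su, Dst, full = TRUE) {
  n <- length(su$yst)
  V <- theta[2L] * Dst
  dix <- su$dix
  V[dix] <- V[dix] + theta[1L] * su$lam + theta[3L]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Ri <- backsolve(R, su$In)
  Vfun <- function(v) Ri %*% crossprod(Ri, v)
  X <- su$Xst
  yst <- su$yst
  ViX <- Vfun(X)
  XtViX <- crossprod(X, ViX)
  cXt <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXt)) return(NULL)
  C <- chol2inv(cXt)
  beta <- C %*% crossprod(ViX, yst)
  r <- yst - X %*% beta
  Py <- Vfun(r)
  yPy <- sum(yst * Py)
  logL <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(cXt))) + yPy +
                    (n - ncol(X)) * log(2 * pi))
  if (!full) return(logL)

  dVi <- rowSums(Ri^2)
  trVi <- sum(dVi)
  trViG <- sum(dVi * su$lam)
  trViD <- (n - theta[1L] * trViG - theta[3L] * trVi) / theta[2L]
  DViX <- Dst %*% ViX
  KViX <- list(su$lam * ViX, DViX, ViX)
  trVK <- c(trViG, trViD, trVi)
  KPy <- list(su$lam * Py, Dst %*% Py, Py)
  trpk <- ypkpy <- numeric(3L)
  for (i in 1:3) {
    trpk[i] <- trVK[i] - sum(C * crossprod(ViX, KViX[[i]]))
    ypkpy[i] <- sum(Py * KPy[[i]])
  }
  score <- -0.5 * (trpk - ypkpy)
  Pfun <- function(v) Vfun(v) - ViX %*% (C %*% crossprod(ViX, v))
  PKPy <- lapply(KPy, Pfun)
  ai <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    ai[i, j] <- ai[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
  }
  list(logL = logL, score = score, ai = ai, trpk = trpk, ypkpy = ypkpy,
       beta = beta, beta_cov = C, Py = Py)
}

## su: eigen setup from .reml_eigen_setup plus In and dix
.rot_setup <- function(y, X, G) {
  su <- .reml_eigen_setup(y, X, G)
  n <- length(y)
  su$In <- diag(n)
  su$dix <- seq.int(1L, n * n, by = n + 1L)
  su
}

.reml_core_rot <- function(su, Dst, vtot, init, maxit = 100, tol_logl = 1e-6,
                           tol_par = 1e-4, em_iter = 0) {
  floor_val <- 1e-8 * vtot
  ef <- function(th) .reml_rot_eval(th, su, Dst, TRUE)
  el <- function(th) {
    out <- .reml_rot_eval(th, su, Dst, FALSE)
    if (is.null(out)) -Inf else out
  }
  res <- .reml_iterate(init, ef, el, floor_val, maxit, tol_logl, tol_par,
                       em_iter)
  list(vc = res$theta, logL = res$eval$logL, iterations = res$iterations,
       converged = res$converged, boundary = res$boundary)
}

.reml_core <- function(y, X, Ks, init = NULL, maxit = 200, tol_logl = 1e-6,
                       tol_par = 1e-4, em_iter = 2, method = "auto",
                       eigen_setup = NULL) {
  n <- length(y)
  p <- ncol(X)
  vtot <- stats::var(y)
  if (!is.finite(vtot) || vtot <= 0) stop("response is constant", call. = FALSE)
  k <- length(Ks) + 1L
  floor_val <- 1e-8 * vtot
  if (is.null(init)) init <- rep(vtot / k, k)
  use_eigen <- (method == "eigen" || (method == "auto" && length(Ks) == 1L))
  if (use_eigen) {
    setup <- eigen_setup %||% .reml_eigen_setup(y, X, Ks[[1L]])
    ef <- function(th) .reml_eigen_eval(th, setup, n, p, TRUE)
    el <- function(th) {
      out <- .reml_eigen_eval(th, setup, n, p, FALSE)
      if (is.null(out)) -Inf else out
    }
  } else {
    ef <- function(th) .reml_dense_eval(th, y, X, Ks, n, p, TRUE)
    el <- function(th) {
      out <- .reml_dense_eval(th, y, X, Ks, n, p, FALSE)
      if (is.null(out)) -Inf else out
    }
  }
  res <- .reml_iterate(init, ef, el, floor_val, maxit, tol_logl, tol_par,
                       em_iter)
  ev <- res$eval
  vc_cov <- tryCatch(solve(ev$ai), error = function(e) matrix(NA_real_, k, k))
  list(vc = res$theta, logL = ev$logL, beta = as.vector(ev$beta),
       beta_cov = ev$beta_cov, ai = ev$ai, vc_cov = vc_cov, Py = ev$Py,
       iterations = res$iterations, converged = res$converged,
       boundary = res$boundary, n = n, p = p,
       method = if (use_eigen) "eigen" else "dense")
}

## ---- public fitting interface ----------------------------------------------

#' Fit a variance-component mixed model by average-information REML
#'
#' Maximizes the restricted likelihood of
#' `y = X beta + sum_r u_r + e`, with `u_r ~ N(0, K_r sigma2_r)` and
#' `e ~ N(0, I sigma2_e)`, over non-negative variance components.
#' The first `em_iter` iterations use stabilized expectation-maximization
#' style multiplicative updates; subsequent iterations take
#' average-information (AI) steps with step-halving and an EM fallback
#' whenever an AI step would decrease the likelihood or leave the
#' positive-definite region. Components whose updates go negative are
#' pinned at a floor of `1e-8 * var(y)` and flagged as boundary solutions.
#' Non-convergence within `maxit` gives a flagged fit, not an error:
#' binary codings of near-degenerate traits are expected to misbehave, and
#' downstream scans must see the flag rather than an exception.
#'
#' With a single random term the model is fitted in the eigenbasis of `K`,
#' where `V` is diagonal (fast path, identical likelihood); with several
#' terms a dense-matrix path is used.
#'
#' @param y numeric response (coded trait).
#' @param X fixed-effect design matrix; default intercept only. The
#'   conventional design for horn-trait mapping is intercept plus age at
#'   phenotyping.
#' @param K covariance matrix of a single random term, or a named list of
#'   such matrices (e.g. `list(polygenic = G, qtl = D)`).
#' @param init optional starting values (one per random term plus residual).
#' @param maxit,tol_logl,tol_par iteration cap and convergence tolerances
#'   (absolute log-likelihood change and relative parameter change).
#' @param em_iter number of initial EM-style iterations.
#' @param method `"auto"` (eigen path when a single random term), or force
#'   `"eigen"` / `"dense"`.
#' @return an object of class `reml_fit` with components `vc` (named
#'   variance components including `residual`), `vc_se`, `beta`, `logLik`,
#'   `iterations`, `converged`, `boundary`, and the data needed by the
#'   methods ([coef()], [logLik()], [residuals()], [simulate()], ...).
#' @examples
#' set.seed(1)
#' n <- 60
#' G <- tcrossprod(matrix(rnorm(n * 80), n)) / 80
#' y <- rnorm(n)
#' fit <- reml_fit(y, K = G)
#' fit
#' @export
reml_fit <- function(y, X = NULL, K, init = NULL, maxit = 200,
                     tol_logl = 1e-6, tol_par = 1e-4, em_iter = 2,
                     method = c("auto", "eigen", "dense")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) stop("'X' rows must match length(y)", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("'X' is not of full column rank", call. = FALSE)
  if (is.matrix(K)) K <- list(K)
  if (!is.list(K) || !all(vapply(K, is.matrix, logical(1)))) {
    stop("'K' must be a covariance matrix or a list of them", call. = FALSE)
  }
  if (is.null(names(K)) || any(names(K) == "")) {
    names(K) <- paste0("K", seq_along(K))
  }
  if (any(vapply(K, nrow, integer(1)) != n)) {
    stop("covariance matrices must be n x n", call. = FALSE)
  }
  if (n < ncol(X) + length(K) + 2L) {
    stop("too few observations for the number of parameters", call. = FALSE)
  }
  core <- .reml_core(y, X, K, init = init, maxit = maxit,
                     tol_logl = tol_logl, tol_par = tol_par,
                     em_iter = em_iter, method = method)
  vc <- stats::setNames(core$vc, c(names(K), "residual"))
  vc_se <- sqrt(pmax(diag(core$vc_cov), 0))
  structure(list(
    call = match.call(), vc = vc, vc_se = stats::setNames(vc_se, names(vc)),
    vc_cov = core$vc_cov, ai = core$ai,
    beta = stats::setNames(core$beta, colnames(X)), beta_cov = core$beta_cov,
    logLik = core$logL, iterations = core$iterations,
    converged = core$converged,
    boundary = stats::setNames(core$boundary, names(vc)),
    method = core$method, n = core$n, p = core$p,
    y = y, X = X, K = K, Py = core$Py), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("REML variance-component fit (", x$method, " path)\n", sep = "")
  tab <- cbind(estimate = x$vc, SE = x$vc_se)
  print(round(tab, digits))
  cat("logLik:", format(x$logLik, digits = 8),
      " iterations:", x$iterations,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  if (any(x$boundary)) {
    cat("boundary components:", paste(names(x$vc)[x$boundary], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  se <- sqrt(diag(as.matrix(object$beta_cov)))
  z <- object$beta / se
  fixef <- cbind(estimate = object$beta, SE = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)))
  vtot <- sum(object$vc)
  vcomp <- cbind(estimate = object$vc, SE = object$vc_se,
                 proportion = object$vc / vtot)
  out <- list(fixef = fixef, vcomp = vcomp, logLik = object$logLik,
              converged = object$converged, n = object$n,
              iterations = object$iterations)
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, digits = 4, ...) {
  cat("Variance components:\n")
  print(round(x$vcomp, digits))
  cat("\nFixed effects:\n")
  print(signif(x$fixef, digits))
  cat("\nlogLik:", format(x$logLik, digits = 8), " n:", x$n,
      " iterations:", x$iterations,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
vcov.reml_fit <- function(object, ...) object$beta_cov

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) + length(object$vc),
            nobs = object$n, class = "logLik")
}

#' Random-effect predictions (BLUPs) of a REML fit
#' @param fit a [reml_fit()] object.
#' @return named list of BLUP vectors, one per random term.
#' @export
random_effects <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  terms <- names(fit$K)
  out <- lapply(seq_along(fit$K), function(i) {
    as.vector(fit$vc[i] * (fit$K[[i]] %*% fit$Py))
  })
  stats::setNames(out, terms)
}

#' @export
fitted.reml_fit <- function(object, ...) {
  as.vector(object$X %*% object$beta)
}

#' @export
residuals.reml_fit <- function(object,
                               type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object)
  if (type == "conditional") {
    for (u in random_effects(object)) r <- r - u
  }
  r
}

#' @export
simulate.reml_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  V <- diag(object$vc[["residual"]], n)
  for (i in seq_along(object$K)) V <- V + object$vc[[i]] * object$K[[i]]
  R <- chol(V)
  mu <- fitted(object)
  out <- as.data.frame(mu + crossprod(R, matrix(stats::rnorm(n * nsim), n)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

## ---- likelihood-ratio testing ----------------------------------------------

#' Likelihood-ratio test between nested REML fits
#'
#' `LRT = -2 (logL(H0) - logL(H1))`, where H0 (e.g. polygenic-only) is
#' nested in H1 (adds the locus-specific QTL term). Numerically negative
#' values are clamped to 0; the raw value is kept as an attribute. If
#' either fit failed to converge the value is returned with a warning and
#' a `converged` attribute set to `FALSE`.
#'
#' @param fit_h1,fit_h0 the alternative and null [reml_fit()] objects (or
#'   any objects with `logLik` and `converged` fields).
#' @return the LRT value with attributes `raw` and `converged`.
#' @export
lrt <- function(fit_h1, fit_h0) {
  l1 <- if (is.numeric(fit_h1)) fit_h1 else fit_h1$logLik
  l0 <- if (is.numeric(fit_h0)) fit_h0 else fit_h0$logLik
  ok <- TRUE
  for (f in list(fit_h1, fit_h0)) {
    if (!is.numeric(f) && isFALSE(f$converged)) ok <- FALSE
  }
  raw <- -2 * (l0 - l1)
  if (!ok) warning("LRT computed from an unconverged fit", call. = FALSE)
  structure(max(0, raw), raw = raw, converged = ok)
}

#' Convert LRT values to p-values and -log10(p)
#'
#' Treats the LRT under the null as chi-squared with one degree of freedom
#' (the convention used for midpoint QTL tests; the true null at a variance
#' boundary is a 50:50 mixture of a point mass at 0 and chi-squared(1), so
#' this convention is conservative by at most a factor of two).
#'
#' @param lrt_value non-negative LRT value(s).
#' @return upper-tail chi-squared(1) probability.
#' @export
lrt_to_p <- function(lrt_value) {
  if (any(lrt_value < 0)) stop("LRT values must be non-negative", call. = FALSE)
  stats::pchisq(lrt_value, df = 1, lower.tail = FALSE)
}

#' @rdname lrt_to_p
#' @param p p-value(s) in (0, 1].
#' @export
p_to_neglog10 <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  -log10(p)
}

## ---- GREML SNP heritability -------------------------------------------------

#' GREML SNP-heritability with permutation validation
#'
#' Estimates the fraction of phenotypic variance captured by all SNPs,
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`, from a single-GRM REML fit.
#' The standard error follows from the average-information matrix by the
#' delta method. As validation, the phenotype is permuted across
#' individuals `n_permutations` times (covariates stay attached to the
#' individuals) and h2 re-estimated on each permuted vector; under
#' permutation the genome-phenotype link is broken, so permuted estimates
#' should collapse towards 0. The empirical p-value is the fraction of
#' permuted estimates at or above the observed one.
#'
#' @param y coded trait vector.
#' @param X fixed-effect design (default intercept only).
#' @param G genomic relationship matrix from [grm()].
#' @param n_permutations number of phenotype permutations.
#' @param seed integer seed for the permutations.
#' @return object of class `greml_h2`: `h2`, `se`, `fit` (the
#'   [reml_fit()]), `permuted` (vector of permuted estimates),
#'   `p_empirical`.
#' @export
greml_h2 <- function(y, X = NULL, G, n_permutations = 100, seed = 1) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  fit <- reml_fit(y, X, K = list(genomic = G), method = "eigen")
  h2_of <- function(vc) vc[1L] / sum(vc)
  h2 <- unname(h2_of(fit$vc))
  tot <- sum(fit$vc)
  grad <- c(fit$vc[["residual"]], -fit$vc[[1L]]) / tot^2
  se <- sqrt(max(0, drop(t(grad) %*% fit$vc_cov %*% grad)))

  setup <- .reml_eigen_setup(y, X, G)
  perm_h2 <- numeric(n_permutations)
  if (n_permutations > 0) {
    set.seed(as.integer(seed))
    for (b in seq_len(n_permutations)) {
      yp <- y[sample.int(n)]
      su <- setup
      su$yst <- crossprod(setup$U, yp)
      core <- .reml_core(yp, X, list(G), method = "eigen", eigen_setup = su)
      perm_h2[b] <- h2_of(core$vc)
    }
  }
  structure(list(h2 = h2, se = se, fit = fit, permuted = perm_h2,
                 p_empirical = if (n_permutations > 0) {
                   mean(perm_h2 >= h2)
                 } else NA_real_,
                 n_permutations = n_permutations),
            class = "greml_h2")
}

#' @export
print.greml_h2 <- function(x, ...) {
  cat(sprintf("GREML SNP-heritability: %.3f (SE %.3f)\n", x$h2, x$se))
  if (x$n_permutations > 0) {
    cat(sprintf("  %d permutations: mean permuted h2 = %.3f, empirical p = %.3g\n",
                x$n_permutations, mean(x$permuted), x$p_empirical))
  }
  if (!x$fit$converged) cat("  [fit NOT CONVERGED]\n")
  invisible(x)
}
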