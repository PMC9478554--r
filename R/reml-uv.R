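#' @importFrom stats model.matrix optimize var sd cor na.omit pt
NULL

## Build the fixed-effect design (intercept + sex + batch, treatment coding,
## first observed level as reference). Aliased columns are dropped with a
## warning; factors collapsing to a single level are omitted.
buildFixedDesign <- function(pheno, idx = seq_along(pheno@ids)) {
  df <- data.frame(sex = droplevels(pheno@sex[idx]),
                   batch = droplevels(pheno@batch[idx]))
  terms <- c(if (nlevels(df$sex) >= 2) "sex",
             if (nlevels(df$batch) >= 2) "batch")
  f <- if (length(terms)) paste("~", paste(terms, collapse = " + ")) else "~ 1"
  X <- model.matrix(as.formula(f), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping aliased fixed-effect columns: ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

## Extract one trait/time record vector aligned to the GRM ids (NA where
## unphenotyped) together with the fixed design rows for the same ids.
alignRecords <- function(grm, pheno, trait, time) {
  ids <- individualIds(grm)
  extra <- setdiff(pheno@ids, ids)
  if (length(extra))
    stop("phenotyped individuals missing from the GRM: ",
         paste(head(extra, 3), collapse = ", "))
  tv <- traitValues(pheno, trait)
  tlab <- as.character(time)
  if (!tlab %in% colnames(tv)) stop("unknown time point: ", time)
  y <- rep(NA_real_, length(ids))
  names(y) <- ids
  y[pheno@ids] <- tv[, tlab]
  Xp <- buildFixedDesign(pheno)
  X <- matrix(0, length(ids), ncol(Xp),
              dimnames = list(ids, colnames(Xp)))
  X[pheno@ids, ] <- Xp
  list(y = y, X = X)
}

## Eigendecompose a phenotyped submatrix of G, stabilizing once on failure.
eigenPSD <- function(Gs) {
  e <- eigen(Gs, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    e <- eigen(Gs + diag(1e-6, nrow(Gs)), symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      stop("GRM submatrix is not positive semi-definite even after stabilization")
  }
  e$values <- pmax(e$values, 0)
  e
}

## -2 x REML log-likelihood pieces in the rotated basis, at fixed weights
## w = 1/(sigma2u * d + sigma2e). Returns the GLS beta, residual quadratic,
## and the two log-determinants.
uvRotatedGLS <- function(Uy, UX, w) {
  XtWX <- crossprod(UX * w, UX)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(UX * w, Uy)))
  r <- Uy - UX %*% beta
  list(beta = drop(beta), q = sum(w * r^2),
       ldXVX = 2 * sum(log(diag(ch))), r = drop(r))
}

## -2 REML log-likelihood at explicit (sigma2u, sigma2e), rotated basis.
uvNeg2LogLik <- function(Uy, UX, d, sigma2u, sigma2e) {
  v <- sigma2u * d + sigma2e
  if (any(v <= 0)) return(Inf)
  w <- 1 / v
  gls <- uvRotatedGLS(Uy, UX, w)
  np <- length(Uy) - ncol(UX)
  np * log(2 * pi) + sum(log(v)) + gls$ldXVX + gls$q
}

#' REML log-likelihood of the univariate genomic model
#'
#' Evaluates the restricted log-likelihood of
#' `y = Xb + Zu + e`, `u ~ N(0, G sigma2u)`, `e ~ N(0, I sigma2e)` at given
#' variance components, using the eigen-rotation of the phenotyped GRM
#' submatrix. Mainly useful for diagnostics and for verifying fits against
#' direct dense computations.
#'
#' @param grm a [GRM-class]
#' @param pheno a [PhenotypeTable-class]
#' @param trait,time trait name and time-point label.
#' @param sigma2u,sigma2e variance components (both positive).
#' @return the REML log-likelihood (a scalar).
#' @export
uvREMLLogLik <- function(grm, pheno, trait, time, sigma2u, sigma2e) {
  al <- alignRecords(grm, pheno, trait, time)
  obs <- which(!is.na(al$y))
  e <- eigenPSD(grmMatrix(grm)[obs, obs])
  Uy <- crossprod(e$vectors, al$y[obs])
  UX <- crossprod(e$vectors, al$X[obs, , drop = FALSE])
  -0.5 * uvNeg2LogLik(Uy, UX, e$values, sigma2u, sigma2e)
}

#' Fit the univariate genomic animal model by REML
#'
#' Exact profiled REML: the phenotyped submatrix of `G` is eigendecomposed
#' once, the records and design are rotated, the residual variance is
#' profiled out, and the variance ratio `lambda = sigma2u/sigma2e` is
#' maximized by Brent search on `log(lambda)`. GEBVs are returned for every
#' individual in the GRM; unphenotyped ones are predicted purely through
#' their genomic relationships. The standard error of the heritability comes
#' from the inverse observed information of `(sigma2u, sigma2e)` by the
#' delta method.
#'
#' @param grm a [GRM-class] covering all phenotyped individuals.
#' @param pheno a [PhenotypeTable-class]
#' @param trait trait name.
#' @param time time-point label (one of `timePoints(pheno)`).
#' @param lambdaBounds search bounds for the variance ratio.
#' @param minRecords minimum number of phenotyped individuals (default 30).
#' @return a [UvFit-class]
#' @export
fitUvLMM <- function(grm, pheno, trait, time,
                     lambdaBounds = c(1e-6, 1e6), minRecords = 30) {
  stopifnot(is(grm, "GRM"), is(pheno, "PhenotypeTable"))
  al <- alignRecords(grm, pheno, trait, time)
  y <- al$y
  obs <- which(!is.na(y))
  if (length(obs) < minRecords)
    stop("need at least ", minRecords, " phenotyped individuals, got ",
         length(obs))
  X <- al$X[obs, , drop = FALSE]
  ids <- individualIds(grm)
  G <- grmMatrix(grm)
  e <- eigenPSD(G[obs, obs])
  Uy <- crossprod(e$vectors, y[obs])
  UX <- crossprod(e$vectors, X)
  d <- e$values
  n <- length(obs); p <- ncol(X); np <- n - p

  nEval <- 0L
  profiled <- function(loglam) {
    nEval <<- nEval + 1L
    lam <- exp(loglam)
    v <- lam * d + 1
    w <- 1 / v
    gls <- uvRotatedGLS(Uy, UX, w)
    s2e <- gls$q / np
    np * log(2 * pi) + np * log(s2e) + sum(log(v)) + gls$ldXVX + np
  }
  opt <- optimize(profiled, interval = log(lambdaBounds), tol = 1e-10)
  lam <- exp(opt$minimum)
  v <- lam * d + 1
  w <- 1 / v
  gls <- uvRotatedGLS(Uy, UX, w)
  s2e <- gls$q / np
  s2u <- lam * s2e
  loglik <- -0.5 * opt$objective

  ## boundary handling: genetic variance floored at 1e-8 x phenotypic var
  phenVar <- var(y[obs])
  boundary <- s2u < 1e-8 * phenVar
  if (boundary) s2u <- 0
  h2 <- if (s2u + s2e > 0) s2u / (s2u + s2e) else 0

  seH2 <- NA_real_
  if (!boundary) {
    seH2 <- tryCatch({
      f2 <- function(th) uvNeg2LogLik(Uy, UX, d, th[1], th[2])
      H <- numericHessian(f2, c(s2u, s2e))
      info <- H / 2
      covm <- solve(info)
      gr <- c(s2e, -s2u) / (s2u + s2e)^2
      se <- suppressWarnings(sqrt(drop(t(gr) %*% covm %*% gr)))
      if (is.finite(se)) se else NA_real_
    }, error = function(e) NA_real_)
  }

  ## V^{-1}(y - X beta) on the phenotyped set, back in the original basis
  wts <- w / s2e  # 1/(s2u d + s2e)
  m <- drop(e$vectors %*% (wts * gls$r))
  gebvAll <- drop(s2u * G[, obs, drop = FALSE] %*% m)
  names(gebvAll) <- ids
  beta <- gls$beta
  names(beta) <- colnames(X)

  new("UvFit", sigma2u = s2u, sigma2e = s2e, h2 = h2, seH2 = seH2,
      beta = beta, gebv = gebvAll, loglik = loglik, nIterations = nEval,
      converged = TRUE, boundary = boundary, phenIds = ids[obs],
      infoVec = m)
}

## Central-difference Hessian; steps scaled to the parameter magnitudes.
numericHessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- rel * (abs(x) + rel)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) {
      H[i, i] <- (f(x + h * (seq_len(k) == i)) - 2 * f(x) +
                    f(x - h * (seq_len(k) == i))) / h[i]^2
    } else {
      ei <- h * (seq_len(k) == i); ej <- h * (seq_len(k) == j)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' @describeIn predictGEBV BLUP of the genetic effect for the targets from a
#'   univariate fit: `sigma2u * G[target, phenotyped] V^{-1}(y - X beta)`.
#' @export
setMethod("predictGEBV", signature(fit = "UvFit"),
  function(fit, grm, targetIds) {
    ids <- individualIds(grm)
    bad <- setdiff(targetIds, ids)
    if (length(bad)) stop("unknown ids: ", paste(head(bad, 3), collapse = ", "))
    G <- grmMatrix(grm)
    drop(fit@sigma2u *
           G[targetIds, fit@phenIds, drop = FALSE] %*% fit@infoVec)
  })
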