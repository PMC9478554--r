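## Multivariate (T time points) genomic REML on the mixed-model equations.
##
## Model, records stacked trait-major with per-cell missingness:
##   y = Xb + Zu + e,  u ~ N(0, SigmaU x G),  e_i ~ N(0, SigmaE[s_i, s_i])
## per individual i with observed set s_i. All individuals in the GRM enter
## the random part, so unphenotyped animals are predicted through G.
##
## Estimation: EM burn-in (monotone, robust far from the optimum) followed
## by average-information (AI) updates with step halving and covariance
## bending.

## Symmetrize and floor eigenvalues at 1e-6 x trace/T (scale taken from the
## absolute diagonal so a wild update cannot collapse the floor to zero).
bendCov <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  scale <- max(sum(abs(diag(S))), max(abs(e$values)), 1e-12)
  floorv <- 1e-6 * scale / nrow(S)
  if (min(e$values) < floorv) {
    S <- e$vectors %*% (pmax(e$values, floorv) * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

## Per-individual inverse-residual weights grouped by missingness pattern.
## Returns Wn: n x T x T array with Wn[i, t, s] = (SigmaE[s_i, s_i]^{-1})[t, s]
## (zero-padded), plus log|R| and the pattern grouping.
residWeights <- function(SigmaE, O, patterns) {
  n <- nrow(O); T <- ncol(O)
  Wn <- array(0, c(n, T, T))
  logDetR <- 0
  for (pt in patterns) {
    o <- pt$obs
    if (!any(o)) next
    Ri <- solve(SigmaE[o, o, drop = FALSE])
    logDetR <- logDetR + length(pt$idx) * determinant(
      SigmaE[o, o, drop = FALSE], logarithm = TRUE)$modulus
    S <- matrix(0, T, T)
    S[o, o] <- Ri
    for (t in seq_len(T)) for (s in seq_len(T))
      if (S[t, s] != 0) Wn[pt$idx, t, s] <- S[t, s]
    pt$Ri <- Ri
  }
  list(Wn = Wn, logDetR = as.numeric(logDetR))
}

## Assemble and factorize the MME for given (SigmaU, SigmaE).
## State returned: solution, full inverse, log-likelihood and the pieces the
## EM and AI updates need.
mvMMESolve <- function(st, SigmaU, SigmaE) {
  n <- st$n; T <- st$T; p <- st$p
  rw <- tryCatch(residWeights(SigmaE, st$O, st$patterns),
                 error = function(e) NULL)
  if (is.null(rw)) return(NULL)
  Wn <- rw$Wn
  SuInv <- tryCatch(solve(SigmaU), error = function(e) NULL)
  if (is.null(SuInv)) return(NULL)
  dim <- T * p + T * n
  fIdx <- function(t) ((t - 1) * p + 1):(t * p)
  uIdx <- function(t) T * p + ((t - 1) * n + 1):(t * n)
  M <- matrix(0, dim, dim)
  Ry <- matrix(0, n, T)   # R^{-1} y as n x T
  for (t in seq_len(T)) for (s in seq_len(T)) {
    w <- Wn[, t, s]
    if (any(w != 0)) {
      Ry[, t] <- Ry[, t] + w * st$y0[, s]
      M[fIdx(t), fIdx(s)] <- crossprod(st$X, w * st$X)
      M[fIdx(t), uIdx(s)] <- t(st$X * w)
      M[uIdx(t), fIdx(s)] <- st$X * w
    }
    blk <- SuInv[t, s] * st$Gi
    if (any(w != 0)) {
      dg <- seq(1, n * n, by = n + 1)
      blk[dg] <- blk[dg] + w
    }
    M[uIdx(t), uIdx(s)] <- M[uIdx(t), uIdx(s)] + blk
  }
  rhs <- numeric(dim)
  for (t in seq_len(T)) {
    rhs[fIdx(t)] <- crossprod(st$X, Ry[, t])
    rhs[uIdx(t)] <- Ry[, t]
  }
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  logDetM <- 2 * sum(log(diag(ch)))
  logDetGstar <- n * determinant(SigmaU, logarithm = TRUE)$modulus +
    T * st$logDetG
  yPy <- sum(st$y0 * Ry) - sum(rhs * sol)
  neg2 <- (st$nObs - T * p) * log(2 * pi) + rw$logDetR +
    as.numeric(logDetGstar) + logDetM + yPy
  beta <- matrix(sol[seq_len(T * p)], p, T)
  Uh <- matrix(sol[(T * p + 1):dim], n, T)
  Cinv <- chol2inv(ch)
  list(loglik = -0.5 * neg2, beta = beta, Uh = Uh, Cinv = Cinv, Ry = Ry,
       Wn = Wn, SuInv = SuInv, fIdx = fIdx, uIdx = uIdx, rhs = rhs,
       sol = sol)
}

## Quantities shared by the EM and AI updates, derived from one MME solve.
mvDerived <- function(st, ms) {
  n <- st$n; T <- st$T; p <- st$p
  GiU <- st$Gi %*% ms$Uh
  H <- crossprod(ms$Uh, GiU)                   # uhat_t' G^{-1} uhat_s
  Q <- matrix(0, T, T)                         # tr(G^{-1} Cuu[t,s])
  Cbb <- Cbu <- vector("list", T * T)
  Rbb <- Rbu <- Duu <- array(0, c(n, T, T))
  at <- function(t, s) (t - 1) * T + s
  for (t in seq_len(T)) for (s in seq_len(T)) {
    cbb <- ms$Cinv[ms$fIdx(t), ms$fIdx(s), drop = FALSE]
    cbu <- ms$Cinv[ms$fIdx(t), ms$uIdx(s), drop = FALSE]
    cuu <- ms$Cinv[ms$uIdx(t), ms$uIdx(s), drop = FALSE]
    Q[t, s] <- sum(st$Gi * t(cuu))
    Rbb[, t, s] <- rowSums((st$X %*% cbb) * st$X)
    Rbu[, t, s] <- rowSums(t(cbu) * st$X)
    Duu[, t, s] <- diag(cuu)
    Cbb[[at(t, s)]] <- cbb
    Cbu[[at(t, s)]] <- cbu
  }
  ## residuals, zero at missing cells
  XB <- st$X %*% ms$beta
  Eh <- st$y0 - XB - ms$Uh
  Eh[!st$O] <- 0
  ## PY = R^{-1} ehat
  PY <- matrix(0, n, T)
  for (t in seq_len(T)) for (s in seq_len(T)) {
    w <- ms$Wn[, t, s]
    if (any(w != 0)) PY[, t] <- PY[, t] + w * Eh[, s]
  }
  list(GiU = GiU, H = H, Q = Q, Rbb = Rbb, Rbu = Rbu, Duu = Duu,
       Eh = Eh, PY = PY)
}

## One EM update of (SigmaU, SigmaE). Monotone in the REML log-likelihood.
mvEMUpdate <- function(st, ms, dv, SigmaU, SigmaE) {
  n <- st$n; T <- st$T
  SuNew <- (dv$H + dv$Q) / n
  SuNew <- (SuNew + t(SuNew)) / 2
  ## residual update: complete-data residual second moments per individual
  SeAcc <- matrix(0, T, T)
  for (pt in st$patterns) {
    o <- pt$obs
    if (!any(o)) next
    idx <- pt$idx
    no <- sum(o)
    ## L maps observed residuals to the full T-vector expectation
    L <- matrix(0, T, no)
    L[which(o) + (seq_len(no) - 1) * T] <- 1   # identity rows for observed
    Cnd <- matrix(0, T, T)
    if (any(!o)) {
      Roo <- SigmaE[o, o, drop = FALSE]
      Rmo <- SigmaE[!o, o, drop = FALSE]
      B <- Rmo %*% solve(Roo)
      L[!o, ] <- B
      Cnd[!o, !o] <- SigmaE[!o, !o, drop = FALSE] - B %*% t(Rmo)
    }
    Em <- dv$Eh[idx, o, drop = FALSE] %*% t(L)      # expected full residuals
    ## posterior uncertainty of the observed residuals, summed over the group
    PhiSum <- matrix(0, no, no)
    ot <- which(o)
    for (a in seq_len(no)) for (b in seq_len(no)) {
      ta <- ot[a]; tb <- ot[b]
      PhiSum[a, b] <- sum(dv$Rbb[idx, ta, tb]) + sum(dv$Rbu[idx, ta, tb]) +
        sum(dv$Rbu[idx, tb, ta]) + sum(dv$Duu[idx, ta, tb])
    }
    SeAcc <- SeAcc + crossprod(Em) + length(idx) * Cnd +
      L %*% PhiSum %*% t(L)
  }
  SeNew <- SeAcc / st$nE
  list(SigmaU = bendCov(SuNew), SigmaE = bendCov((SeNew + t(SeNew)) / 2))
}

## REML scores and AI matrix for theta = (vech SigmaU, vech SigmaE).
mvAIStep <- function(st, ms, dv, SigmaU, SigmaE) {
  n <- st$n; T <- st$T
  pars <- list()
  for (t in seq_len(T)) for (s in t:T) pars <- c(pars, list(c("u", t, s)))
  for (t in seq_len(T)) for (s in t:T) pars <- c(pars, list(c("e", t, s)))
  np <- length(pars)
  score <- numeric(np)
  Fv <- Gv <- vector("list", np)
  RHS <- vector("list", np)
  SuInv <- ms$SuInv
  for (k in seq_len(np)) {
    pk <- pars[[k]]
    t <- as.integer(pk[2]); s <- as.integer(pk[3])
    E <- matrix(0, T, T); E[t, s] <- E[t, s] + 1; E[s, t] <- E[s, t] + 1
    if (t == s) E[t, t] <- 1
    if (pk[1] == "u") {
      A <- SuInv %*% E %*% SuInv
      tr1 <- n * sum(E * SuInv)
      tr2 <- sum(A * t(dv$Q))
      quad <- sum(A * dv$H)
      score[k] <- -0.5 * (tr1 - tr2 - quad)
      Fm <- ms$Uh %*% t(E %*% SuInv)
      Fm[!st$O] <- 0
    } else {
      trR <- if (t == s) sum(ms$Wn[, t, t]) else 2 * sum(ms$Wn[, t, s])
      trCM <- 0
      for (a in seq_len(T)) for (b in seq_len(T)) {
        if (t == s) w2 <- ms$Wn[, a, t] * ms$Wn[, t, b]
        else w2 <- ms$Wn[, a, t] * ms$Wn[, s, b] + ms$Wn[, a, s] * ms$Wn[, t, b]
        if (any(w2 != 0))
          trCM <- trCM + sum(w2 * (dv$Rbb[, a, b] + 2 * dv$Rbu[, a, b] +
                                     dv$Duu[, a, b]))
      }
      quad <- if (t == s) sum(dv$PY[, t]^2) else 2 * sum(dv$PY[, t] * dv$PY[, s])
      score[k] <- -0.5 * (trR - trCM - quad)
      Fm <- matrix(0, n, T)
      if (t == s) {
        Fm[, t] <- dv$PY[, t]
      } else {
        both <- st$O[, t] & st$O[, s]
        Fm[both, t] <- dv$PY[both, s]
        Fm[both, s] <- dv$PY[both, t]
      }
    }
    ## g = R^{-1} f and the MME right-hand side built from f
    Gm <- matrix(0, n, T)
    for (a in seq_len(T)) for (b in seq_len(T)) {
      w <- ms$Wn[, a, b]
      if (any(w != 0)) Gm[, a] <- Gm[, a] + w * Fm[, b]
    }
    r <- numeric(T * st$p + T * n)
    for (a in seq_len(T)) {
      r[ms$fIdx(a)] <- crossprod(st$X, Gm[, a])
      r[ms$uIdx(a)] <- Gm[, a]
    }
    Fv[[k]] <- Fm; Gv[[k]] <- Gm; RHS[[k]] <- r
  }
  SOL <- ms$Cinv %*% do.call(cbind, RHS)
  AI <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in i:np) {
    AI[i, j] <- AI[j, i] <-
      0.5 * (sum(Fv[[i]] * Gv[[j]]) - sum(RHS[[i]] * SOL[, j]))
  }
  list(score = score, AI = AI, pars = pars)
}

applyDelta <- function(SigmaU, SigmaE, pars, delta) {
  T <- nrow(SigmaU)
  Su <- SigmaU; Se <- SigmaE
  for (k in seq_along(pars)) {
    pk <- pars[[k]]
    t <- as.integer(pk[2]); s <- as.integer(pk[3])
    if (pk[1] == "u") {
      Su[t, s] <- Su[t, s] + delta[k]; if (t != s) Su[s, t] <- Su[t, s]
    } else {
      Se[t, s] <- Se[t, s] + delta[k]; if (t != s) Se[s, t] <- Se[t, s]
    }
  }
  list(SigmaU = bendCov(Su), SigmaE = bendCov(Se))
}

## ---------------------------------------------------------------------------
## Complete-record engine (canonical transformation). When every phenotyped
## individual carries records at all T time points, eigendecomposing the
## phenotyped GRM submatrix block-diagonalizes the model into independent
## 3x3 problems per eigencomponent: component k has covariance
## V_k = d_k SigmaU + SigmaE. All EM and AI quantities are then O(n) per
## iteration and G is never inverted.

## Solve the rotated GLS at given (SigmaU, SigmaE). Yt, Xt are the rotated
## records/design; d the eigenvalues. Returns NULL when a V_k is singular.
cdSolve <- function(cd, SigmaU, SigmaE) {
  m <- nrow(cd$Yt); T <- ncol(cd$Yt); p <- ncol(cd$Xt)
  Vinv <- array(0, c(T, T, m))
  logDetV <- 0
  for (k in seq_len(m)) {
    Vk <- cd$d[k] * SigmaU + SigmaE
    ch <- tryCatch(chol(Vk), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logDetV <- logDetV + 2 * sum(log(diag(ch)))
    Vinv[, , k] <- chol2inv(ch)
  }
  fBlk <- function(t) ((t - 1) * p + 1):(t * p)
  F <- matrix(0, T * p, T * p)
  rhs <- numeric(T * p)
  for (t in seq_len(T)) {
    acc <- 0
    for (s in seq_len(T)) {
      F[fBlk(t), fBlk(s)] <- crossprod(cd$Xt, Vinv[t, s, ] * cd$Xt)
      acc <- acc + Vinv[t, s, ] * cd$Yt[, s]
    }
    rhs[fBlk(t)] <- crossprod(cd$Xt, acc)
  }
  chF <- tryCatch(chol(F), error = function(e) NULL)
  if (is.null(chF)) return(NULL)
  b <- backsolve(chF, forwardsolve(t(chF), rhs))
  B <- matrix(b, p, T)
  Rm <- cd$Yt - cd$Xt %*% B
  Mw <- matrix(0, m, T)                       # V^{-1}(y - Xb) per component
  for (t in seq_len(T)) for (s in seq_len(T))
    Mw[, t] <- Mw[, t] + Vinv[t, s, ] * Rm[, s]
  yPy <- sum(Rm * Mw)
  neg2 <- (m * T - T * p) * log(2 * pi) + logDetV +
    2 * sum(log(diag(chF))) + yPy
  list(loglik = -0.5 * neg2, B = B, Rm = Rm, Mw = Mw, Vinv = Vinv,
       Finv = chol2inv(chF), fBlk = fBlk)
}

## P_kk = V_k^{-1} - V_k^{-1} X_k F^{-1} X_k' V_k^{-1} per component
## (the REML projection restricted to component k).
cdProjection <- function(cd, sol) {
  m <- nrow(cd$Yt); T <- ncol(cd$Yt)
  Avec <- array(0, c(T, T, m))
  for (t in seq_len(T)) for (s in seq_len(T))
    Avec[t, s, ] <- rowSums((cd$Xt %*%
      sol$Finv[sol$fBlk(t), sol$fBlk(s), drop = FALSE]) * cd$Xt)
  Pkk <- sol$Vinv
  for (t in seq_len(T)) for (s in seq_len(T)) {
    corr <- 0
    for (a in seq_len(T)) for (b in seq_len(T))
      corr <- corr + sol$Vinv[t, a, ] * Avec[a, b, ] * sol$Vinv[b, s, ]
    Pkk[t, s, ] <- Pkk[t, s, ] - corr
  }
  Pkk
}

cdEMUpdate <- function(cd, sol, Pkk, SigmaU, SigmaE) {
  m <- nrow(cd$Yt); T <- ncol(cd$Yt)
  pos <- cd$d > 1e-10 * max(cd$d)
  mPos <- sum(pos)
  dP <- ifelse(pos, cd$d, 0)
  sumdPkk <- matrix(0, T, T)
  sumPkk <- matrix(0, T, T)
  for (t in seq_len(T)) for (s in seq_len(T)) {
    sumdPkk[t, s] <- sum(dP * Pkk[t, s, ])
    sumPkk[t, s] <- sum(Pkk[t, s, ])
  }
  term1 <- SigmaU %*% crossprod(sol$Mw, sol$Mw * dP) %*% SigmaU
  SuNew <- (term1 + mPos * SigmaU - SigmaU %*% sumdPkk %*% SigmaU) / mPos
  Uh <- (sol$Mw %*% SigmaU) * cd$d
  Eh <- sol$Rm - Uh
  SeNew <- (crossprod(Eh) + m * SigmaE -
              SigmaE %*% sumPkk %*% SigmaE) / m
  list(SigmaU = bendCov((SuNew + t(SuNew)) / 2),
       SigmaE = bendCov((SeNew + t(SeNew)) / 2))
}

cdAIStep <- function(cd, sol, Pkk, SigmaU, SigmaE) {
  m <- nrow(cd$Yt); T <- ncol(cd$Yt)
  pars <- list()
  for (t in seq_len(T)) for (s in t:T) pars <- c(pars, list(c("u", t, s)))
  for (t in seq_len(T)) for (s in t:T) pars <- c(pars, list(c("e", t, s)))
  np <- length(pars)
  score <- numeric(np)
  Fms <- Gms <- Sxv <- vector("list", np)
  for (i in seq_len(np)) {
    pk <- pars[[i]]
    t <- as.integer(pk[2]); s <- as.integer(pk[3])
    cvec <- if (pk[1] == "u") cd$d else rep(1, m)
    ## f = V_i Py per component
    Fm <- matrix(0, m, T)
    if (t == s) {
      Fm[, t] <- cvec * sol$Mw[, t]
      trP <- sum(cvec * Pkk[t, t, ])
      quad <- sum(cvec * sol$Mw[, t]^2)
    } else {
      Fm[, t] <- cvec * sol$Mw[, s]
      Fm[, s] <- cvec * sol$Mw[, t]
      trP <- 2 * sum(cvec * Pkk[t, s, ])
      quad <- 2 * sum(cvec * sol$Mw[, t] * sol$Mw[, s])
    }
    score[i] <- -0.5 * (trP - quad)
    ## P f = V^{-1} f - V^{-1} X F^{-1} X' V^{-1} f
    Gm <- matrix(0, m, T)
    for (a in seq_len(T)) for (b in seq_len(T))
      Gm[, a] <- Gm[, a] + sol$Vinv[a, b, ] * Fm[, b]
    h <- unlist(lapply(seq_len(T), function(a) crossprod(cd$Xt, Gm[, a])))
    fs <- sol$Finv %*% h
    Sx <- vapply(seq_len(T), function(a)
      drop(cd$Xt %*% fs[sol$fBlk(a)]), numeric(m))
    SxV <- matrix(0, m, T)
    for (a in seq_len(T)) for (b in seq_len(T))
      SxV[, a] <- SxV[, a] + sol$Vinv[a, b, ] * Sx[, b]
    Fms[[i]] <- Fm; Gms[[i]] <- Gm; Sxv[[i]] <- SxV
  }
  AI <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in i:np)
    AI[i, j] <- AI[j, i] <-
      0.5 * sum(Fms[[i]] * (Gms[[j]] - Sxv[[j]]))
  list(score = score, AI = AI, pars = pars)
}

## Full EM + AI schedule on the rotated representation.
fitMvComplete <- function(cd, vt, emIterations, maxIterations, tol, verbose) {
  T <- ncol(cd$Yt)
  SigmaU <- diag(vt / 2, T)
  SigmaE <- diag(vt / 2, T)
  sol <- cdSolve(cd, SigmaU, SigmaE)
  if (is.null(sol)) stop("initial rotated equations are not positive definite")
  trace <- sol$loglik
  convergedFlag <- FALSE
  iter <- 0L
  while (iter < maxIterations) {
    iter <- iter + 1L
    Pkk <- cdProjection(cd, sol)
    if (iter <= emIterations) {
      up <- cdEMUpdate(cd, sol, Pkk, SigmaU, SigmaE)
      solNew <- cdSolve(cd, up$SigmaU, up$SigmaE)
      if (is.null(solNew)) break
      SigmaU <- up$SigmaU; SigmaE <- up$SigmaE; sol <- solNew
    } else {
      ai <- cdAIStep(cd, sol, Pkk, SigmaU, SigmaE)
      delta <- tryCatch(solve(ai$AI + diag(1e-10, nrow(ai$AI)), ai$score),
                        error = function(e) NULL)
      accepted <- FALSE
      if (!is.null(delta)) {
        step <- 1
        for (half in 1:10) {
          cand <- applyDelta(SigmaU, SigmaE, ai$pars, step * delta)
          solNew <- cdSolve(cd, cand$SigmaU, cand$SigmaE)
          if (!is.null(solNew) && solNew$loglik >= sol$loglik - 1e-10) {
            SigmaU <- cand$SigmaU; SigmaE <- cand$SigmaE; sol <- solNew
            accepted <- TRUE
            break
          }
          step <- step / 2
        }
      }
      if (!accepted) {
        up <- cdEMUpdate(cd, sol, Pkk, SigmaU, SigmaE)
        solNew <- cdSolve(cd, up$SigmaU, up$SigmaE)
        if (is.null(solNew)) break
        SigmaU <- up$SigmaU; SigmaE <- up$SigmaE; sol <- solNew
      }
    }
    trace <- c(trace, sol$loglik)
    if (verbose) message(sprintf("iter %3d  logLik %.6f", iter, sol$loglik))
    nt <- length(trace)
    if (iter > emIterations &&
        abs(trace[nt] - trace[nt - 1]) < tol * (abs(trace[nt - 1]) + 1)) {
      convergedFlag <- TRUE
      break
    }
  }
  list(SigmaU = SigmaU, SigmaE = SigmaE, sol = sol, trace = trace,
       iter = iter, converged = convergedFlag)
}

#' Fit the multivariate (multi-age) genomic model by REML
#'
#' Treats the records of one trait at each time point as distinct traits
#' with genetic covariance `SigmaU x G` (Kronecker) and residual covariance
#' `SigmaE x I`, allowing arbitrary per-cell missing records (each time
#' point enters through its own incidence). When every phenotyped animal
#' carries records at all time points (complete designs, including the
#' leave-all-out cross-validation strategy), the model is solved in the
#' eigenbasis of the phenotyped GRM submatrix, where it decouples into
#' independent per-component blocks and `G` is never inverted; partial
#' patterns use the full mixed-model equations. Either way estimation runs
#' a monotone EM burn-in for stability, then average-information REML with
#' step halving;
#' any non-positive-definite covariance proposal is bent (eigenvalue floor
#' at `1e-6 x trace/T`). GEBVs are produced for every individual in the GRM
#' at every time point.
#'
#' @param grm a [GRM-class] covering all phenotyped individuals.
#' @param pheno a [PhenotypeTable-class]
#' @param trait trait name.
#' @param emIterations EM burn-in iterations (default 8).
#' @param maxIterations total iteration cap (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param minRecords minimum records per time point (default 30).
#' @param verbose print the iteration trace.
#' @return an [MvFit-class]. Non-convergence is flagged, not an error.
#' @export
fitMvLMM <- function(grm, pheno, trait, emIterations = 8,
                     maxIterations = 200, tol = 1e-8, minRecords = 30,
                     verbose = FALSE) {
  stopifnot(is(grm, "GRM"), is(pheno, "PhenotypeTable"))
  ids <- individualIds(grm)
  extra <- setdiff(pheno@ids, ids)
  if (length(extra))
    stop("phenotyped individuals missing from the GRM: ",
         paste(head(extra, 3), collapse = ", "))
  tv <- traitValues(pheno, trait)
  T <- ncol(tv)
  n <- length(ids)
  Y <- matrix(NA_real_, n, T, dimnames = list(ids, colnames(tv)))
  Y[pheno@ids, ] <- tv
  O <- !is.na(Y)
  if (any(colSums(O) < minRecords))
    stop("need at least ", minRecords, " records per time point")
  Xp <- buildFixedDesign(pheno)
  X <- matrix(0, n, ncol(Xp), dimnames = list(ids, colnames(Xp)))
  X[pheno@ids, ] <- Xp

  ## Complete-record case (every animal has all T records or none): use the
  ## canonical transformation — eigendecompose once, iterate in O(n), never
  ## invert G.
  nrec <- rowSums(O)
  if (all(nrec %in% c(0L, T))) {
    P <- which(nrec == T)
    e <- eigenPSD(grmMatrix(grm)[P, P])
    cd <- list(Yt = crossprod(e$vectors, Y[P, , drop = FALSE]),
               Xt = crossprod(e$vectors, X[P, , drop = FALSE]),
               d = e$values)
    vt <- apply(Y, 2, var, na.rm = TRUE)
    res <- fitMvComplete(cd, vt, emIterations, maxIterations, tol, verbose)
    SigmaU <- res$SigmaU; SigmaE <- res$SigmaE
    dSu <- diag(SigmaU); dSe <- diag(SigmaE)
    PY <- matrix(0, n, T, dimnames = list(ids, colnames(tv)))
    PY[P, ] <- e$vectors %*% res$sol$Mw
    gebvM <- grmMatrix(grm) %*% PY %*% SigmaU
    dimnames(gebvM) <- list(ids, colnames(tv))
    beta <- as.numeric(res$sol$B)
    names(beta) <- as.vector(outer(colnames(Xp), colnames(tv),
                                   function(a, b) paste(b, a, sep = ":")))
    recIds <- lapply(seq_len(T), function(t) ids[O[, t]])
    names(recIds) <- colnames(tv)
    return(new("MvFit", SigmaU = SigmaU, SigmaE = SigmaE,
               geneticCorr = SigmaU / sqrt(outer(dSu, dSu)),
               h2 = as.numeric(dSu / (dSu + dSe)), gebv = gebvM,
               beta = beta, loglik = res$sol$loglik,
               loglikTrace = res$trace, nIterations = res$iter,
               converged = res$converged, PY = PY, recordIds = recIds,
               times = pheno@times))
  }

  ## Invert G once. In-sample-frequency GRMs are singular (rows sum to 0),
  ## so the inverse only exists after a diagonal shift; 1e-4 x mean(diag)
  ## keeps the equations well conditioned while moving the estimates by far
  ## less than their sampling error (the shift adds that fraction of
  ## individual-specific genetic variance).
  G <- grmMatrix(grm)
  chG <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(chG) || min(diag(chG)) < 1e-4 * max(diag(chG))) {
    G <- G + diag(1e-4 * mean(diag(G)), n)
    chG <- chol(G)
  }
  Gi <- chol2inv(chG)
  logDetG <- 2 * sum(log(diag(chG)))

  key <- O %*% 2^(seq_len(T) - 1)
  patterns <- lapply(unique(key[key > 0]), function(k) {
    list(obs = as.logical(O[match(k, key), ]), idx = which(key == k))
  })
  y0 <- Y; y0[!O] <- 0
  st <- list(n = n, T = T, p = ncol(X), X = X, O = O, y0 = y0, Gi = Gi,
             logDetG = logDetG, patterns = patterns, nObs = sum(O),
             nE = sum(key > 0))

  ## starting values: half the per-time-point phenotypic variance each
  vt <- apply(Y, 2, var, na.rm = TRUE)
  SigmaU <- diag(vt / 2, T)
  SigmaE <- diag(vt / 2, T)

  ms <- mvMMESolve(st, SigmaU, SigmaE)
  if (is.null(ms)) stop("initial mixed-model equations are not positive definite")
  trace <- ms$loglik
  convergedFlag <- FALSE
  iter <- 0L
  while (iter < maxIterations) {
    iter <- iter + 1L
    dv <- mvDerived(st, ms)
    if (iter <= emIterations) {
      up <- mvEMUpdate(st, ms, dv, SigmaU, SigmaE)
      msNew <- mvMMESolve(st, up$SigmaU, up$SigmaE)
      if (is.null(msNew)) break
      SigmaU <- up$SigmaU; SigmaE <- up$SigmaE; ms <- msNew
    } else {
      ai <- mvAIStep(st, ms, dv, SigmaU, SigmaE)
      delta <- tryCatch(solve(ai$AI + diag(1e-10, nrow(ai$AI)), ai$score),
                        error = function(e) NULL)
      accepted <- FALSE
      if (!is.null(delta)) {
        step <- 1
        for (half in 1:10) {
          cand <- applyDelta(SigmaU, SigmaE, ai$pars, step * delta)
          msNew <- mvMMESolve(st, cand$SigmaU, cand$SigmaE)
          if (!is.null(msNew) && msNew$loglik >= ms$loglik - 1e-10) {
            SigmaU <- cand$SigmaU; SigmaE <- cand$SigmaE; ms <- msNew
            accepted <- TRUE
            break
          }
          step <- step / 2
        }
      }
      if (!accepted) {
        ## fall back to one EM step when AI cannot improve
        up <- mvEMUpdate(st, ms, dv, SigmaU, SigmaE)
        msNew <- mvMMESolve(st, up$SigmaU, up$SigmaE)
        if (is.null(msNew)) break
        SigmaU <- up$SigmaU; SigmaE <- up$SigmaE; ms <- msNew
      }
    }
    trace <- c(trace, ms$loglik)
    if (verbose)
      message(sprintf("iter %3d  logLik %.6f", iter, ms$loglik))
    nt <- length(trace)
    if (iter > emIterations &&
        abs(trace[nt] - trace[nt - 1]) < tol * (abs(trace[nt - 1]) + 1)) {
      convergedFlag <- TRUE
      break
    }
  }

  dSu <- diag(SigmaU); dSe <- diag(SigmaE)
  h2 <- dSu / (dSu + dSe)
  gcor <- SigmaU / sqrt(outer(dSu, dSu))
  dv <- mvDerived(st, ms)
  gebvM <- ms$Uh
  dimnames(gebvM) <- list(ids, colnames(tv))
  beta <- as.numeric(ms$beta)
  names(beta) <- as.vector(outer(colnames(Xp), colnames(tv),
                                 function(a, b) paste(b, a, sep = ":")))
  recIds <- lapply(seq_len(T), function(t) ids[O[, t]])
  names(recIds) <- colnames(tv)
  PY <- dv$PY
  dimnames(PY) <- list(ids, colnames(tv))
  new("MvFit", SigmaU = SigmaU, SigmaE = SigmaE, geneticCorr = gcor,
      h2 = as.numeric(h2), gebv = gebvM, beta = beta, loglik = ms$loglik,
      loglikTrace = trace, nIterations = iter, converged = convergedFlag,
      PY = PY, recordIds = recIds, times = pheno@times)
}

#' @describeIn predictGEBV BLUP for the targets at every time point from a
#'   multivariate fit: `G[target, ] %*% PY %*% SigmaU`.
#' @export
setMethod("predictGEBV", signature(fit = "MvFit"),
  function(fit, grm, targetIds) {
    ids <- individualIds(grm)
    bad <- setdiff(targetIds, ids)
    if (length(bad)) stop("unknown ids: ", paste(head(bad, 3), collapse = ", "))
    G <- grmMatrix(grm)
    out <- G[targetIds, rownames(fit@PY), drop = FALSE] %*% fit@PY %*% fit@SigmaU
    dimnames(out) <- list(targetIds, colnames(fit@PY))
    out
  })
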