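# Model-to-data fit: flat bulk-solvent + anisotropic scale model, R factors,
# merohedral twin laws and twin-fraction refinement, TLS ADP reconstruction
# and the total-versus-residual convention heuristic, header cutoffs.

.scaleModel <- function(kOverall = 1, bOverall = 0, uCryst = matrix(0, 3, 3),
                        kSol = 0, bSol = 0)
  new("ScaleModel", kOverall = kOverall, bOverall = bOverall,
      uCryst = uCryst, kSol = kSol, bSol = bSol)

# Anisotropy/overall-B factor a(h) = exp(-bOverall s^2/4 - 2 pi^2 s'Us).
.anisoFactor <- function(scale, s) {
  s2 <- rowSums(s * s)
  q <- rowSums((s %*% scale@uCryst) * s)
  exp(-scale@bOverall * s2 / 4 - 2 * pi^2 * q)
}

#' Bulk-solvent-corrected, scaled model amplitudes
#'
#' F_model(h) = kOverall exp(-bOverall s^2/4) exp(-2 pi^2 s'U_cryst s)
#' |F_calc(h) + kSol exp(-bSol s^2/4) F_mask(h)| (complex sum before the
#' modulus).
#'
#' @param scale a [ScaleModel-class].
#' @param fCalc,fMaskV complex vectors of model and mask structure factors.
#' @param miller n x 3 integer matrix.
#' @param frame a [CrystalFrame-class].
#' @return numeric amplitude vector.
#' @export
fModel <- function(scale, fCalc, fMaskV, miller, frame) {
  s <- .recipVectors(rbind(miller), frame)
  s2 <- rowSums(s * s)
  Fs <- abs(fCalc + scale@kSol * exp(-scale@bSol * s2 / 4) * fMaskV)
  scale@kOverall * .anisoFactor(scale, s) * Fs
}

#' Crystallographic R factor
#'
#' R = sum(||F_obs| - |F_model||) / sum(|F_obs|) over a selection; an empty
#' selection yields NA.
#'
#' @param fObs,fModelAmp numeric amplitude vectors.
#' @param sel logical selection (default all).
#' @export
rFactor <- function(fObs, fModelAmp, sel = rep(TRUE, length(fObs))) {
  if (!any(sel)) return(NA_real_)
  sum(abs(fObs[sel] - fModelAmp[sel])) / sum(fObs[sel])
}

# Point-group projection of a Cartesian tensor: average R U R' over the
# proper rotations, then remove the trace.
.projectTensor <- function(U, frame) {
  rots <- .millerRotations(frame)
  acc <- matrix(0, 3, 3)
  for (R in rots) {
    Rc <- .cartRotation(R, frame)
    acc <- acc + Rc %*% U %*% t(Rc)
  }
  U <- acc / length(rots)
  U <- (U + t(U)) / 2
  list(U = U - diag(3) * sum(diag(U)) / 3, trace = sum(diag(U)))
}

#' Fit the bulk-solvent and scaling model
#'
#' Minimizes R on the working set: a grid search over kSol in {0, 0.05, ...,
#' 0.6} and bSol in {10, 20, ..., 150} with the overall scale analytic at
#' each node, followed by coordinate-descent polish (tolerance 1e-4 on R)
#' and a log-linear least-squares fit of the anisotropic scale tensor,
#' symmetry-projected onto the point group with the trace folded into the
#' isotropic overall B. With fewer than 50 reflections the bulk-solvent term
#' is disabled with a warning.
#'
#' @param fObs numeric observed amplitudes.
#' @param fCalc,fMaskV complex structure factors of model and mask.
#' @param miller n x 3 integer matrix.
#' @param frame a [CrystalFrame-class].
#' @param work logical working-set mask (default all).
#' @param fitAniso fit the anisotropic scale tensor.
#' @return a [ScaleModel-class].
#' @export
fitScaleModel <- function(fObs, fCalc, fMaskV, miller, frame,
                          work = rep(TRUE, length(fObs)), fitAniso = TRUE) {
  s <- .recipVectors(rbind(miller), frame)
  s2 <- rowSums(s * s)
  scale <- .scaleModel()
  evalR <- function(kSol, bSol, aniso) {
    Fs <- abs(fCalc + kSol * exp(-bSol * s2 / 4) * fMaskV) * aniso
    k <- sum(fObs[work] * Fs[work]) / sum(Fs[work]^2)
    list(r = rFactor(fObs, k * Fs, work), k = k)
  }
  if (sum(work) < 50) {
    warning("fewer than 50 working reflections: bulk solvent disabled")
    a <- rep(1, length(fObs))
    e <- evalR(0, 0, a)
    return(.scaleModel(kOverall = e$k))
  }
  aniso <- rep(1, length(fObs))
  kGrid <- seq(0, 0.6, by = 0.05); bGrid <- seq(10, 150, by = 10)
  best <- list(r = Inf, kSol = 0, bSol = 0)
  for (ks in kGrid) for (bs in (if (ks == 0) 50 else bGrid)) {
    e <- evalR(ks, bs, aniso)
    if (e$r < best$r) best <- list(r = e$r, kSol = ks, bSol = bs, k = e$k)
  }
  uC <- matrix(0, 3, 3); bOv <- 0; kOv <- best$k
  for (cycle in 1:3) {
    rPrev <- best$r
    if (fitAniso) {
      # log-linear residual fit of the exponential scale tensor
      Fs <- abs(fCalc + best$kSol * exp(-best$bSol * s2 / 4) * fMaskV)
      af <- exp(-bOv * s2 / 4 - 2 * pi^2 * rowSums((s %*% uC) * s))
      pred <- kOv * af * Fs
      ok <- work & fObs > 0 & pred > 1e-8 * mean(pred)
      y <- log(fObs[ok] / pred[ok])
      X <- cbind(s[ok, 1]^2, s[ok, 2]^2, s[ok, 3]^2,
                 2 * s[ok, 1] * s[ok, 2], 2 * s[ok, 1] * s[ok, 3],
                 2 * s[ok, 2] * s[ok, 3])
      fit <- lm(y ~ X)
      cf <- coef(fit)
      dU <- .uVecToMat(-unname(cf[-1]) / (2 * pi^2))
      pr <- .projectTensor(uC + dU, frame)
      uC <- pr$U                          # traceless by construction
      bOv <- bOv + 8 * pi^2 * pr$trace / 3  # trace goes to the isotropic B
      kOv <- kOv * exp(unname(cf[1]))
    }
    aniso <- exp(-bOv * s2 / 4 - 2 * pi^2 * rowSums((s %*% uC) * s))
    # coordinate-descent polish of the solvent parameters
    ok <- optimize(function(ks) evalR(ks, best$bSol, aniso)$r,
                   c(0, 0.8), tol = 1e-4)
    best$kSol <- ok$minimum
    ob <- optimize(function(bs) evalR(best$kSol, bs, aniso)$r,
                   c(5, 300), tol = 1e-2)
    best$bSol <- ob$minimum
    e <- evalR(best$kSol, best$bSol, aniso)
    best$r <- e$r; kOv <- e$k
    if (abs(rPrev - best$r) < 1e-4) break
  }
  # snap a negligible solvent contribution to zero
  e0 <- evalR(0, 0, aniso)
  if (e0$r <= best$r + 1e-6) {
    best$kSol <- 0; best$bSol <- 0; kOv <- e0$k
  }
  .scaleModel(kOverall = kOv, bOverall = bOv, uCryst = uC,
              kSol = best$kSol, bSol = best$bSol)
}

## ---- twinning ----

#' Enumerate candidate merohedral twin laws
#'
#' Integer operations on Miller indices that preserve the reciprocal metric
#' (within tolerance) but are not symmetry operations, reduced to coset
#' representatives of order 2 or 3 modulo the point group and Friedel
#' inversion. Cells without extra metric symmetry yield an empty list.
#'
#' @param frame a [CrystalFrame-class].
#' @param relTol relative metric tolerance (default 5e-3, roughly 1 degree /
#'   0.1 Angstrom on typical cells).
#' @return list of 3x3 integer matrices (acting on row Miller indices).
#' @export
candidateTwinLaws <- function(frame, relTol = 5e-3) {
  Gs <- frame@frac %*% t(frame@frac)   # reciprocal metric: |s|^2 = h Gs h'
  ref <- sqrt(sum(Gs^2))
  ents <- expand.grid(rep(list(-1:1), 9))
  pg <- .millerRotations(frame)
  pgKeys <- unlist(lapply(pg, function(R)
    c(paste(R, collapse = ","), paste(-R, collapse = ","))))
  laws <- list()
  for (i in seq_len(nrow(ents))) {
    M <- matrix(as.numeric(ents[i, ]), 3, 3)
    if (abs(det(M) - 1) > 1e-9) next
    if (sqrt(sum((M %*% Gs %*% t(M) - Gs)^2)) > relTol * ref) next
    if (paste(M, collapse = ",") %in% pgKeys) next
    laws[[length(laws) + 1L]] <- M
  }
  if (!length(laws)) return(list())
  # reduce to double cosets modulo the point group (applied before or after
  # the law) and Friedel inversion
  cosetKey <- function(M) {
    ks <- character(0)
    for (R1 in pg) for (R2 in pg) {
      P <- R1 %*% M %*% R2
      ks <- c(ks, paste(P, collapse = ","), paste(-P, collapse = ","))
    }
    min(ks)
  }
  keys <- vapply(laws, cosetKey, character(1))
  out <- list()
  for (k in unique(keys)) {
    members <- laws[keys == k]
    ords <- vapply(members, .matrixOrder, numeric(1))
    if (any(ords %in% c(2, 3)))
      out[[length(out) + 1L]] <- members[[which(ords %in% c(2, 3))[1]]]
  }
  out
}

.matrixOrder <- function(M, maxOrder = 6) {
  P <- diag(3)
  for (n in 1:maxOrder) {
    P <- P %*% M
    if (max(abs(P - diag(3))) < 1e-9) return(n)
  }
  Inf
}

#' Refine a twin fraction against one twin law
#'
#' |F_twin(h)|^2 = (1 - alpha) F_model(h)^2 + alpha F_model(T h)^2; alpha is
#' scanned on [0, 0.5] in steps of 0.01 and polished by bounded 1-D
#' minimization of the working-set R factor, with the overall scale analytic
#' at each alpha. Reflections whose twin mate is missing from the model set
#' are skipped and counted.
#'
#' @param fObs observed amplitudes.
#' @param fModelAmp model amplitudes (same order as `miller`).
#' @param law 3x3 integer twin-law matrix.
#' @param miller n x 3 canonical Miller indices.
#' @param frame a [CrystalFrame-class].
#' @param work logical working-set mask.
#' @return list(alpha, r, nSkipped, twin = [TwinModel-class]).
#' @export
twinFit <- function(fObs, fModelAmp, law, miller, frame,
                    work = rep(TRUE, length(fObs))) {
  hT <- rbind(miller) %*% law
  can <- mapToAsu(hT, frame)$miller
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- match(key(can), key(rbind(miller)))
  ok <- !is.na(idx)
  nSkip <- sum(!ok)
  w <- work & ok
  F2 <- fModelAmp^2
  evalR <- function(alpha) {
    Ft <- sqrt((1 - alpha) * F2[w] + alpha * F2[idx[w]])
    k <- sum(fObs[w] * Ft) / sum(Ft^2)
    sum(abs(fObs[w] - k * Ft)) / sum(fObs[w])
  }
  grid <- seq(0, 0.5, by = 0.01)
  rs <- vapply(grid, evalR, numeric(1))
  a0 <- grid[which.min(rs)]
  op <- optimize(evalR, c(max(0, a0 - 0.01), min(0.5, a0 + 0.01)), tol = 1e-4)
  alpha <- op$minimum; r <- op$objective
  if (rs[1] <= r) { alpha <- 0; r <- rs[1] }
  list(alpha = alpha, r = r, nSkipped = nSkip,
       twin = new("TwinModel", law = law, fraction = alpha))
}

## ---- TLS ----

#' Reconstruct anisotropic U from TLS parameters
#'
#' With d = xyz - origin (Angstrom), A the cross-product matrix (A lambda =
#' lambda x d), L converted from squared degrees to squared radians and S
#' from Angstrom-degrees to Angstrom-radians:
#' U = T + A L A' + A S + S' A'.
#'
#' @param group a [TLSGroup-class].
#' @param xyz n x 3 Cartesian coordinates.
#' @return n x 6 matrix of U components (u11, u22, u33, u12, u13, u23),
#'   Angstrom^2.
#' @export
uFromTls <- function(group, xyz) {
  xyz <- rbind(xyz)
  k <- pi / 180
  L <- group@L * k^2
  S <- group@S * k
  out <- matrix(0, nrow(xyz), 6)
  for (i in seq_len(nrow(xyz))) {
    d <- xyz[i, ] - group@origin
    A <- matrix(c(0, d[3], -d[2],
                  -d[3], 0, d[1],
                  d[2], -d[1], 0), 3, 3, byrow = TRUE)
    U <- group@T + A %*% L %*% t(A) + A %*% S + t(S) %*% t(A)
    U <- (U + t(U)) / 2
    out[i, ] <- .uMatToVec(U)
  }
  out
}

# atoms matched by a TLS selection (data.frame chain/from/to rows, ORed)
.selectAtoms <- function(tab, selection) {
  sel <- logical(nrow(tab))
  for (r in seq_len(nrow(selection)))
    sel <- sel | (tab$chain == selection$chain[r] &
                  tab$resseq >= selection$from[r] &
                  tab$resseq <= selection$to[r])
  sel
}

#' Add the TLS contribution to a model's ADPs
#'
#' For every atom matched by a group selection the reconstructed U_TLS is
#' added to the atom's residual ADP (isotropic B becomes an anisotropic
#' total U). Used to convert residual-convention models to total ADPs.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param groups list of [TLSGroup-class] (default: the ensemble's own).
#' @return the modified ensemble.
#' @export
applyTlsToModel <- function(ensemble, groups = tlsGroups(ensemble)) {
  ensemble@models <- lapply(ensemble@models, function(tab) {
    for (g in groups) {
      sel <- .selectAtoms(tab, g@selection)
      if (!any(sel)) next
      U <- uFromTls(g, as.matrix(tab[sel, c("x", "y", "z")]))
      uRes <- as.matrix(tab[sel, c("u11", "u22", "u33", "u12", "u13", "u23")])
      iso <- is.na(uRes[, 1])
      uRes[iso, ] <- cbind(matrix(bToU(tab$b[sel][iso]), sum(iso), 3), 0, 0, 0)
      tab[sel, c("u11", "u22", "u33", "u12", "u13", "u23")] <- U + uRes
    }
    tab
  })
  ensemble
}

## ---- cutoffs and the fit driver ----

#' Apply PDB-header resolution and sigma cutoffs to a reflection set
#'
#' @param set a [ReflectionSet-class].
#' @param header header list from [readPdb()] (resLimits, sigmaCutoff).
#' @param frame a [CrystalFrame-class].
#' @return list(set, variant = "all data" or "header cutoffs", nRemoved).
#' @export
applyHeaderCutoffs <- function(set, header, frame) {
  keep <- rep(TRUE, nrow(set@miller))
  applied <- FALSE
  if (!is.null(header$resLimits) && any(!is.na(header$resLimits))) {
    d <- dSpacing(set@miller, frame)
    lims <- header$resLimits
    if (!is.na(lims[2])) { keep <- keep & d >= lims[2] - 1e-6; applied <- TRUE }
    if (!is.na(lims[1])) { keep <- keep & d <= lims[1] + 1e-6; applied <- TRUE }
  }
  if (!is.null(header$sigmaCutoff) && !is.na(header$sigmaCutoff) &&
      any(!is.na(set@sigma))) {
    keep <- keep & (is.na(set@sigma) |
                    set@value >= header$sigmaCutoff * set@sigma)
    applied <- TRUE
  }
  list(set = .subsetReflections(set, keep),
       variant = if (applied) "header cutoffs" else "all data",
       nRemoved = sum(!keep))
}

.subsetReflections <- function(set, keep) {
  new("ReflectionSet", miller = set@miller[keep, , drop = FALSE],
      value = set@value[keep], sigma = set@sigma[keep], kind = set@kind,
      free = if (length(set@free)) set@free[keep] else logical(0),
      centric = set@centric[keep], epsilon = set@epsilon[keep],
      anomalous = set@anomalous)
}

.fitResult <- function(rW, rF, nW, nF, nOut, scale, twin = NULL,
                       adp = "total", variant = "all data")
  new("FitResult", rWork = rW, rFree = rF, nWork = as.integer(nW),
      nFree = as.integer(nF), nOutliers = as.integer(nOut), scale = scale,
      twin = twin, adpConvention = adp, cutoffVariant = variant)

#' Fit a model to a reflection set
#'
#' Runs the full path: structure factors for the observed indices, solvent
#' mask and its transform, bulk-solvent + anisotropic scale fit on the
#' working set, R_work/R_free, and (optionally) twin-law evaluation with the
#' verdict going to the configuration with the lowest R.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param set a [ReflectionSet-class] holding amplitudes.
#' @param mode "xray" or "neutron".
#' @param method "fft" or "direct" structure-factor path.
#' @param mask optional precomputed [SolventMask-class] (reused across
#'   ADP-convention runs, as the mask depends only on coordinates).
#' @param twinLaws list of candidate law matrices ("auto" enumerates them);
#'   NULL disables twin tests.
#' @param outliers logical mask of reflections to exclude from scaling
#'   (counted in the result).
#' @param adpConvention label recorded in the result.
#' @param variant cutoff-variant label recorded in the result.
#' @param fCalcOverride precomputed complex F_calc (internal reuse).
#' @return a [FitResult-class]; when twin laws were tested, the per-law
#'   results are attached as attribute "twinTable".
#' @export
fitModelToData <- function(ensemble, set, mode = "xray", method = "fft",
                           mask = NULL, twinLaws = NULL, outliers = NULL,
                           adpConvention = "total", variant = "all data",
                           fCalcOverride = NULL) {
  frame <- ensemble@frame
  miller <- set@miller
  fObs <- set@value
  d <- dSpacing(miller, frame)
  dMin <- min(d)
  if (is.null(outliers)) outliers <- logical(length(fObs))
  free <- if (length(set@free)) set@free else logical(length(fObs))
  work <- !free & !outliers
  fC <- if (!is.null(fCalcOverride)) fCalcOverride
        else if (method == "direct") fcalcDirect(ensemble, miller, mode)
        else fcalcFft(ensemble, miller, dMin, mode)
  if (is.null(mask)) mask <- solventMask(ensemble, dMin = dMin)
  fM <- fMask(mask, frame, miller)
  scale <- fitScaleModel(fObs, fC, fM, miller, frame, work = work)
  fMod <- fModel(scale, fC, fM, miller, frame)
  rW <- rFactor(fObs, fMod, work)
  rF <- if (any(free & !outliers)) rFactor(fObs, fMod, free & !outliers)
        else NA_real_
  res <- .fitResult(rW, rF, sum(work), sum(free & !outliers), sum(outliers),
                    scale, NULL, adpConvention, variant)
  if (!is.null(twinLaws)) {
    if (identical(twinLaws, "auto")) twinLaws <- candidateTwinLaws(frame)
    if (length(twinLaws)) {
      tw <- lapply(twinLaws, function(law)
        twinFit(fObs, fMod, law, miller, frame, work = work))
      rs <- vapply(tw, `[[`, numeric(1), "r")
      bestLaw <- which.min(rs)
      tab <- data.frame(
        law = vapply(twinLaws, function(M)
          paste(as.integer(t(M)), collapse = " "), character(1)),
        alpha = vapply(tw, `[[`, numeric(1), "alpha"), r = rs)
      attr(res, "twinTable") <- tab
      if (rs[bestLaw] < rW) {
        best <- tw[[bestLaw]]
        hT <- miller %*% twinLaws[[bestLaw]]
        can <- mapToAsu(hT, frame)$miller
        idx <- match(paste(can[, 1], can[, 2], can[, 3]),
                     paste(miller[, 1], miller[, 2], miller[, 3]))
        okT <- !is.na(idx)
        Ft <- sqrt((1 - best$alpha) * fMod^2 +
                   best$alpha * fMod[ifelse(okT, idx, 1)]^2)
        Ft[!okT] <- fMod[!okT]
        k <- sum(fObs[work & okT] * Ft[work & okT]) /
          sum(Ft[work & okT]^2)
        rWT <- rFactor(fObs, k * Ft, work & okT)
        rFT <- if (any(free & okT)) rFactor(fObs, k * Ft, free & !outliers & okT)
               else NA_real_
        res2 <- .fitResult(rWT, rFT, sum(work & okT), sum(free & okT),
                           sum(outliers), scale, best$twin, adpConvention,
                           variant)
        attr(res2, "twinTable") <- tab
        attr(res2, "untwinnedR") <- rW
        res <- res2
      }
    }
  }
  res
}

#' Resolve the total-versus-residual ADP convention
#'
#' Deposited ATOM/ANISOU records of TLS-refined structures may hold either
#' total ADPs or residuals with the TLS contribution in the header. Both
#' interpretations are scored with the full scale-and-R pipeline (one shared
#' solvent mask, which depends only on coordinates) and the convention with
#' the lower R_work wins; differences below 0.1 percentage points default to
#' "total" (the deposited values stand). When every TLS group is defective
#' the convention is forced to "total" and the defect list is attached.
#'
#' @param ensemble a [ModelEnsemble-class] (ADPs as deposited).
#' @param set a [ReflectionSet-class].
#' @param ... passed to [fitModelToData()].
#' @return list(convention, fits = list(total =, residual =), defects).
#' @export
resolveAdpConvention <- function(ensemble, set, ...) {
  groups <- tlsGroups(ensemble)
  dMin <- min(dSpacing(set@miller, ensemble@frame))
  mask <- solventMask(ensemble, dMin = dMin)
  fitTotal <- fitModelToData(ensemble, set, mask = mask,
                             adpConvention = "total", ...)
  if (!length(groups)) {
    return(list(convention = "total",
                fits = list(total = fitTotal, residual = NULL),
                defects = ensemble@tlsDefects))
  }
  ensTot <- applyTlsToModel(ensemble, groups)
  fitResid <- fitModelToData(ensTot, set, mask = mask,
                             adpConvention = "residual->total", ...)
  conv <- if (rWork(fitResid) < rWork(fitTotal) - 0.001) "residual->total"
          else "total"
  list(convention = conv,
       fits = list(total = fitTotal, residual = fitResid),
       defects = ensemble@tlsDefects)
}
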