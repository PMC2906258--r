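test_that("F_model reduces to |F_calc| in the trivial limits and matches hand arithmetic", {
  frame <- makeCrystalFrame(c(10, 11, 12, 90, 90, 90), "P1")
  h <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 3, 3))
  fC <- complex(real = c(10, -4, 2), imaginary = c(0, 3, -1))
  fM <- complex(real = c(5, 1, 0.2), imaginary = c(1, -2, 0))
  ident <- new("ScaleModel", kOverall = 1, bOverall = 0,
               uCryst = matrix(0, 3, 3), kSol = 0, bSol = 0)
  expect_equal(fModel(ident, fC, fM, h, frame), Mod(fC))

  # b_sol -> infinity kills the solvent term at d < 3 A
  bigB <- new("ScaleModel", kOverall = 1, bOverall = 0,
              uCryst = matrix(0, 3, 3), kSol = 0.4, bSol = 1e5)
  hHi <- rbind(c(4, 0, 0), c(0, 4, 0))  # d = 2.5, 2.75
  fC2 <- complex(real = c(3, 5)); fM2 <- complex(real = c(2, 2))
  expect_equal(fModel(bigB, fC2, fM2, hHi, frame), Mod(fC2),
               tolerance = 1e-6)

  # scalar-arithmetic oracle with k_sol = 0.35, b_sol = 46
  sc <- new("ScaleModel", kOverall = 1.2, bOverall = 0,
            uCryst = matrix(0, 3, 3), kSol = 0.35, bSol = 46)
  s2 <- 1 / dSpacing(h, frame)^2
  byHand <- 1.2 * sqrt(Mod(fC + 0.35 * exp(-46 * s2 / 4) * fM)^2)
  expect_equal(fModel(sc, fC, fM, h, frame), byHand, tolerance = 1e-12)
})

test_that("R factor matches hand computation and brackets hold", {
  fo <- c(10, 20, 30, 5, 15)
  expect_equal(rFactor(fo, fo), 0)
  expect_equal(rFactor(fo, 2 * fo), 1)
  fm <- c(11, 18, 33, 4, 16)
  expect_equal(rFactor(fo, fm), (1 + 2 + 3 + 1 + 1) / 80)
  expect_true(is.na(rFactor(fo, fm, rep(FALSE, 5))))

  # R over the union lies between R_work and R_free
  fx <- smallP21()
  fit <- fitModelToData(fx$ens, fx$set, method = "direct")
  fC <- fcalcDirect(fx$ens, millerIndices(fx$set))
  mask <- solventMask(fx$ens, dMin = 2.0)
  fMv <- fMask(mask, fx$ens@frame, millerIndices(fx$set))
  fMod <- fModel(scaleModel(fit), fC, fMv, millerIndices(fx$set), fx$ens@frame)
  rAll <- rFactor(reflValues(fx$set), fMod)
  expect_gte(rAll, min(rWork(fit), rFree(fit)) - 1e-12)
  expect_lte(rAll, max(rWork(fit), rFree(fit)) + 1e-12)
})

test_that("scale-model fitting recovers the generating parameters", {
  for (seed in 1:3) {
    ens <- makeToyCrystal(50, "P21", seed = seed)
    truth <- groundTruth(kSol = 0.35, bSol = 46, noise = 0.03,
                         seed = seed + 100)
    set <- simulateFobs(ens, truth, dMin = 2.0)
    fit <- fitModelToData(ens, set, method = "direct")
    expect_lt(abs(scaleModel(fit)@kSol - 0.35), 0.05)
    expect_lt(abs(scaleModel(fit)@bSol - 46), 10)
  }

  # null recovery: no solvent in the data
  ens <- makeToyCrystal(50, "P21", seed = 9)
  set0 <- simulateFobs(ens, groundTruth(kSol = 0, noise = 0.02, seed = 5),
                       dMin = 2.0)
  fit0 <- fitModelToData(ens, set0, method = "direct")
  expect_lte(scaleModel(fit0)@kSol, 0.05)
  expect_lt(rWork(fit0), 0.03)
})

test_that("anisotropic scale exponents are recovered within 10% per component", {
  ens <- makeToyCrystal(50, "P1", seed = 14)
  uTrue <- diag(c(-0.02, 0.02, 0))  # traceless Cartesian exponent, A^2
  truth <- groundTruth(kSol = 0, uCryst = uTrue, noise = 0, seed = 3)
  set <- simulateFobs(ens, truth, dMin = 2.0)
  fit <- fitModelToData(ens, set, method = "direct")
  uHat <- scaleModel(fit)@uCryst
  big <- abs(uTrue) > 1e-6
  expect_lt(max(abs(uHat[big] - uTrue[big]) / abs(uTrue[big])), 0.1)
  expect_lt(rWork(fit), 1e-3)
})

test_that("the fitted scale never leaves R above the solvent-free baseline", {
  fx <- smallP21()
  frame <- fx$ens@frame
  miller <- millerIndices(fx$set)
  fC <- fcalcDirect(fx$ens, miller)
  mask <- solventMask(fx$ens, dMin = 2.0)
  fMv <- fMask(mask, frame, miller)
  work <- !freeFlags(fx$set)
  fo <- reflValues(fx$set)
  fit <- fitScaleModel(fo, fC, fMv, miller, frame, work = work)
  rFit <- rFactor(fo, fModel(fit, fC, fMv, miller, frame), work)
  kBest <- sum(fo[work] * Mod(fC)[work]) / sum(Mod(fC)[work]^2)
  rBase <- rFactor(fo, kBest * Mod(fC), work)
  expect_lte(rFit, rBase + 1e-9)

  # fewer than 50 reflections: solvent disabled with a warning
  keep <- seq_len(nrow(miller)) <= 40
  expect_warning(
    small <- fitScaleModel(fo[keep], fC[keep], fMv[keep],
                           miller[keep, ], frame),
    "50")
  expect_equal(small@kSol, 0)
})

test_that("twin-law enumeration matches the lattice metric", {
  expect_length(candidateTwinLaws(
    makeCrystalFrame(c(10, 11, 12, 90, 90, 90), "P212121")), 0)
  lawsP4 <- candidateTwinLaws(makeCrystalFrame(c(10, 10, 12, 90, 90, 90), "P4"))
  expect_length(lawsP4, 1)
  expect_true(xtalfit:::.matrixOrder(lawsP4[[1]]) == 2)
  # the law is the (k,h,-l)-type coset: it must swap intensities of
  # reflections unrelated by P4 symmetry
  h <- c(1, 2, 3)
  img <- as.numeric(h %*% lawsP4[[1]])
  frame <- makeCrystalFrame(c(10, 10, 12, 90, 90, 90), "P4")
  expect_equal(dSpacing(rbind(img), frame), dSpacing(rbind(h), frame))
  lawsP31 <- candidateTwinLaws(makeCrystalFrame(c(10, 10, 12, 90, 90, 120), "P31"))
  expect_gte(length(lawsP31), 1)
  expect_true(any(vapply(lawsP31, xtalfit:::.matrixOrder, numeric(1)) == 2))
})

test_that("twin fractions are recovered and the null case stays untwinned", {
  frame <- makeCrystalFrame(c(14, 14, 17, 90, 90, 90), "P4")
  law <- candidateTwinLaws(frame)[[1]]
  for (seed in 1:3) {
    ens <- makeToyCrystal(40, "P4", seed = seed)
    lw <- candidateTwinLaws(ens@frame)[[1]]
    truth <- groundTruth(kSol = 0, noise = 0.03, twinLaw = lw,
                         twinFraction = 0.45, seed = seed + 50)
    set <- simulateFobs(ens, truth, dMin = 2.0)
    miller <- millerIndices(set)
    fC <- fcalcDirect(ens, miller)
    k <- sum(reflValues(set) * Mod(fC)) / sum(Mod(fC)^2)
    tw <- twinFit(reflValues(set), k * Mod(fC), lw, miller, ens@frame)
    expect_lt(abs(tw$alpha - 0.45), 0.03)
    rBlind <- rFactor(reflValues(set), k * Mod(fC))
    expect_gt(rBlind - tw$r, 0.05)

    # untwinned data: alpha stays near zero and R does not improve
    setU <- simulateFobs(ens, groundTruth(kSol = 0, noise = 0.03,
                                          seed = seed + 60), dMin = 2.0)
    fCU <- fcalcDirect(ens, millerIndices(setU))
    kU <- sum(reflValues(setU) * Mod(fCU)) / sum(Mod(fCU)^2)
    twU <- twinFit(reflValues(setU), kU * Mod(fCU), lw,
                   millerIndices(setU), ens@frame)
    expect_lte(twU$alpha, 0.02)
    rU <- rFactor(reflValues(setU), kU * Mod(fCU))
    expect_gte(twU$r, rU - 0.001)
  }

  # alpha = 0.5: replacing the law by its inverse leaves R unchanged
  ens <- makeToyCrystal(40, "P4", seed = 7)
  lw <- candidateTwinLaws(ens@frame)[[1]]
  set5 <- simulateFobs(ens, groundTruth(kSol = 0, noise = 0.02, twinLaw = lw,
                                        twinFraction = 0.5, seed = 70),
                       dMin = 2.0)
  fC <- fcalcDirect(ens, millerIndices(set5))
  k <- sum(reflValues(set5) * Mod(fC)) / sum(Mod(fC)^2)
  t1 <- twinFit(reflValues(set5), k * Mod(fC), lw, millerIndices(set5),
                ens@frame)
  t2 <- twinFit(reflValues(set5), k * Mod(fC), round(solve(lw)),
                millerIndices(set5), ens@frame)
  expect_equal(t1$r, t2$r, tolerance = 1e-6)
})

test_that("TLS U reconstruction obeys the rigid-body formula", {
  g0 <- new("TLSGroup", selection = data.frame(chain = "A", from = 1, to = 99),
            selectionText = "chain A", origin = c(1, 2, 3),
            T = diag(c(0.02, 0.03, 0.04)), L = matrix(0, 3, 3),
            S = matrix(0, 3, 3), dialect = "phenix")
  xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  U <- uFromTls(g0, xyz)
  expect_true(all(abs(U[, 1] - 0.02) < 1e-12))
  expect_true(all(abs(U[, 4:6]) < 1e-12))

  # pure libration about x: an atom on the axis through the origin is static
  gL <- g0
  gL@L <- diag(c(25, 0, 0))
  onAxis <- matrix(c(1 + 5, 2, 3), 1, 3)
  expect_equal(uFromTls(gL, onAxis),
               matrix(xtalfit:::.uMatToVec(g0@T), 1), tolerance = 1e-12)

  # Monte-Carlo rigid-body covariance oracle for random T/L/S
  set.seed(21)
  J <- crossprod(matrix(rnorm(36, sd = 0.08), 6, 6))
  k <- pi / 180
  g <- new("TLSGroup", selection = data.frame(chain = "A", from = 1, to = 99),
           selectionText = "chain A", origin = c(0, 0, 0),
           T = J[4:6, 4:6], L = J[1:3, 1:3] / k^2, S = J[1:3, 4:6] / k,
           dialect = "refmac")
  xyz <- matrix(rnorm(15, sd = 5), 5, 3)
  U <- uFromTls(g, xyz)
  R <- chol(J + diag(6) * 1e-12)
  draws <- matrix(rnorm(6 * 1e5), ncol = 6) %*% R
  for (i in 1:5) {
    d <- xyz[i, ]
    u <- cbind(draws[, 2] * d[3] - draws[, 3] * d[2],
               draws[, 3] * d[1] - draws[, 1] * d[3],
               draws[, 1] * d[2] - draws[, 2] * d[1]) + draws[, 4:6]
    Umc <- crossprod(u) / nrow(u)
    expect_lt(max(abs(Umc - xtalfit:::.uVecToMat(U[i, ]))) /
                max(abs(U[i, ])), 0.02)
  }
})

test_that("the ADP-convention heuristic picks the generating convention", {
  ens <- makeToyCrystal(60, "P21", seed = 21, bRange = c(8, 12))
  tab <- atomTable(ens)
  g <- new("TLSGroup",
           selection = data.frame(chain = "A", from = min(tab$resseq),
                                  to = max(tab$resseq)),
           selectionText = "chain A", origin = colMeans(tab[, c("x", "y", "z")]),
           T = diag(3) * 0.04, L = diag(3) * 40, S = matrix(0, 3, 3),
           dialect = "phenix")
  truth <- groundTruth(kSol = 0.35, bSol = 46, noise = 0.03, seed = 31)

  # deposited with residual B + TLS header: data carry the TLS contribution
  setResid <- simulateFobs(applyTlsToModel(ens, list(g)), truth, dMin = 2.2)
  dep <- ens; dep@tlsGroups <- list(g)
  res <- resolveAdpConvention(dep, setResid, method = "direct")
  expect_equal(res$convention, "residual->total")
  expect_gte(rWork(res$fits$total) - rWork(res$fits$residual), 0.02)

  # deposited with total B (no TLS in the data beyond the ADPs)
  setTotal <- simulateFobs(ens, truth, dMin = 2.2)
  resT <- resolveAdpConvention(dep, setTotal, method = "direct")
  expect_equal(resT$convention, "total")

  # all groups defective: convention forced to total, R stays high
  depBad <- applyTlsToModel(ens, list()) # no-op; simulate defective parse
  depBad@tlsGroups <- list()
  depBad@tlsDefects <- data.frame(group = 1L, category = "a", line = 1L,
                                  message = "unparseable selection")
  resBad <- resolveAdpConvention(depBad, setResid, method = "direct")
  expect_equal(resBad$convention, "total")
  expect_gt(rWork(resBad$fits$total), rWork(res$fits$residual) + 0.02)
  expect_equal(resBad$defects$category, "a")
})

test_that("header cutoffs filter by resolution window and F/sigma", {
  fx <- smallP21()
  frame <- fx$ens@frame
  none <- applyHeaderCutoffs(fx$set, list(), frame)
  expect_equal(none$variant, "all data")
  expect_equal(none$nRemoved, 0)

  d <- dSpacing(millerIndices(fx$set), frame)
  hdr <- list(resLimits = c(8, NA), sigmaCutoff = NA_real_)
  cut <- applyHeaderCutoffs(fx$set, hdr, frame)
  expect_equal(cut$variant, "header cutoffs")
  expect_equal(nrow(millerIndices(cut$set)), sum(d <= 8 + 1e-6))

  hdrS <- list(sigmaCutoff = 2)
  cutS <- applyHeaderCutoffs(fx$set, hdrS, frame)
  byHand <- sum(reflValues(fx$set) >= 2 * reflSigmas(fx$set))
  expect_equal(nrow(millerIndices(cutS$set)), byHand)
})
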