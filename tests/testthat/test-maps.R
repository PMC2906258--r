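test_that("sigma-A approaches 1 for a perfect model and collapses for a random one", {
  fx <- smallP21Clean()
  miller <- millerIndices(fx$set)
  fC <- fcalcDirect(fx$ens, miller)
  mask <- solventMask(fx$ens, dMin = 2.0)
  fMv <- fMask(mask, fx$ens@frame, miller)
  sc <- new("ScaleModel", kOverall = 1, bOverall = 0, uCryst = matrix(0, 3, 3),
            kSol = 0.35, bSol = 46)
  fMod <- fModel(sc, fC, fMv, miller, fx$ens@frame)
  sa <- estimateSigmaA(reflValues(fx$set), fMod, fx$set, fx$ens@frame)
  expect_true(all(sa@bins$sigmaA >= 0.99))
  expect_gt(mean(sa@m), 0.95)
  expect_true(all(sa@m >= 0 & sa@m <= 1))
  expect_true(all(sa@D >= 0))

  # randomly permuted model amplitudes: the signal collapses (wide bins
  # tame the estimator's small-sample scatter)
  set.seed(12)
  for (i in 1:3) {
    saPerm <- estimateSigmaA(reflValues(fx$set), sample(fMod), fx$set,
                             fx$ens@frame, nBins = 4)
    expect_lte(mean(saPerm@bins$sigmaA), 0.2)
    expect_lte(max(saPerm@bins$sigmaA), 0.45)
  }
})

test_that("coordinate noise produces a Luzzati-like sigma-A falloff with resolution", {
  fx <- smallP21Clean()
  miller <- millerIndices(fx$set)
  set.seed(30)
  noisy <- fx$ens
  noisy@models[[1]][, c("x", "y", "z")] <-
    noisy@models[[1]][, c("x", "y", "z")] +
    matrix(rnorm(3 * nrow(atomTable(noisy)), sd = 0.3), ncol = 3)
  fMod <- Mod(fcalcDirect(noisy, miller))
  sa <- estimateSigmaA(reflValues(fx$set), fMod, fx$set, fx$ens@frame)
  b <- sa@bins
  sRes <- 1 / ((b$dMax + b$dMin) / 2)   # increasing = higher resolution
  expect_lt(cor(sRes, b$sigmaA, method = "spearman"), 0)
})

test_that("map coefficient algebra holds in the perfect-model limit", {
  fx <- smallP21Clean()
  miller <- millerIndices(fx$set)
  fC <- fcalcDirect(fx$ens, miller)
  # perfect model with m = 1, D = 1 supplied: 2mFo-DFc == Fc exactly
  n <- nrow(miller)
  sa1 <- new("SigmaATable",
             bins = data.frame(dMax = max(dSpacing(miller, fx$ens@frame)),
                               dMin = min(dSpacing(miller, fx$ens@frame)),
                               n = n, sigmaA = 1, D = 1),
             m = rep(1, n), D = rep(1, n), bin = rep(1L, n))
  setPerfect <- fx$set
  setPerfect@value <- Mod(fC)
  co <- mapCoefficients("2mfo-dfc", setPerfect, fC, sa1, fx$ens@frame)
  expect_equal(co$coeff, fC, tolerance = 1e-12)
  diffCo <- mapCoefficients("mfo-dfc", setPerfect, fC, sa1, fx$ens@frame)
  expect_lt(max(Mod(diffCo$coeff)), 1e-10)
  co32 <- mapCoefficients("3fo-2fc", setPerfect, fC, frame = fx$ens@frame)
  expect_equal(co32$coeff, fC, tolerance = 1e-12)
})

test_that("missing observations are filled with D Fc", {
  fx <- smallP21Clean()
  miller <- millerIndices(fx$set)
  fC <- fcalcDirect(fx$ens, miller)
  set.seed(8)
  keep <- runif(nrow(miller)) > 0.1
  sub <- xtalfit:::.subsetReflections(fx$set, keep)
  fCsub <- fC[keep]
  sa <- estimateSigmaA(reflValues(sub), Mod(fCsub), sub, fx$ens@frame)
  co <- mapCoefficients("2mfo-dfc", sub, fCsub, sa, fx$ens@frame,
                        fillMissing = TRUE, fullMiller = miller,
                        fModelFullC = fC)
  expect_equal(nrow(co$miller), nrow(miller))
  expect_error(mapCoefficients("2mfo-dfc", sub, fCsub, sa, fx$ens@frame,
                               fillMissing = TRUE), "fullMiller")
})

test_that("anomalous difference coefficients need Friedel pairs", {
  fx <- smallP21Clean()
  expect_error(mapCoefficients("anom", fx$set,
                               fcalcDirect(fx$ens, millerIndices(fx$set)),
                               frame = fx$ens@frame), "anomalous")
})

test_that("map synthesis is sigma-scaled, peaks at atoms, and obeys Parseval", {
  frame <- makeCrystalFrame(c(12, 13, 14, 90, 90, 90), "P1")
  one <- ensembleFromTable(atomRow(1, "C", 3.1, 7.2, 5.3, b = 15), frame)
  hs <- millerSet(frame, 2.0)
  fC <- fcalcDirect(one, hs)
  map <- synthesizeMap(list(miller = hs, coeff = fC), frame, dMin = 2.0)
  expect_lt(abs(mean(mapValues(map))), 1e-10)
  expect_lt(abs(sd(as.numeric(mapValues(map))) - 1), 1e-10)

  pk <- which(mapValues(map) == max(mapValues(map)), arr.ind = TRUE)[1, ]
  xf <- (cartToFrac(c(3.1, 7.2, 5.3), frame) %% 1) * map@grid
  expect_true(all(abs(as.numeric(pk) - 1 - as.numeric(xf)) <= 1))

  # Parseval: raw grid variance equals 2 sum|F|^2 / V^2 (Friedel pairs)
  dims <- map@grid
  grid <- array(0 + 0i, dims)
  idx <- 1L + (hs[, 1] %% dims[1]) +
    dims[1] * ((hs[, 2] %% dims[2]) + dims[2] * (hs[, 3] %% dims[3]))
  grid[idx] <- fC
  idxm <- 1L + ((-hs[, 1]) %% dims[1]) +
    dims[1] * (((-hs[, 2]) %% dims[2]) + dims[2] * ((-hs[, 3]) %% dims[3]))
  grid[idxm] <- Conj(fC)
  vals <- Re(fft(grid)) / cellVolume(frame)
  expect_equal(mean(vals^2) - mean(vals)^2,
               2 * sum(Mod(fC)^2) / cellVolume(frame)^2,
               tolerance = 1e-6)

  expect_error(synthesizeMap(list(miller = hs, coeff = fC * 0), frame,
                             dMin = 2.0), "zero")
})

test_that("real-space correlation is 1 against itself, -1 against negation, and finds the displaced atom", {
  frame <- makeCrystalFrame(c(12, 13, 14, 90, 90, 90), "P1")
  tab <- rbind(atomRow(1, "C", 3, 3, 3, b = 12),
               atomRow(2, "O", 8, 9, 4, b = 12),
               atomRow(3, "N", 5, 10, 10, b = 12))
  ens <- ensembleFromTable(tab, frame)
  hs <- millerSet(frame, 2.0)
  fC <- fcalcDirect(ens, hs)
  map <- synthesizeMap(list(miller = hs, coeff = fC), frame, dMin = 2.0)

  ccSelf <- realSpaceCC(map, map, ens, "atom")
  expect_true(all(abs(ccSelf$cc - 1) < 1e-12))
  neg <- new("RealSpaceMap", grid = map@grid, values = -mapValues(map),
             frame = frame)
  expect_true(all(abs(realSpaceCC(map, neg, ens, "atom")$cc + 1) < 1e-12))

  # displace one atom in the model: it gets the worst CC against the
  # map computed from the true positions
  moved <- ens
  moved@models[[1]]$x[2] <- moved@models[[1]]$x[2] + 1.5
  fCmov <- fcalcDirect(moved, hs)
  mapMov <- synthesizeMap(list(miller = hs, coeff = fCmov), frame, dMin = 2.0)
  cc <- realSpaceCC(map, mapMov, moved, "atom")
  expect_equal(which.min(cc$cc), 2L)

  # residue granularity unions the atom spheres
  ccRes <- realSpaceCC(map, map, ens, "residue")
  expect_equal(nrow(ccRes), 3)
  expect_true(all(ccRes$nVoxels >= ccSelf$nVoxels))
})

test_that("model degradation monotonically lowers the mean correlation", {
  fx <- smallP21Clean()
  miller <- millerIndices(fx$set)
  frame <- fx$ens@frame
  fC <- fcalcDirect(fx$ens, miller)
  dims <- xtalfit:::.gridDims(frame, 2.0, 4)
  mapTrue <- synthesizeMap(list(miller = miller, coeff = fC), frame,
                           dims = dims)
  meanCC <- vapply(c(0, 0.3, 0.6), function(sdv) {
    set.seed(40)
    noisy <- fx$ens
    noisy@models[[1]][, c("x", "y", "z")] <-
      noisy@models[[1]][, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(atomTable(noisy)), sd = sdv), ncol = 3)
    fCn <- fcalcDirect(noisy, miller)
    mapN <- synthesizeMap(list(miller = miller, coeff = fCn), frame,
                          dims = dims)
    mean(realSpaceCC(mapTrue, mapN, fx$ens, "atom")$cc, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meanCC) < 0))
  expect_gt(meanCC[1], 0.999)
})
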