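test_that("SHELX HKL fixed columns parse exactly, honouring the terminator", {
  txt <- c("   1   2   3  123.45   12.34",
           "  -4   5  -6   78.90    7.89",
           "  10 -11  12    0.50    0.05",
           "   0   0   0    0.00    0.00",
           "   7   7   7  999.00   99.00")
  raw <- readReflections(text = txt, format = "shelx")
  expect_equal(nrow(raw), 3)
  expect_equal(raw$h, c(1, -4, 10))
  expect_equal(raw$value, c(123.45, 78.90, 0.50))
  expect_equal(raw$sigma, c(12.34, 7.89, 0.05))
  expect_equal(attr(readReflections(text = txt), "format"), "shelx")
  expect_error(readReflections(text = character(0)), "empty")
})

test_that("CNS free-format and plain columns parse, including flags", {
  cns <- c("INDE     1    2    3 FOBS=   123.450 SIGMA=    12.340 TEST= 1",
           "INDE    -4    5   -6 FOBS=    78.900 SIGMA=     7.890 TEST= 0")
  raw <- readReflections(text = cns)
  expect_equal(attr(raw, "format"), "cns")
  expect_equal(raw$k, c(2, 5))
  expect_equal(raw$flag, c(1, 0))

  cols <- c("1 2 3 123.45 12.34 0", "-4 5 -6 78.9 7.89 1")
  raw2 <- readReflections(text = cols, format = "columns")
  expect_equal(raw2$value, c(123.45, 78.9))
  expect_equal(raw2$flag, c(0, 1))
  expect_error(readReflections(text = "1 2 three 4 5", format = "columns"),
               "line 1")
})

test_that("amplitude/intensity detection uses the acentric Wilson moment", {
  frame <- makeCrystalFrame(c(30, 31, 32, 90, 90, 90), "P1")
  hs <- millerSet(frame, 2.5)
  set.seed(11)
  nMC <- 50
  hits <- 0
  for (i in 1:nMC) {
    # Wilson draws: amplitudes F with F^2 ~ exponential
    F <- sqrt(stats::rexp(nrow(hs)))
    raw <- data.frame(h = hs[, 1], k = hs[, 2], l = hs[, 3],
                      value = F, sigma = 0.01)
    gA <- guessDataKind(raw, frame)
    rawI <- raw; rawI$value <- F^2
    gI <- guessDataKind(rawI, frame)
    hits <- hits + (gA$kind == "amplitude") + (gI$kind == "intensity")
    if (i == 1) {
      expect_lt(abs(gA$ratio - 4 / pi), 0.06)
      expect_lt(abs(gI$ratio - 2), 0.25)
    }
  }
  expect_gte(hits / (2 * nMC), 0.95)

  # any negative value forces intensity
  raw <- data.frame(h = hs[1:300, 1], k = hs[1:300, 2], l = hs[1:300, 3],
                    value = c(-5, runif(299)), sigma = 1)
  expect_equal(guessDataKind(raw, frame)$kind, "intensity")

  # too few acentrics: declared kind, low confidence
  small <- data.frame(h = 1:10, k = 2, l = 3, value = runif(10), sigma = 1)
  g <- guessDataKind(small, frame, declared = "intensity")
  expect_equal(g$kind, "intensity")
  expect_equal(g$confidence, "low")
})

test_that("intensity-to-amplitude conversion uses truncation and first-order errors", {
  raw <- data.frame(h = 1, k = 0, l = 0, value = 100, sigma = 10)
  out <- toAmplitudes(raw, "intensity")
  expect_equal(out$value, 10)
  expect_equal(out$sigma, 0.5)
  expect_equal(toAmplitudes(data.frame(h = 1, k = 0, l = 0, value = -5,
                                       sigma = 4), "intensity")$value, 0)
  # Wilson first-moment relation <F>^2/<F^2> = pi/4
  set.seed(4)
  I <- stats::rexp(20000)
  F <- toAmplitudes(data.frame(h = 1, k = 1, l = 1, value = I, sigma = 1),
                    "intensity")$value
  expect_lt(abs(mean(F)^2 / mean(F^2) - pi / 4), 0.02)
})

test_that("merging to the ASU averages duplicates and counts redundancy", {
  frame <- makeCrystalFrame(c(10, 11, 12, 90, 90, 90), "P212121")
  raw <- data.frame(h = c(1, -1), k = c(2, -2), l = c(3, -3),
                    value = c(10, 12), sigma = c(1, 1))
  m <- mergeToAsu(raw, frame)
  expect_equal(nrow(millerIndices(m$set)), 1)
  expect_equal(m$nRedundant, 1)
  expect_equal(reflValues(m$set), 11)

  # full orbit collapses to one reflection; count matches the orbit size
  h0 <- c(1, 2, 3)
  orbit <- unique(do.call(rbind, lapply(xtalfit:::.millerRotations(frame),
    function(R) rbind(h0 %*% R, -(h0 %*% R)))))
  rawO <- data.frame(h = orbit[, 1], k = orbit[, 2], l = orbit[, 3],
                     value = 5, sigma = 1)
  mO <- mergeToAsu(rawO, frame)
  expect_equal(nrow(millerIndices(mO$set)), 1)
  expect_equal(mO$nRedundant, nrow(orbit) - 1)

  # idempotence and anomalous pair preservation
  m2 <- mergeToAsu(data.frame(h = millerIndices(m$set)[, 1],
                              k = millerIndices(m$set)[, 2],
                              l = millerIndices(m$set)[, 3],
                              value = reflValues(m$set),
                              sigma = 1), frame)
  expect_equal(m2$nRedundant, 0)
  mAno <- mergeToAsu(raw, frame, anomalous = TRUE)
  expect_equal(nrow(millerIndices(mAno$set)), 2)
})

test_that("free-flag conventions are auto-detected", {
  set.seed(5)
  f01 <- as.numeric(runif(2000) < 0.05)
  e <- extractFreeFlags(f01)
  expect_equal(e$mask, f01 == 1)

  fN <- sample(0:19, 2000, replace = TRUE)
  e2 <- extractFreeFlags(fN)
  expect_equal(e2$mask, fN == 0)
  expect_lt(abs(mean(e2$mask) - 0.05), 0.02)

  expect_warning(e3 <- extractFreeFlags(rep(1, 100)), "constant")
  expect_null(e3$mask)
  expect_null(extractFreeFlags(NULL)$mask)
})

test_that("completeness shells partition the range and detect deletions", {
  fx <- smallP21Clean()
  cs <- completenessShells(fx$set, fx$ens@frame, 5)
  expect_true(all(abs(cs$completeness - 1) < 1e-9))
  expect_true(all(cs$completeness >= 0 & cs$completeness <= 1))

  set.seed(6)
  keep <- runif(nrow(millerIndices(fx$set))) > 0.5
  half <- xtalfit:::.subsetReflections(fx$set, keep)
  ch <- completenessShells(half, fx$ens@frame, 5)
  overall <- sum(ch$nObs) / sum(ch$nPossible)
  expect_lt(abs(overall - mean(keep)), 0.02)

  # deleting only the lowest-resolution shell empties only that shell
  d <- dSpacing(millerIndices(fx$set), fx$ens@frame)
  cut <- quantile(d, 0.8)
  noLow <- xtalfit:::.subsetReflections(fx$set, d < cut)
  cl <- completenessShells(noLow, fx$ens@frame, 5)
  expect_lt(max(cl$dMax), cut + 1e-6)
})

test_that("Wilson B is recovered within 2 A^2 and is scale invariant", {
  for (B in c(10, 25, 50)) {
    ens <- wilsonCrystal(60, B = B, seed = 13)
    set <- simulateFobs(ens, groundTruth(kSol = 0, noise = 0), dMin = 1.6)
    content <- table(atomTable(ens)$element) * length(symOps(ens@frame))
    wb <- wilsonB(set, ens@frame, content)
    expect_lt(abs(wb$B - B), 2)
    # scale invariance: x10 on intensities shifts only the scale
    set10 <- set
    set10@value <- set@value * sqrt(10)
    wb10 <- wilsonB(set10, ens@frame, content)
    expect_lt(abs(wb10$B - wb$B), 1e-6)
    expect_gt(wb10$scale / wb$scale, 5)
  }
  # B = 0 comes back near zero
  ens0 <- wilsonCrystal(60, B = 0.01, seed = 13)
  set0 <- simulateFobs(ens0, groundTruth(kSol = 0, noise = 0), dMin = 1.6)
  content <- table(atomTable(ens0)$element) * length(symOps(ens0@frame))
  expect_lt(abs(wilsonB(set0, ens0@frame, content)$B), 2)

  # no data beyond 4 A -> n.a.
  lowres <- simulateFobs(makeToyCrystal(40, "P21", seed = 1),
                         groundTruth(kSol = 0, noise = 0), dMin = 4.5)
  expect_true(is.na(wilsonB(lowres, makeToyCrystal(40, "P21", seed = 1)@frame,
                            c(C = 40))$B))
})

test_that("Wilson outlier rejection flags spikes and little else on clean data", {
  fx <- smallP21Clean()
  clean <- wilsonOutliers(fx$set, fx$ens@frame)
  expect_lte(clean$n, 1)

  spiked <- fx$set
  target <- which.min(abs(spiked@value - stats::median(spiked@value)))[1]
  spiked@value[target] <- spiked@value[target] * 10
  out <- wilsonOutliers(spiked, fx$ens@frame)
  expect_true(out$mask[target])
  expect_equal(out$n, 1)

  empty <- xtalfit:::.subsetReflections(fx$set, rep(FALSE, length(fx$set@value)))
  expect_equal(wilsonOutliers(empty, fx$ens@frame)$n, 0)
})
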