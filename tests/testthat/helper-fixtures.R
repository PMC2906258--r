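# Shared fixtures, built once per test run and memoised.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# small P21 crystal with solvent-corrected, lightly noisy data
smallP21 <- function() cachedFixture("smallP21", function() {
  ens <- makeToyCrystal(50, "P21", seed = 3)
  truth <- groundTruth(kSol = 0.35, bSol = 46, noise = 0.03, seed = 7)
  set <- simulateFobs(ens, truth, dMin = 2.0)
  list(ens = ens, set = set, truth = truth)
})

# noise-free twin of the same crystal
smallP21Clean <- function() cachedFixture("smallP21Clean", function() {
  ens <- smallP21()$ens
  truth <- groundTruth(kSol = 0.35, bSol = 46, noise = 0, seed = 7)
  set <- simulateFobs(ens, truth, dMin = 2.0)
  list(ens = ens, set = set, truth = truth)
})

# a bare ensemble from an atom table (for hand-built models)
ensembleFromTable <- function(tab, frame) {
  need <- c("u11", "u22", "u33", "u12", "u13", "u23")
  for (cn in need) if (is.null(tab[[cn]])) tab[[cn]] <- NA_real_
  if (is.null(tab$scatter)) tab$scatter <- tab$element
  if (is.null(tab$het)) tab$het <- FALSE
  if (is.null(tab$altloc)) tab$altloc <- " "
  if (is.null(tab$icode)) tab$icode <- " "
  if (is.null(tab$resname)) tab$resname <- "UNK"
  if (is.null(tab$name)) tab$name <- tab$element
  new("ModelEnsemble", models = list(tab), frame = frame,
      tlsGroups = list(), tlsDefects = xtalfit:::.emptyTlsDefects(),
      header = list())
}

atomRow <- function(serial, el, x, y, z, b = 20, occ = 1, chain = "A",
                    resseq = serial) {
  data.frame(serial = serial, name = el, altloc = " ", resname = "UNK",
             chain = chain, resseq = resseq, icode = " ", x = x, y = y,
             z = z, occ = occ, b = b, element = el, het = FALSE,
             u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
             u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
             scatter = el, stringsAsFactors = FALSE)
}

# ideal Wilson crystal: point-like atoms at uniform random positions (no
# compact blob, no minimum separation), so <I> = sum f^2 exp(-B s^2/2) holds
# without Debye ripples
wilsonCrystal <- function(n = 60, B = 25, seed = 1, spacegroup = "P21") {
  cell <- xtalfit:::.defaultCell(n, spacegroup)
  frame <- makeCrystalFrame(cell, spacegroup)
  set.seed(seed)
  els <- sample(c("C", "N", "O"), n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  xyz <- fracToCart(matrix(runif(3 * n), ncol = 3), frame)
  tab <- do.call(rbind, lapply(seq_len(n), function(i)
    atomRow(i, els[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], b = B)))
  ensembleFromTable(tab, frame)
}

# well-formed refmac-dialect TLS REMARK 3 block
refmacTlsBlock <- function() c(
  "REMARK   3  TLS DETAILS",
  "REMARK   3   NUMBER OF TLS GROUPS  :    1",
  "REMARK   3   TLS GROUP :     1",
  "REMARK   3    NUMBER OF COMPONENTS GROUP :    1",
  "REMARK   3    COMPONENTS        C SSSEQI TO C SSSEQI",
  "REMARK   3    RESIDUE RANGE :   A     1        A   100",
  "REMARK   3    ORIGIN FOR THE GROUP (A):  12.3450  23.4560   8.7650",
  "REMARK   3    T TENSOR",
  "REMARK   3      T11:   0.0100 T22:   0.0200",
  "REMARK   3      T33:   0.0300 T12:   0.0010",
  "REMARK   3      T13:   0.0020 T23:   0.0030",
  "REMARK   3    L TENSOR",
  "REMARK   3      L11:   1.0000 L22:   2.0000",
  "REMARK   3      L33:   3.0000 L12:   0.1000",
  "REMARK   3      L13:   0.2000 L23:   0.3000",
  "REMARK   3    S TENSOR",
  "REMARK   3      S11:   0.0100 S12:   0.0200 S13:   0.0300",
  "REMARK   3      S21:   0.0400 S22:   0.0500 S23:   0.0600",
  "REMARK   3      S31:   0.0700 S32:   0.0800 S33:   0.0900")

phenixTlsBlock <- function(selection = "chain A and resseq 1:100") {
  blk <- refmacTlsBlock()
  blk <- blk[!grepl("COMPONENTS", blk)]
  sub("RESIDUE RANGE :   A     1        A   100",
      paste0("SELECTION: ", selection), blk)
}
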