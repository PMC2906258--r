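# PDB model I/O: fixed-column ATOM/HETATM/ANISOU parsing, multi-model
# ensembles, CRYST1, REMARK 290 operators, REMARK 3 header statistics and
# TLS blocks in the two common dialects, plus the model audits.

.substrTrim <- function(x, a, b) trimws(substr(x, a, b))
.numOrNA <- function(x) suppressWarnings(as.numeric(x))

.elementFromName <- function(name) {
  nm <- gsub("[0-9'\"]", "", name)
  nm <- trimws(nm)
  if (nchar(nm) == 0) return("X")
  two <- toupper(substr(nm, 1, 2))
  if (two %in% names(.VDW_RADII) && nchar(trimws(two)) == 2 &&
      substr(name, 1, 1) != " ") return(two)
  one <- toupper(substr(nm, 1, 1))
  if (one %in% c("H", "D", "C", "N", "O", "S", "P")) return(one)
  "X"
}

.parseAtomLine <- function(line, lineno) {
  el <- toupper(.substrTrim(line, 77, 78))
  name <- substr(line, 13, 16)
  if (el == "") el <- .elementFromName(name)
  list(serial = as.integer(.substrTrim(line, 7, 11)),
       name = trimws(name),
       altloc = substr(line, 17, 17),
       resname = .substrTrim(line, 18, 20),
       chain = substr(line, 22, 22),
       resseq = as.integer(.substrTrim(line, 23, 26)),
       icode = substr(line, 27, 27),
       x = .numOrNA(substr(line, 31, 38)),
       y = .numOrNA(substr(line, 39, 46)),
       z = .numOrNA(substr(line, 47, 54)),
       occ = .numOrNA(substr(line, 55, 60)),
       b = .numOrNA(substr(line, 61, 66)),
       element = el,
       het = startsWith(line, "HETATM"))
}

.emptyAtomTable <- function(n = 0) {
  data.frame(serial = integer(n), name = character(n), altloc = character(n),
             resname = character(n), chain = character(n), resseq = integer(n),
             icode = character(n), x = numeric(n), y = numeric(n),
             z = numeric(n), occ = numeric(n), b = numeric(n),
             element = character(n), scatter = character(n),
             het = logical(n),
             u11 = numeric(n), u22 = numeric(n), u33 = numeric(n),
             u12 = numeric(n), u13 = numeric(n), u23 = numeric(n),
             stringsAsFactors = FALSE)
}

.parseRemark290 <- function(lines, frame = NULL) {
  # coordinate-triplet lines: "REMARK 290     NNNMMM   OPERATOR"
  trip <- grep("^REMARK 290\\s+\\d{4,6}\\s+[XYZxyz0-9/, +-]+$", lines,
               value = TRUE)
  trip <- trip[grepl("[XYZxyz]", trip)]
  if (length(trip)) {
    ops <- lapply(trip, function(l) {
      expr <- sub("^REMARK 290\\s+\\d+\\s+", "", l)
      .parseSymopString(expr)
    })
    return(ops)
  }
  NULL
}

.parseHeaderInfo <- function(lines) {
  grab <- function(pattern) {
    m <- grep(pattern, lines, value = TRUE)
    if (!length(m)) return(NA_real_)
    tail <- sub(".*:", "", m[1])
    v <- regmatches(tail, regexpr("-?[0-9]*\\.?[0-9]+\\s*$", tail))
    if (!length(v)) NA_real_ else .numOrNA(v)
  }
  resHigh <- grab("^REMARK   3   RESOLUTION RANGE HIGH")
  resLow <- grab("^REMARK   3   RESOLUTION RANGE LOW")
  list(reportedRWork = grab("^REMARK   3   R VALUE\\s+\\(WORKING SET"),
       reportedRFree = grab("^REMARK   3   FREE R VALUE\\s+:"),
       resLimits = c(resLow, resHigh),
       sigmaCutoff = grab("^REMARK   3   DATA CUTOFF\\s+\\(SIGMA"),
       reportedWilsonB = grab("^REMARK   3   FROM WILSON PLOT"))
}

#' Read PDB model file(s)
#'
#' Parses fixed-column PDB v3 records. ANISOU records are merged onto the
#' preceding ATOM/HETATM (U in Angstrom^2 x 10^4); MODEL/ENDMDL delimits
#' models; CRYST1 defines the crystal frame; symmetry operators are taken
#' from REMARK 290 coordinate-triplet lines when present, otherwise from the
#' built-in space-group table. REMARK 3 yields header statistics and TLS
#' groups. Multiple files are concatenated as additional models sharing the
#' first file's frame (split multi-model depositions).
#'
#' @param paths character vector of file paths, or a single character vector
#'   of PDB lines via `text`.
#' @param text optional character vector of raw PDB lines (overrides paths).
#' @return A [ModelEnsemble-class].
#' @export
readPdb <- function(paths = NULL, text = NULL) {
  allLines <- if (!is.null(text)) list(text) else lapply(paths, readLines)
  models <- list()
  frame <- NULL
  tls <- list(groups = list(), defects = .emptyTlsDefects())
  header <- NULL
  for (lines in allLines) {
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (is.null(frame)) {
      if (!length(cl))
        stop("missing CRYST1 record: cannot compute structure factors")
      cell <- c(.numOrNA(substr(cl[1], 7, 15)), .numOrNA(substr(cl[1], 16, 24)),
                .numOrNA(substr(cl[1], 25, 33)), .numOrNA(substr(cl[1], 34, 40)),
                .numOrNA(substr(cl[1], 41, 47)), .numOrNA(substr(cl[1], 48, 54)))
      sg <- trimws(substr(cl[1], 56, 66))
      ops <- .parseRemark290(lines)
      frame <- if (!is.null(ops)) makeCrystalFrame(cell, sg, symops = ops)
               else makeCrystalFrame(cell, sg)
    }
    if (is.null(header)) {
      header <- .parseHeaderInfo(lines)
      r3 <- grep("^REMARK   3", lines, value = TRUE)
      tls <- parseTlsHeader(r3)
    }
    models <- c(models, .parseModelBlocks(lines))
  }
  if (!length(models)) stop("no ATOM/HETATM records found")
  new("ModelEnsemble", models = models, frame = frame,
      tlsGroups = tls$groups, tlsDefects = tls$defects, header = header)
}

.parseModelBlocks <- function(lines) {
  isAtom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  isAni <- startsWith(lines, "ANISOU")
  isModel <- startsWith(lines, "MODEL")
  modelId <- cumsum(isModel)
  keep <- which(isAtom | isAni)
  if (!length(keep)) return(list())
  blocks <- split(keep, modelId[keep])
  lapply(blocks, function(idx) {
    recs <- lines[idx]
    atomIdx <- which(startsWith(recs, "ATOM  ") | startsWith(recs, "HETATM"))
    parsed <- lapply(seq_along(atomIdx), function(i)
      .parseAtomLine(recs[atomIdx[i]], idx[atomIdx[i]]))
    g <- function(col) unlist(lapply(parsed, `[[`, col))
    tab <- data.frame(serial = g("serial"), name = g("name"),
                      altloc = g("altloc"), resname = g("resname"),
                      chain = g("chain"), resseq = g("resseq"),
                      icode = g("icode"), x = g("x"), y = g("y"), z = g("z"),
                      occ = g("occ"), b = g("b"), element = g("element"),
                      het = g("het"), stringsAsFactors = FALSE)
    tab$u11 <- tab$u22 <- tab$u33 <- tab$u12 <- tab$u13 <- tab$u23 <- NA_real_
    tab$scatter <- ifelse(tab$element %in% c(names(.VDW_RADII), "D"),
                          tab$element, "X")
    # attach ANISOU to the preceding atom record
    aniIdx <- which(startsWith(recs, "ANISOU"))
    for (ai in aniIdx) {
      prev <- max(atomIdx[atomIdx < ai], -1L)
      serial <- as.integer(.substrTrim(recs[ai], 7, 11))
      if (prev < 0 ||
          as.integer(.substrTrim(recs[prev], 7, 11)) != serial)
        stop("ANISOU record without matching ATOM (serial ", serial, ")")
      j <- which(atomIdx == prev)
      u <- .numOrNA(c(substr(recs[ai], 29, 35), substr(recs[ai], 36, 42),
                      substr(recs[ai], 43, 49), substr(recs[ai], 50, 56),
                      substr(recs[ai], 57, 63), substr(recs[ai], 64, 70))) / 1e4
      tab[j, c("u11", "u22", "u33", "u12", "u13", "u23")] <- as.list(u)
    }
    tab
  })
}

#' Write a ModelEnsemble as a PDB file
#'
#' Emits CRYST1 plus ATOM/HETATM (and ANISOU where anisotropic U is present)
#' records with PDB v3 column widths; MODEL/ENDMDL wrap multi-model
#' ensembles.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param path output path; when NULL the lines are returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
writePdb <- function(ensemble, path = NULL) {
  frame <- ensemble@frame
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                 frame@cell[1], frame@cell[2], frame@cell[3],
                 frame@cell[4], frame@cell[5], frame@cell[6],
                 frame@spacegroup)
  multi <- nModels(ensemble) > 1
  padName <- function(n, el) {
    # element right-justified in 13-14 for one-letter elements
    if (nchar(n) >= 4) substr(sprintf("%-4s", n), 1, 4)
    else if (nchar(el) == 1) sprintf(" %-3s", n)
    else sprintf("%-4s", n)
  }
  for (mi in seq_len(nModels(ensemble))) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", mi))
    tab <- ensemble@models[[mi]]
    for (i in seq_len(nrow(tab))) {
      a <- tab[i, ]
      rec <- if (a$het) "HETATM" else "ATOM  "
      out <- c(out, sprintf("%s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                            rec, a$serial, padName(a$name, a$element),
                            a$altloc, a$resname, a$chain, a$resseq, a$icode,
                            a$x, a$y, a$z, a$occ, a$b, a$element))
      if (!is.na(a$u11)) {
        u <- round(c(a$u11, a$u22, a$u33, a$u12, a$u13, a$u23) * 1e4)
        out <- c(out, sprintf("ANISOU%5d %s%s%-3s %s%4d%s %7d%7d%7d%7d%7d%7d      %2s",
                              a$serial, padName(a$name, a$element), a$altloc,
                              a$resname, a$chain, a$resseq, a$icode,
                              u[1], u[2], u[3], u[4], u[5], u[6], a$element))
      }
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

## ---- TLS header parsing ----

.emptyTlsDefects <- function()
  data.frame(group = integer(0), category = character(0),
             line = integer(0), message = character(0),
             stringsAsFactors = FALSE)

.parsePhenixSelection <- function(txt) {
  clauses <- strsplit(txt, "\\s+or\\s+", perl = TRUE)[[1]]
  rows <- lapply(clauses, function(cl) {
    cl <- trimws(gsub("[()]", "", cl))
    m <- regmatches(cl, regexec(
      "^chain\\s+'?([A-Za-z0-9])'?(\\s+and\\s+(resseq|resid)\\s+(-?\\d+)\\s*(:|through)\\s*(-?\\d+))?$",
      cl, ignore.case = TRUE))[[1]]
    if (!length(m)) return(NULL)
    if (m[3] == "") data.frame(chain = m[2], from = -Inf, to = Inf)
    else data.frame(chain = m[2], from = as.numeric(m[5]), to = as.numeric(m[7]))
  })
  if (any(vapply(rows, is.null, logical(1))) || !length(rows)) return(NULL)
  do.call(rbind, rows)
}

.parseRefmacRanges <- function(txts) {
  rows <- lapply(txts, function(txt) {
    tx <- trimws(txt)
    m <- regmatches(tx, regexec(
      "^([A-Za-z0-9])\\s+(-?\\d+)\\s+([A-Za-z0-9])\\s+(-?\\d+)$", tx))[[1]]
    if (length(m) != 5 || m[2] != m[4]) return(NULL)
    data.frame(chain = m[2], from = as.numeric(m[3]), to = as.numeric(m[5]))
  })
  if (any(vapply(rows, is.null, logical(1))) || !length(rows)) return(NULL)
  do.call(rbind, rows)
}

.tlsMatrixFromTokens <- function(tokens, prefix) {
  need <- if (prefix == "S") c("11", "12", "13", "21", "22", "23", "31", "32", "33")
          else c("11", "22", "33", "12", "13", "23")
  keys <- paste0(prefix, need)
  if (!all(keys %in% names(tokens))) return(NULL)
  v <- tokens[keys]
  if (any(is.na(v))) return(NULL)
  if (prefix == "S") matrix(v, 3, 3, byrow = TRUE)
  else .uVecToMat(v)
}

#' Parse TLS groups from REMARK 3 lines
#'
#' Auto-detects the two common header dialects: refmac-style groups carry
#' "RESIDUE RANGE" component lines, phenix-style groups carry a free-text
#' "SELECTION" expression. Malformed groups are not exceptions: each defect
#' is classified as (a) selection problems (missing, unparseable, or
#' overlapping selections), (b) origin problems, or (c) matrix problems
#' (missing or non-numeric tensor elements, undecidable dialect), and the
#' affected group is dropped while well-formed groups are kept.
#'
#' @param lines character vector of REMARK 3 lines (other lines are ignored).
#' @return list with `groups` (list of [TLSGroup-class]) and `defects`
#'   (data.frame: group, category, line, message).
#' @export
parseTlsHeader <- function(lines) {
  defects <- .emptyTlsDefects()
  groups <- list()
  lines0 <- lines
  r3 <- grepl("^REMARK   3", lines)
  starts <- grep("TLS GROUP\\s*:", lines)
  starts <- starts[r3[starts]]
  if (!length(starts)) return(list(groups = groups, defects = defects))
  ends <- c(starts[-1] - 1L, length(lines))
  addDefect <- function(g, cat, ln, msg)
    defects <<- rbind(defects, data.frame(group = g, category = cat,
                                          line = ln, message = msg))
  parsedSel <- list()
  for (gi in seq_along(starts)) {
    blk <- lines[starts[gi]:ends[gi]]
    off <- starts[gi] - 1L
    selLine <- grep("SELECTION\\s*:", blk)
    rangeLines <- grep("RESIDUE RANGE\\s*:", blk)
    originLine <- grep("ORIGIN FOR THE GROUP", blk)
    sel <- NULL; dialect <- NA_character_; selText <- ""
    if (length(selLine) && length(rangeLines)) {
      addDefect(gi, "a", off + selLine[1],
                "ambiguous selection: both dialects present")
    } else if (length(rangeLines)) {
      dialect <- "refmac"
      selText <- sub(".*RESIDUE RANGE\\s*:", "", blk[rangeLines])
      sel <- .parseRefmacRanges(selText)
      if (is.null(sel))
        addDefect(gi, "a", off + rangeLines[1], "unparseable residue range")
      selText <- paste(trimws(selText), collapse = "; ")
    } else if (length(selLine)) {
      dialect <- "phenix"
      selText <- trimws(sub(".*SELECTION\\s*:", "", blk[selLine[1]]))
      if (selText == "" || toupper(selText) == "NULL") {
        addDefect(gi, "a", off + selLine[1], "empty selection")
        sel <- NULL
      } else {
        sel <- .parsePhenixSelection(selText)
        if (is.null(sel))
          addDefect(gi, "a", off + selLine[1], "unparseable selection")
      }
    } else {
      addDefect(gi, "a", off + 1L, "missing selection")
    }
    origin <- NULL
    if (!length(originLine)) {
      addDefect(gi, "b", off + 1L, "missing origin line")
    } else {
      nums <- regmatches(blk[originLine[1]],
                         gregexpr("-?[0-9]+\\.[0-9]+", blk[originLine[1]]))[[1]]
      if (length(nums) != 3) addDefect(gi, "b", off + originLine[1],
                                       "origin not three numbers")
      else origin <- as.numeric(nums)
    }
    toks <- regmatches(blk, gregexpr("[TLS][0-9][0-9]:\\s*-?[0-9.]+", blk))
    toks <- unlist(toks)
    vals <- as.numeric(sub(".*:\\s*", "", toks))
    names(vals) <- substr(toks, 1, 3)
    Tm <- .tlsMatrixFromTokens(vals, "T")
    Lm <- .tlsMatrixFromTokens(vals, "L")
    Sm <- .tlsMatrixFromTokens(vals, "S")
    if (is.null(Tm) || is.null(Lm) || is.null(Sm))
      addDefect(gi, "c", off + 1L, "missing or incomplete T/L/S matrices")
    ok <- !is.null(sel) && !is.null(origin) &&
      !is.null(Tm) && !is.null(Lm) && !is.null(Sm)
    parsedSel[[gi]] <- if (ok) sel else NULL
    if (ok)
      groups[[length(groups) + 1L]] <-
        structure(new("TLSGroup", selection = sel, selectionText = selText,
                      origin = origin, T = Tm, L = Lm, S = Sm,
                      dialect = dialect), groupIndex = gi)
  }
  # overlap check across surviving groups -> defect a for each one involved
  if (length(groups) > 1) {
    bad <- logical(length(groups))
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      a <- groups[[i]]@selection; b <- groups[[j]]@selection
      for (ra in seq_len(nrow(a))) for (rb in seq_len(nrow(b))) {
        if (a$chain[ra] == b$chain[rb] &&
            a$from[ra] <= b$to[rb] && b$from[rb] <= a$to[ra]) {
          bad[i] <- bad[j] <- TRUE
          addDefect(attr(groups[[i]], "groupIndex"), "a", NA_integer_,
                    sprintf("selection overlaps group %d",
                            attr(groups[[j]], "groupIndex")))
        }
      }
    }
    groups <- groups[!bad]
  }
  list(groups = groups, defects = defects)
}

## ---- model audits ----

#' Audit a model for the pathologies found in deposited structures
#'
#' Checks: non-positive-definite anisotropic ADPs; zero ADPs; negative
#' occupancies; unknown scattering types; alternative-conformer occupancy
#' sums differing from 1 (tolerance 1e-3); H/D exchangeable site pairs whose
#' occupancies do not sum to 1; and, for multi-model ensembles, the summed
#' per-site occupancy across models.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @return list of class "modelAudit" with one entry per check; all entries
#'   empty on a clean model.
#' @export
auditModel <- function(ensemble) {
  tab <- do.call(rbind, ensemble@models)
  hasU <- !is.na(tab$u11)
  nonPd <- tab$serial[hasU][!vapply(which(hasU), function(i)
    isPositiveDefinite(as.numeric(tab[i, c("u11", "u22", "u33",
                                           "u12", "u13", "u23")])),
    logical(1))]
  zeroAdp <- tab$serial[!hasU & tab$b <= 0]
  negOcc <- tab$serial[tab$occ < 0]
  unknown <- tab$serial[tab$scatter == "X"]

  # altloc occupancy sums
  alt <- tab[tab$altloc != " " & tab$altloc != "", , drop = FALSE]
  altBad <- data.frame(chain = character(0), resseq = integer(0),
                       name = character(0), occSum = numeric(0))
  if (nrow(alt)) {
    key <- paste(alt$chain, alt$resseq, alt$icode, alt$name)
    sums <- tapply(alt$occ, key, sum)
    bad <- which(abs(sums - 1) > 1e-3)
    if (length(bad)) {
      parts <- strsplit(names(sums)[bad], " ")
      altBad <- data.frame(chain = vapply(parts, `[`, "", 1),
                           resseq = as.integer(vapply(parts, `[`, "", 2)),
                           name = vapply(parts, `[`, "", 4),
                           occSum = as.numeric(sums[bad]))
    }
  }

  # H/D exchangeable pairs: same name modulo the H/D lead character,
  # same position within 1e-3 A
  hd <- data.frame(chain = character(0), resseq = integer(0),
                   site = character(0), occSum = numeric(0),
                   underOccupied = logical(0))
  hAtoms <- tab[tab$element == "H", , drop = FALSE]
  dAtoms <- tab[tab$element == "D", , drop = FALSE]
  if (nrow(hAtoms) && nrow(dAtoms)) {
    stem <- function(df) sub("^[HD]", "", df$name)
    hKey <- paste(hAtoms$chain, hAtoms$resseq, stem(hAtoms))
    dKey <- paste(dAtoms$chain, dAtoms$resseq, stem(dAtoms))
    common <- intersect(hKey, dKey)
    for (k in common) {
      hi <- hAtoms[match(k, hKey), ]; di <- dAtoms[match(k, dKey), ]
      if (sqrt(sum((c(hi$x, hi$y, hi$z) - c(di$x, di$y, di$z))^2)) <= 1e-3) {
        s <- hi$occ + di$occ
        hd <- rbind(hd, data.frame(chain = hi$chain, resseq = hi$resseq,
                                   site = trimws(sub("^[HD]", "", hi$name)),
                                   occSum = s,
                                   underOccupied = s < 1 - 1e-3))
      }
    }
  }

  # multi-model per-site occupancy totals
  mm <- data.frame(chain = character(0), resseq = integer(0),
                   name = character(0), occTotal = numeric(0))
  if (nModels(ensemble) > 1) {
    key <- paste(tab$chain, tab$resseq, tab$name, tab$altloc)
    tot <- tapply(tab$occ, key, sum)
    parts <- strsplit(names(tot), " ")
    mm <- data.frame(chain = vapply(parts, `[`, "", 1),
                     resseq = as.integer(vapply(parts, `[`, "", 2)),
                     name = vapply(parts, `[`, "", 3),
                     occTotal = as.numeric(tot))
  }

  structure(list(nonPositiveDefinite = nonPd, zeroAdp = zeroAdp,
                 negativeOccupancy = negOcc, unknownScatteringType = unknown,
                 altlocOccupancy = altBad, hdExchange = hd,
                 multiModelOccupancy = mm),
            class = "modelAudit")
}

#' @export
print.modelAudit <- function(x, ...) {
  cat("Model audit:\n")
  cat(sprintf("  non-positive-definite ADPs : %d\n", length(x$nonPositiveDefinite)))
  cat(sprintf("  zero ADPs                  : %d\n", length(x$zeroAdp)))
  cat(sprintf("  negative occupancies       : %d\n", length(x$negativeOccupancy)))
  cat(sprintf("  unknown scattering types   : %d\n", length(x$unknownScatteringType)))
  cat(sprintf("  bad altloc occupancy sums  : %d\n", nrow(x$altlocOccupancy)))
  cat(sprintf("  H/D exchange sites         : %d (%d under-occupied)\n",
              nrow(x$hdExchange), sum(x$hdExchange$underOccupied)))
  if (nrow(x$multiModelOccupancy))
    cat(sprintf("  multi-model site occupancy : mean total %.3f over %d sites\n",
                mean(x$multiModelOccupancy$occTotal),
                nrow(x$multiModelOccupancy)))
  invisible(x)
}

#' Remove or repair hydrogen/deuterium atoms
#'
#' `stripHydrogens` removes all H and D atoms from every model.
#' `setHAdpFromParent` copies the B factor and occupancy of each H/D atom
#' from its bonded heavy atom (the nearest heavy atom within 1.3 Angstrom);
#' an H atom with no such neighbour is left unchanged with a warning.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @return the modified ensemble.
#' @export
stripHydrogens <- function(ensemble) {
  ensemble@models <- lapply(ensemble@models, function(m)
    m[!(m$element %in% c("H", "D")), , drop = FALSE])
  ensemble
}

#' @rdname stripHydrogens
#' @export
setHAdpFromParent <- function(ensemble) {
  ensemble@models <- lapply(ensemble@models, function(m) {
    isH <- m$element %in% c("H", "D")
    heavy <- m[!isH, , drop = FALSE]
    if (!nrow(heavy)) return(m)
    for (i in which(isH)) {
      d2 <- (heavy$x - m$x[i])^2 + (heavy$y - m$y[i])^2 + (heavy$z - m$z[i])^2
      j <- which.min(d2)
      if (d2[j] > 1.3^2) {
        warning("H atom serial ", m$serial[i],
                " has no heavy neighbour within 1.3 A; left unchanged")
        next
      }
      m$b[i] <- heavy$b[j]
      m$occ[i] <- heavy$occ[j]
    }
    m
  })
  ensemble
}
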