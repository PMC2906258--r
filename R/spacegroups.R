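# Space-group symmetry: coordinate-triplet parsing, a built-in generator
# table for the common space groups, and closure under composition.
#
# Operators act on fractional coordinates as x' = R x + t with R integer
# (conventional settings only) and t in [0, 1).

.parseSymopString <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("bad symop string: ", s)
  if (any(grepl("[^xyz0-9+/.\\-]", parts))) stop("bad symop string: ", s)
  R <- matrix(0, 3, 3); t <- numeric(3)
  basis <- rbind(c(0, 0, 0), diag(3))
  for (i in 1:3) {
    ex <- parse(text = parts[i])[[1]]
    vals <- apply(basis, 1, function(v)
      eval(ex, list(x = v[1], y = v[2], z = v[3]), baseenv()))
    t[i] <- vals[1]
    R[i, ] <- vals[2:4] - vals[1]
  }
  list(R = R, t = t %% 1)
}

.symopKey <- function(op)
  paste(c(round(op$R), round(op$t * 24) %% 24), collapse = ",")

.composeOps <- function(a, b)  # apply b first, then a
  list(R = a$R %*% b$R, t = (a$R %*% b$t + a$t) %% 1)

.identityOp <- function() list(R = diag(3), t = numeric(3))

.opsContainIdentity <- function(ops)
  any(vapply(ops, function(o)
    max(abs(o$R - diag(3))) < 1e-9 && max(abs(o$t %% 1)) < 1e-9, logical(1)))

.opsClosed <- function(ops) {
  keys <- vapply(ops, .symopKey, character(1))
  for (a in ops) for (b in ops)
    if (!(.symopKey(.composeOps(a, b)) %in% keys)) return(FALSE)
  TRUE
}

.closeOps <- function(gens) {
  ops <- list(.identityOp())
  names(ops) <- .symopKey(ops[[1]])
  queue <- gens
  while (length(queue)) {
    op <- queue[[1]]; queue <- queue[-1]
    k <- .symopKey(op)
    if (!is.null(ops[[k]])) next
    ops[[k]] <- op
    for (o in ops) {
      queue <- c(queue, list(.composeOps(op, o), .composeOps(o, op)))
    }
    if (length(ops) > 192) stop("symop closure did not terminate")
  }
  unname(ops)
}

# Generators per Hermann-Mauguin symbol (conventional settings, b-unique
# monoclinic, hexagonal setting for rhombohedral groups). Closure fills in
# the full coset list, so only generators are written here.
.SG_GENERATORS <- list(
  "P1"       = character(0),
  "P-1"      = c("-x,-y,-z"),
  "P2"       = c("-x,y,-z"),
  "P21"      = c("-x,y+1/2,-z"),
  "C2"       = c("-x,y,-z", "x+1/2,y+1/2,z"),
  "P222"     = c("-x,-y,z", "x,-y,-z"),
  "P2221"    = c("-x,-y,z+1/2", "x,-y,-z"),
  "P21212"   = c("-x,-y,z", "-x+1/2,y+1/2,-z"),
  "P212121"  = c("-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2"),
  "C2221"    = c("-x,-y,z+1/2", "x,-y,-z", "x+1/2,y+1/2,z"),
  "I222"     = c("-x,-y,z", "x,-y,-z", "x+1/2,y+1/2,z+1/2"),
  "P4"       = c("-y,x,z"),
  "P41"      = c("-y,x,z+1/4"),
  "P42"      = c("-y,x,z+1/2"),
  "P43"      = c("-y,x,z+3/4"),
  "P422"     = c("-y,x,z", "x,-y,-z"),
  "P41212"   = c("-y+1/2,x+1/2,z+1/4", "-x+1/2,y+1/2,-z+1/4"),
  "I4"       = c("-y,x,z", "x+1/2,y+1/2,z+1/2"),
  "P3"       = c("-y,x-y,z"),
  "P31"      = c("-y,x-y,z+1/3"),
  "P32"      = c("-y,x-y,z+2/3"),
  "P321"     = c("-y,x-y,z", "y,x,-z"),
  "P312"     = c("-y,x-y,z", "-y,-x,-z"),
  "R3"       = c("-y,x-y,z", "x+2/3,y+1/3,z+1/3"),
  "P6"       = c("x-y,x,z"),
  "P61"      = c("x-y,x,z+1/6"),
  "P65"      = c("x-y,x,z+5/6"),
  "P23"      = c("-x,-y,z", "x,-y,-z", "z,x,y"),
  "I23"      = c("-x,-y,z", "x,-y,-z", "z,x,y", "x+1/2,y+1/2,z+1/2"),
  "P213"     = c("-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "z,x,y")
)

.normalizeSgSymbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]]", "", symbol))
  sub("^([A-Z])", "\\1", s)
}

#' Symmetry operators for a space-group symbol
#'
#' Looks the Hermann-Mauguin symbol up in the built-in table of common space
#' groups and returns the closed operator set. Non-standard settings and
#' symbols outside the table are an error; operators may instead be supplied
#' explicitly (e.g. from REMARK 290) to [makeCrystalFrame()].
#'
#' @param symbol Hermann-Mauguin symbol, spaces optional ("P 21 21 21").
#' @return list of operators `list(R, t)`.
#' @export
spaceGroupOps <- function(symbol) {
  key <- .normalizeSgSymbol(symbol)
  gens <- .SG_GENERATORS[[key]]
  if (is.null(gens))
    stop("space group '", symbol, "' not in the built-in table; ",
         "supply symops explicitly")
  .closeOps(lapply(gens, .parseSymopString))
}

#' @rdname spaceGroupOps
#' @export
knownSpaceGroups <- function() names(.SG_GENERATORS)

.orthMatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate unit cell (volume <= 0)")
  v <- sqrt(v2)
  matrix(c(a, b * cg, cc * cb,
           0, b * sg, cc * (ca - cb * cg) / sg,
           0, 0,      cc * v / sg), 3, 3, byrow = TRUE)
}

#' Construct a CrystalFrame
#'
#' @param cell numeric(6): a, b, c in Angstrom, alpha, beta, gamma in degrees.
#' @param spacegroup Hermann-Mauguin symbol (used for the built-in operator
#'   table when `symops` is not given).
#' @param symops optional explicit operator list (e.g. parsed from
#'   REMARK 290); overrides the table.
#' @return A [CrystalFrame-class] object.
#' @examples
#' makeCrystalFrame(c(10, 10, 10, 90, 90, 90), "P1")
#' @export
makeCrystalFrame <- function(cell, spacegroup = "P1", symops = NULL) {
  cell <- as.numeric(cell)
  if (is.null(symops)) symops <- spaceGroupOps(spacegroup)
  orth <- .orthMatrix(cell)
  new("CrystalFrame", cell = cell, spacegroup = spacegroup,
      symops = symops, orth = orth, frac = solve(orth))
}

#' @rdname makeCrystalFrame
#' @param frame a CrystalFrame.
#' @export
cellVolume <- function(frame) abs(det(frame@orth))

# Cartesian reciprocal-space vectors (rows), Angstrom^-1: s = t(frac) %*% h.
.recipVectors <- function(h, frame) h %*% frame@frac

# Proper rotation part of an operator expressed in the Cartesian frame.
.cartRotation <- function(R, frame) frame@orth %*% R %*% frame@frac
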