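# Structure standardization on top of the OpenBabel toolkit
# (ChemmineR/ChemmineOB): parse SMILES, keep the largest fragment, clear
# stereo, neutralize protonatable/deprotonatable charges, and derive the
# heavy-atom representation used everywhere downstream.

.ATOMIC_MASS <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Na = 22.99, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
  Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Ga = 69.723,
  Ge = 72.63, As = 74.922, Se = 78.971, Br = 79.904, Zr = 91.224,
  Pd = 106.42, Ag = 107.868, Cd = 112.414, In = 114.818, Sn = 118.71,
  Sb = 121.76, I = 126.904, Yb = 173.045, Pt = 195.084, Au = 196.967,
  Hg = 200.592, Tl = 204.38, Pb = 207.2
)

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)

.stripStereo <- function(smiles) {
  gsub("[/\\\\]", "", gsub("@", "", smiles))
}

# Canonical SMILES via OpenBabel; NA for unparseable input.
.obCanonical <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                                 paste0(s, "\n"))),
      error = function(e) "")
    tok <- strsplit(out, "[\t\n]")[[1]]
    if (length(tok) < 1 || !nzchar(tok[1])) NA_character_ else tok[1]
  }, character(1), USE.NAMES = FALSE)
}

# Split a multi-record MOL2 text into per-molecule atom type / aromatic-flag
# tables, keyed by the record name.
.parseMol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  nms <- character(length(starts))
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    nms[k] <- trimws(rec[2])
    ai <- which(rec == "@<TRIPOS>ATOM")
    if (!length(ai)) next
    sect <- which(startsWith(rec, "@<TRIPOS>"))
    aend <- min(c(sect[sect > ai[1]] - 1L, length(rec)))
    atom_lines <- rec[(ai[1] + 1L):aend]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    types <- vapply(strsplit(trimws(atom_lines), "[[:space:]]+"),
                    function(f) f[6], character(1))
    out[[k]] <- types
  }
  names(out) <- nms
  out
}

.hybridFromMol2 <- function(types, degrees) {
  suffix <- tolower(sub("^[^.]+\\.?", "", types))
  hy <- rep("SP3", length(types))
  hy[suffix == "1"] <- "SP"
  hy[suffix %in% c("2", "ar", "am", "pl3", "co2")] <- "SP2"
  hy[suffix %in% c("3", "4", "o", "o2", "th")] <- "SP3"
  hy[degrees == 5L] <- "SP3D"
  hy[degrees >= 6L] <- "SP3D2"
  hy
}

.effectiveValence <- function(el, q) {
  v0 <- .DEFAULT_VALENCE[el]
  v0[is.na(v0)] <- 0
  out <- v0
  np <- el %in% c("N", "P", "O", "S")
  out[np] <- v0[np] + q[np]
  cs <- el %in% c("C", "Si")
  out[cs] <- v0[cs] - abs(q[cs])
  bb <- el == "B"
  out[bb] <- 3 - q[bb]
  pmax(out, 0)
}

# Implicit hydrogens from kekulized bond order sums, with the usual
# hypervalence allowances for S and P.
.implicitH <- function(el, q, bosum) {
  val <- .effectiveValence(el, q)
  s <- el == "S" & q == 0
  val[s & bosum > 2 & bosum <= 4] <- 4
  val[s & bosum > 4] <- 6
  p <- el == "P" & q == 0
  val[p & bosum > 3] <- 5
  as.integer(pmax(0, round(val - bosum)))
}

.decodeSdfCharge <- function(code) {
  # V2000 atom-block charge codes: 0 none, 1:+3, 2:+2, 3:+1, 5:-1, 6:-2, 7:-3
  q <- integer(length(code))
  nz <- !is.na(code) & code %in% c(1, 2, 3, 5, 6, 7)
  q[nz] <- 4L - as.integer(code[nz])
  q
}

# Connected components of the bond graph; returns membership vector.
.fragmentMembership <- function(n, bonds) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0)
    g <- igraph::add_edges(g, t(bonds[, 1:2, drop = FALSE]))
  igraph::components(g)$membership
}

# Minimal V2000 writer for canonicalization round trips (implicit H only;
# remaining formal charges as M CHG).
.writeV2000 <- function(mol, title) {
  n <- length(mol@element)
  b <- mol@bonds
  hdr <- c(title, " admetnet", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, mol@element)
  bl <- if (nrow(b) > 0)
    sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3]) else character(0)
  chg <- which(mol@charge != 0L)
  cl <- character(0)
  if (length(chg)) {
    groups <- split(chg, ceiling(seq_along(chg) / 8))
    cl <- vapply(groups, function(idx) {
      paste0(sprintf("M  CHG%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, mol@charge[idx]), collapse = ""))
    }, character(1))
  }
  paste(c(hdr, atoms, bl, cl, "M  END", "$$$$"), collapse = "\n")
}

#' Standardize a batch of structures
#'
#' Applies the preprocessing used before any modeling: clear stereochemistry,
#' keep the largest covalent fragment, and neutralize charges by protonating
#' anionic acids and deprotonating cationic bases (zwitterionic pairs on
#' adjacent atoms, e.g. nitro groups, are left intact; quaternary nitrogens
#' cannot be neutralized and keep their charge). Aromaticity and
#' hybridization are perceived by OpenBabel; hydrogens are implicit.
#' Unparseable SMILES are dropped and reported, not fatal.
#'
#' @param smiles character vector of input SMILES.
#' @param ids compound identifiers (default `cpd1..cpdN`).
#' @param neutralize,largestFragment,clearStereo logical switches for the
#'   three standardization steps (all `TRUE` by default).
#' @param canonicalTautomer reserved switch for tautomer canonicalization;
#'   the underlying toolkit exposes no canonical-tautomer routine, so the
#'   step is currently a no-op and the flag must remain `FALSE`.
#' @return a list with `molecules` (named list of [Molecule-class]) and
#'   `failures` (data.frame of id, smiles, reason for dropped inputs).
#' @examples
#' res <- standardizeMolecules(c("CCO.Cl", "C[C@@H](N)C(=O)O"))
#' vapply(res$molecules, function(m) m@smiles, "")
#' @export
standardizeMolecules <- function(smiles, ids = NULL, neutralize = TRUE,
                                 largestFragment = TRUE, clearStereo = TRUE,
                                 canonicalTautomer = FALSE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (isTRUE(canonicalTautomer))
    stop("tautomer canonicalization is not available in this toolkit")
  if (is.null(ids)) ids <- paste0("cpd", seq_along(smiles))
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  work <- if (clearStereo) .stripStereo(smiles) else smiles

  can0 <- .obCanonical(work)
  ok <- !is.na(can0)
  failures <- data.frame(id = ids[!ok], smiles = smiles[!ok],
                         reason = rep("unparseable SMILES", sum(!ok)),
                         stringsAsFactors = FALSE)
  molecules <- list()
  if (any(ok)) {
    keys <- paste0("m", which(ok))
    inp <- paste0(work[ok], "\t", keys, "\n", collapse = "")
    sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", inp)
    mol2 <- .parseMol2(ChemmineOB::convertFormat("SMI", "MOL2", inp))
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    writeLines(sdf_txt, tf)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE))
    titles <- vapply(ChemmineR::SDFset2SDF(sdfset),
                     function(x) unname(ChemmineR::header(x)["Molecule_Name"]),
                     character(1))
    idx_ok <- which(ok)
    mols <- vector("list", length(idx_ok))
    fail_extra <- logical(length(idx_ok))
    for (k in seq_along(idx_ok)) {
      key <- keys[k]
      pos <- match(key, titles)
      types <- mol2[[key]]
      if (is.na(pos) || is.null(types)) { fail_extra[k] <- TRUE; next }
      m <- tryCatch(
        .buildMolecule(sdfset[[pos]], types, ids[idx_ok[k]],
                       neutralize = neutralize,
                       largestFragment = largestFragment),
        error = function(e) NULL)
      if (is.null(m)) { fail_extra[k] <- TRUE; next }
      mols[[k]] <- m
    }
    if (any(fail_extra))
      failures <- rbind(failures,
        data.frame(id = ids[idx_ok[fail_extra]],
                   smiles = smiles[idx_ok[fail_extra]],
                   reason = "structure perception failed",
                   stringsAsFactors = FALSE))
    mols <- mols[!fail_extra]
    if (length(mols)) {
      # canonical SMILES of the standardized structures, in one batch
      v2k <- vapply(seq_along(mols),
                    function(i) .writeV2000(mols[[i]], paste0("s", i)),
                    character(1))
      can_out <- ChemmineOB::convertFormat("SDF", "CAN",
                                           paste0(v2k, collapse = "\n"))
      can_lines <- strsplit(can_out, "\n", fixed = TRUE)[[1]]
      can_lines <- can_lines[nzchar(trimws(can_lines))]
      toks <- strsplit(can_lines, "\t", fixed = TRUE)
      can_map <- stats::setNames(vapply(toks, `[`, "", 1),
                                 trimws(vapply(toks, `[`, "", 2)))
      for (i in seq_along(mols))
        mols[[i]]@smiles <- unname(can_map[paste0("s", i)])
      names(mols) <- vapply(mols, function(m) m@id, "")
      molecules <- mols
    }
  }
  list(molecules = molecules, failures = failures)
}

#' Standardize a single structure
#'
#' Single-molecule variant of [standardizeMolecules()]; raises an error
#' carrying the offending string when the SMILES cannot be parsed.
#'
#' @param smiles one SMILES string.
#' @param ... passed to [standardizeMolecules()].
#' @return a [Molecule-class].
#' @examples
#' m <- standardizeMolecule("CC(=O)[O-]")
#' m@charge  # neutralized
#' @export
standardizeMolecule <- function(smiles, ...) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  res <- standardizeMolecules(smiles, ids = "x", ...)
  if (!length(res$molecules))
    stop("cannot standardize SMILES: '", smiles, "' (",
         res$failures$reason[1], ")")
  res$molecules[[1]]
}

# Assemble a Molecule from a parsed SDF record + MOL2 atom types.
.buildMolecule <- function(sdf, mol2types, id, neutralize = TRUE,
                           largestFragment = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (n < 1) stop("no atoms")
  el <- sub("_[0-9]+$", "", rownames(ab))
  # the V2000 charge code lands in ChemmineR's "C6" column; single-atom
  # records may carry fewer columns (no charge information at all)
  chg_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  q <- .decodeSdfCharge(chg_col)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    m <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
    m <- m[m[, 1] >= 1L & m[, 2] >= 1L, , drop = FALSE]  # placeholder rows
    m[m[, 3] == 4L, 3] <- 1L  # defensive: any residual aromatic code
    m
  }
  if (length(mol2types) != n) stop("MOL2/SDF atom count mismatch")
  aromatic <- grepl("\\.ar$", mol2types, ignore.case = TRUE)

  if (largestFragment && n > 1) {
    memb <- .fragmentMembership(n, bonds)
    sizes <- tabulate(memb)
    keep_frag <- which.max(sizes)
    keep <- which(memb == keep_frag)
    remap <- match(seq_len(n), keep)
    el <- el[keep]; q <- q[keep]; aromatic <- aromatic[keep]
    mol2types <- mol2types[keep]
    if (nrow(bonds) > 0) {
      inb <- bonds[, 1] %in% keep & bonds[, 2] %in% keep
      bonds <- bonds[inb, , drop = FALSE]
      bonds[, 1] <- remap[bonds[, 1]]
      bonds[, 2] <- remap[bonds[, 2]]
    }
    n <- length(el)
  }

  deg <- integer(n)
  bosum <- numeric(n)
  if (nrow(bonds) > 0) {
    deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
    bosum <- vapply(seq_len(n), function(a)
      sum(bonds[bonds[, 1] == a | bonds[, 2] == a, 3]), numeric(1))
  }

  if (neutralize && any(q != 0L)) {
    nb <- function(a) {
      if (nrow(bonds) == 0) return(integer(0))
      c(bonds[bonds[, 1] == a, 2], bonds[bonds[, 2] == a, 1])
    }
    for (a in which(q != 0L)) {
      neigh_q <- q[nb(a)]
      v0 <- .DEFAULT_VALENCE[el[a]]
      if (is.na(v0)) next                      # metals etc.: leave charged
      if (q[a] < 0 && !any(neigh_q > 0)) {
        if (v0 - bosum[a] >= 0) q[a] <- 0L     # protonate the acid anion
      } else if (q[a] > 0 && !any(neigh_q < 0)) {
        if (bosum[a] <= v0) q[a] <- 0L         # deprotonate the base cation
      }
    }
  }

  nH <- .implicitH(el, q, bosum)
  mass <- .ATOMIC_MASS[el]
  mass[is.na(mass)] <- 0
  mw <- sum(mass) + 1.008 * sum(nH)

  new("Molecule", id = id, smiles = NA_character_, element = el,
      charge = as.integer(q), aromatic = aromatic,
      hybridization = .hybridFromMol2(mol2types, deg),
      bonds = bonds, nH = nH, mw = mw)
}

#' @describeIn Molecule-class number of heavy atoms.
#' @param x,object a `Molecule`.
#' @export
nAtoms <- function(x) length(x@element)

#' @describeIn Molecule-class heavy-atom degrees.
#' @export
atomDegrees <- function(x) {
  n <- nAtoms(x)
  if (nrow(x@bonds) == 0) return(integer(n))
  tabulate(c(x@bonds[, 1], x@bonds[, 2]), nbins = n)
}

#' @describeIn Molecule-class molecular weight (g/mol).
#' @export
molWeight <- function(x) x@mw

setMethod("show", "Molecule", function(object) {
  cat("Molecule", object@id, "\n  SMILES:", object@smiles,
      "\n  heavy atoms:", nAtoms(object), " bonds:", nrow(object@bonds),
      " MW:", round(object@mw, 2), "\n")
})
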