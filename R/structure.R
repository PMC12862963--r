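#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid} (3-letter residue name), \code{elety}
#'   (atom name), \code{x}, \code{y}, \code{z} (Angstrom), \code{o}
#'   (occupancy), \code{is_polymer} (logical). Missing \code{insert},
#'   \code{o} and \code{is_polymer} are filled with defaults.
#' @return object of class \code{"tk_structure"}.
#' @export
structure_model <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!"o" %in% names(atoms)) atoms$o <- 1
  if (!"is_polymer" %in% names(atoms)) atoms$is_polymer <- TRUE
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  structure(list(atoms = atoms), class = "tk_structure")
}

#' @export
print.tk_structure <- function(x, ...) {
  a <- x$atoms
  cat("Structure model:", nrow(a), "atoms,",
      length(unique(a$chain[a$is_polymer])), "polymer chain(s)\n")
  for (ch in unique(a$chain[a$is_polymer])) {
    res <- a[a$is_polymer & a$chain == ch, ]
    cat(sprintf("  chain %s: residues %d..%d\n", ch, min(res$resno),
                max(res$resno)))
  }
  invisible(x)
}

#' Read a crystallographic coordinate file
#'
#' Parses a PDB (or mmCIF) file via \code{bio3d::read.pdb} /
#' \code{bio3d::read.cif}. When alternate locations are present, the
#' highest-occupancy conformer of each atom is kept (ties: first). Waters
#' and small-molecule ligands are retained but flagged non-polymer.
#'
#' @param path coordinate file.
#' @return a \code{\link{structure_model}}.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  pdb <- tryCatch(
    if (grepl("\\.cif$", path, ignore.case = TRUE))
      bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  # highest-occupancy alternate location per atom
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(key, -a$o, seq_len(nrow(a)))
  a <- a[ord, ]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety,
                           sep = "\r")), ]
  a <- a[order(as.integer(rownames(a))), ]
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z, o = a$o,
                      is_polymer = a$type == "ATOM" & a$resid != "HOH",
                      stringsAsFactors = FALSE)
  structure_model(atoms)
}

# One-letter Calpha sequence and residue bookkeeping for a chain.
chain_ca <- function(m, chain) {
  a <- m$atoms
  ca <- a[a$is_polymer & a$chain == chain & a$elety == "CA", ]
  ca <- ca[order(ca$resno, ca$insert), ]
  if (!nrow(ca)) stop("chain '", chain, "' has no Calpha atoms")
  seq1 <- suppressWarnings(bio3d::aa321(ca$resid))
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  list(resno = ca$resno, insert = ca$insert, seq = paste(seq1, collapse = ""),
       xyz = as.matrix(ca[, c("x", "y", "z")]))
}

#' Build a residue correspondence between two chains
#'
#' Sequence-aligns the Calpha sequences of the two chains (global alignment,
#' free terminal gaps) and pairs aligned non-gap columns whose residues
#' both carry the named atom. No outlier trimming is applied.
#'
#' @param a,b \code{tk_structure} models.
#' @param chain_a,chain_b chain identifiers.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return object of class \code{"tk_correspondence"}: data.frame of paired
#'   residues plus the paired coordinate matrices \code{xyz_a},
#'   \code{xyz_b} and \code{n_pairs}.
#' @export
build_correspondence <- function(a, b, chain_a = "A", chain_b = "A",
                                 scheme = scoring_scheme()) {
  ca <- chain_ca(a, chain_a)
  cb <- chain_ca(b, chain_b)
  aln <- tk_align(ca$seq, cb$seq, scheme)
  ga <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  keep <- ga != "-" & gb != "-"
  pa <- cumsum(ga != "-")[keep]
  pb <- cumsum(gb != "-")[keep]
  pairs <- data.frame(resno_a = ca$resno[pa], insert_a = ca$insert[pa],
                      resno_b = cb$resno[pb], insert_b = cb$insert[pb],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, xyz_a = ca$xyz[pa, , drop = FALSE],
                 xyz_b = cb$xyz[pb, , drop = FALSE],
                 n_pairs = length(pa), atom = "CA",
                 chain_a = chain_a, chain_b = chain_b),
            class = "tk_correspondence")
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping point set Q onto P via
#' the SVD construction, with a reflection guard enforcing det(U) = +1.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return list with \code{U} (3 x 3 rotation), \code{t} (translation so
#'   that \code{Q_fit = Q \%*\% t(U) + t}), \code{rmsd},
#'   \code{deviations} (per-point distances after superposition).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 point pairs")
  pm <- colMeans(P); qm <- colMeans(Q)
  Pc <- sweep(P, 2, pm); Qc <- sweep(Q, 2, qm)
  svp <- svd(Pc)$d
  if (svp[1] == 0 || svp[2] < 1e-9 * svp[1])
    stop("degenerate (collinear or coincident) point set")
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate point set: singular cross-covariance")
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- pm - as.vector(U %*% qm)
  Qfit <- Q %*% t(U) + matrix(tvec, n, 3, byrow = TRUE)
  dev <- sqrt(rowSums((P - Qfit)^2))
  list(U = U, t = tvec, rmsd = sqrt(mean(dev^2)), deviations = dev)
}

#' Superpose two structure selections
#'
#' Rigid-body least-squares superposition of corresponding Calpha atoms.
#' When no correspondence is supplied it is built by sequence alignment of
#' the chains (\code{\link{build_correspondence}}).
#'
#' @param a,b \code{tk_structure} models (b is fitted onto a).
#' @param corr optional \code{tk_correspondence}.
#' @param chain_a,chain_b chains used when \code{corr} is NULL.
#' @param scheme scoring scheme for the sequence alignment.
#' @return object of class \code{"tk_superposition"}: rotation \code{U},
#'   translation \code{t}, \code{rmsd}, \code{per_pair_deviation},
#'   \code{n_pairs}, \code{corr}.
#' @export
superpose <- function(a, b, corr = NULL, chain_a = "A", chain_b = "A",
                      scheme = scoring_scheme()) {
  if (is.null(corr)) corr <- build_correspondence(a, b, chain_a, chain_b,
                                                  scheme)
  if (corr$n_pairs < 3L) stop("need at least 3 corresponding atom pairs")
  fit <- kabsch(corr$xyz_a, corr$xyz_b)
  structure(list(U = fit$U, t = fit$t, rmsd = fit$rmsd,
                 per_pair_deviation = fit$deviations,
                 n_pairs = corr$n_pairs, corr = corr),
            class = "tk_superposition")
}

#' @export
print.tk_superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d pairs, RMSD %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Per-residue deviations after superposition
#'
#' @param sup a \code{\link{superpose}} result.
#' @return data.frame of corresponding residue pairs with the
#'   post-superposition Calpha-Calpha distance (Angstrom), in
#'   correspondence order. The mean of squared deviations reproduces
#'   rmsd^2 exactly.
#' @export
per_residue_deviation <- function(sup) {
  stopifnot(inherits(sup, "tk_superposition"))
  cbind(sup$corr$pairs, deviation = sup$per_pair_deviation)
}

# Terminal charged side-chain atoms by residue type.
.TERMINAL_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                        GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"),
                        HIS = c("ND1", "NE2"))
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

parse_res_address <- function(addr) {
  if (is.list(addr)) return(list(chain = addr$chain %||% NA_character_,
                                 resno = as.integer(addr$resno)))
  if (is.character(addr) && grepl("/", addr, fixed = TRUE)) {
    p <- strsplit(addr, "/", fixed = TRUE)[[1]]
    return(list(chain = p[1], resno = as.integer(p[2])))
  }
  list(chain = NA_character_, resno = as.integer(addr))
}

res_atoms <- function(m, chain, resno, side_chain_only = TRUE,
                      heavy_only = TRUE) {
  a <- m$atoms
  sel <- a$is_polymer & a$chain == chain & a$resno == resno
  if (side_chain_only) sel <- sel & !(a$elety %in% .BACKBONE)
  if (heavy_only) sel <- sel & !grepl("^H", a$elety)
  a[sel, , drop = FALSE]
}

min_atom_distance <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(NA_real_)
  XA <- as.matrix(A[, c("x", "y", "z")])
  XB <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(XA^2), rep(1, nrow(XB))) - 2 * XA %*% t(XB) +
    outer(rep(1, nrow(XA)), rowSums(XB^2))
  sqrt(max(0, min(d2)))
}

#' Distance between the functional groups of two residues
#'
#' Default rule (\code{terminal-charged-atoms}): minimum distance between
#' the terminal charged atoms of the two side chains (e.g. the lysine NZ
#' amine and either carboxylate oxygen of a glutamate), the convention
#' used for the K68-E83 salt-bridge gap that reports the open alpha-C
#' conformation. \code{closest-heavy-sidechain}: minimum over all
#' side-chain heavy-atom pairs. When no chain is given the distance is
#' computed per chain copy and aggregated as mean +/- half-range.
#'
#' @param m a \code{tk_structure}.
#' @param resA,resB residue addresses: \code{"A/68"}, \code{"68"}, or
#'   \code{list(chain=, resno=)}.
#' @param rule distance rule.
#' @return list with \code{per_chain} (named numeric), \code{mean},
#'   \code{spread} (half-range across copies), \code{rule},
#'   \code{unresolved} (chains lacking side-chain atoms).
#' @export
functional_group_distance <- function(m, resA, resB,
                                      rule = c("terminal-charged-atoms",
                                               "closest-heavy-sidechain")) {
  rule <- match.arg(rule)
  ra <- parse_res_address(resA)
  rb <- parse_res_address(resB)
  chains <- if (!is.na(ra$chain)) ra$chain
            else unique(m$atoms$chain[m$atoms$is_polymer])
  per <- c(); unresolved <- character(0)
  for (ch in chains) {
    chb <- if (!is.na(rb$chain)) rb$chain else ch
    A <- res_atoms(m, ch, ra$resno)
    B <- res_atoms(m, chb, rb$resno)
    if (rule == "terminal-charged-atoms" && nrow(A) && nrow(B)) {
      ta <- .TERMINAL_ATOMS[[A$resid[1]]]
      if (!is.null(ta)) A <- A[A$elety %in% ta, , drop = FALSE]
      tb <- .TERMINAL_ATOMS[[B$resid[1]]]
      if (!is.null(tb)) B <- B[B$elety %in% tb, , drop = FALSE]
    }
    d <- min_atom_distance(A, B)
    if (is.na(d)) unresolved <- c(unresolved, ch) else {
      per[ch] <- d
    }
  }
  if (!length(per))
    return(list(per_chain = per, mean = NA_real_, spread = NA_real_,
                rule = rule, unresolved = unresolved))
  list(per_chain = per, mean = mean(per),
       spread = (max(per) - min(per)) / 2, rule = rule,
       unresolved = unresolved)
}

#' Check contiguity of a hydrophobic spine
#'
#' For consecutive residues in the listed order, computes the minimum
#' side-chain heavy-atom distance (Calpha fallback for glycine) and flags
#' the spine contiguous iff every consecutive pair is within the cutoff.
#' An optional completion contact (e.g. the CRD position -2 residue against
#' the beta-3 theta column, which closes the C-spine in autoinhibited TK)
#' is reported alongside.
#'
#' @param m a \code{tk_structure}.
#' @param residues residue addresses in spine order (see
#'   \code{\link{functional_group_distance}} for address formats).
#' @param chain chain to use for addresses without one.
#' @param cutoff contiguity cutoff in Angstrom (default 5.5).
#' @param completion optional length-2 list of residue addresses whose
#'   contact distance is reported as the spine-completion contact.
#' @return object of class \code{"tk_spine_report"}: data.frame of
#'   consecutive pairs and distances, \code{contiguous} flag (NA when a
#'   residue is missing), \code{missing} residues, optional
#'   \code{completion} distance.
#' @export
spine_check <- function(m, residues, chain = "A", cutoff = 5.5,
                        completion = NULL) {
  addr <- lapply(residues, parse_res_address)
  atoms <- lapply(addr, function(a) {
    ch <- if (is.na(a$chain)) chain else a$chain
    at <- res_atoms(m, ch, a$resno)
    if (!nrow(at)) at <- res_atoms(m, ch, a$resno, side_chain_only = FALSE)
    at
  })
  labels <- vapply(addr, function(a)
    paste0(if (is.na(a$chain)) chain else a$chain, "/", a$resno), "")
  missing <- labels[vapply(atoms, nrow, 0L) == 0L]
  pairs <- data.frame(from = labels[-length(labels)], to = labels[-1],
                      distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(length(atoms) - 1L))
    pairs$distance[i] <- min_atom_distance(atoms[[i]], atoms[[i + 1L]])
  contiguous <- if (length(missing)) NA else all(pairs$distance <= cutoff)
  comp <- NULL
  if (!is.null(completion)) {
    ca <- parse_res_address(completion[[1]])
    cb <- parse_res_address(completion[[2]])
    comp <- min_atom_distance(
      res_atoms(m, if (is.na(ca$chain)) chain else ca$chain, ca$resno),
      res_atoms(m, if (is.na(cb$chain)) chain else cb$chain, cb$resno))
  }
  structure(list(pairs = pairs, cutoff = cutoff, contiguous = contiguous,
                 missing = missing, completion = comp),
            class = "tk_spine_report")
}

#' @export
print.tk_spine_report <- function(x, ...) {
  cat("Spine contiguity (cutoff", x$cutoff, "A):",
      if (isTRUE(x$contiguous)) "contiguous"
      else if (is.na(x$contiguous)) "undefined (missing residues)"
      else "NOT contiguous", "\n")
  print(x$pairs)
  if (!is.null(x$completion))
    cat(sprintf("  completion contact: %.2f A\n", x$completion))
  invisible(x)
}
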