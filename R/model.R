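# Atomic protein model: backbone N/CA/C/O plus a reduced linear side chain
# per residue (CB and the unbranched chi chain; branch atoms are omitted).
# Coordinates are in Angstroms, torsions in degrees.

# ideal geometry used by the builder and as harmonic reference values
IDEAL <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_CA_CB = 1.53, b_side = 1.52, b_S = 1.81,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_N_CA_CB = 110.5, a_side = 111.0)

# reduced side-chain chains (after CB, each atom adds one chi angle)
SIDE_CHAINS <- list(
  G = character(0), A = "CB",
  S = c("CB", "OG"), C = c("CB", "SG"), T = c("CB", "OG1"),
  V = c("CB", "CG1"), L = c("CB", "CG", "CD1"), I = c("CB", "CG1", "CD1"),
  M = c("CB", "CG", "SD", "CE"), F = c("CB", "CG", "CD1"),
  Y = c("CB", "CG", "CD1"), W = c("CB", "CG", "CD1"),
  P = c("CB", "CG", "CD"), D = c("CB", "CG", "OD1"), N = c("CB", "CG", "OD1"),
  E = c("CB", "CG", "CD", "OE1"), Q = c("CB", "CG", "CD", "OE1"),
  K = c("CB", "CG", "CD", "CE", "NZ"), R = c("CB", "CG", "CD", "NE", "CZ"),
  H = c("CB", "CG", "ND1"), X = "CB")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
              X = "UNK")

n_chi <- function(restype) max(length(SIDE_CHAINS[[restype]]) - 1L, 0L)

#' Construct a protein model object
#'
#' @param atoms data.frame with columns `res` (1-based residue index),
#'   `resname` (one-letter code), `atom` (name), `x`, `y`, `z`.
#' @param sequence character vector of one-letter codes, one per residue
#'   (residues without atoms are "unbuilt").
#' @param breaks integer vector: residue indices i such that the chain is
#'   broken between i and i+1.
#' @param unbuilt list of `c(start, end)` residue spans with no coordinates.
#' @return Object of class `protein_model`.
#' @export
protein_model <- function(atoms, sequence, breaks = integer(),
                          unbuilt = list()) {
  stopifnot(is.data.frame(atoms),
            all(c("res", "resname", "atom", "x", "y", "z") %in% names(atoms)))
  structure(list(atoms = atoms, sequence = sequence,
                 breaks = as.integer(breaks), unbuilt = unbuilt),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("protein_model: %d residues, %d atoms", length(x$sequence),
              nrow(x$atoms)))
  if (length(x$breaks)) cat(sprintf(", %d chain break(s)", length(x$breaks)))
  if (length(x$unbuilt)) cat(sprintf(", %d unbuilt segment(s)", length(x$unbuilt)))
  cat("\n")
  invisible(x)
}

n_residues <- function(model) length(model$sequence)

model_xyz <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

set_model_xyz <- function(model, xyz) {
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

atom_row <- function(model, res, name) {
  which(model$atoms$res == res & model$atoms$atom == name)
}

atom_coord <- function(model, res, name) {
  i <- atom_row(model, res, name)
  if (!length(i)) return(NULL)
  as.numeric(model$atoms[i[1L], c("x", "y", "z")])
}

#' Validate model chain geometry
#'
#' Checks that coordinates are finite and that consecutive-residue C-N
#' distances lie within \[1.2, 1.5\] Angstroms except across annotated chain
#' breaks or unbuilt segments.
#'
#' @param model a [protein_model()].
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_model <- function(model) {
  xyz <- model_xyz(model)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in model")
  built <- sort(unique(model$atoms$res))
  for (i in built) {
    if (!(i + 1L) %in% built) next
    if (i %in% model$breaks) next
    c1 <- atom_coord(model, i, "C")
    n2 <- atom_coord(model, i + 1L, "N")
    if (is.null(c1) || is.null(n2)) next
    d <- vnorm(c1 - n2)
    if (d < 1.2 || d > 1.5) {
      stop(sprintf("peptide bond %d-%d has length %.2f A (no break annotated)",
                   i, i + 1L, d))
    }
  }
  invisible(TRUE)
}

# --- builders -------------------------------------------------------------

#' Build a backbone from torsions at ideal geometry
#'
#' @param sequence character vector of one-letter residue codes.
#' @param phi,psi backbone torsions in degrees (length = n residues;
#'   `phi[1]` is unused).
#' @param omega peptide-bond torsions; `omega[i]` is the bond preceding
#'   residue i (`omega[1]` unused; default 180).
#' @param side_chains build side chains at the given chi (default: extended,
#'   all chi = 180); `FALSE` for backbone only.
#' @return A [protein_model()].
#' @export
build_backbone <- function(sequence, phi, psi, omega = NULL,
                           side_chains = TRUE) {
  n <- length(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  coords <- vector("list", n)
  # seed residue
  N <- c(0, 0, 0)
  CA <- c(IDEAL$b_N_CA, 0, 0)
  ang <- IDEAL$a_N_CA_C * DEG
  C <- CA + IDEAL$b_CA_C * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N2 <- place_atom(coords[[i - 1L]]$N, coords[[i - 1L]]$CA,
                       coords[[i - 1L]]$C, IDEAL$b_C_N, IDEAL$a_CA_C_N,
                       psi[i - 1L])
      CA2 <- place_atom(coords[[i - 1L]]$CA, coords[[i - 1L]]$C, N2,
                        IDEAL$b_N_CA, IDEAL$a_C_N_CA, omega[i])
      C2 <- place_atom(coords[[i - 1L]]$C, N2, CA2,
                       IDEAL$b_CA_C, IDEAL$a_N_CA_C, phi[i])
      N <- N2; CA <- CA2; C <- C2
    }
    O <- place_atom(N, CA, C, IDEAL$b_C_O, IDEAL$a_CA_C_O, psi[i] + 180)
    coords[[i]] <- list(N = N, CA = CA, C = C, O = O)
  }
  rows <- lapply(seq_len(n), function(i) {
    data.frame(res = i, resname = sequence[i],
               atom = c("N", "CA", "C", "O"),
               x = c(coords[[i]]$N[1L], coords[[i]]$CA[1L], coords[[i]]$C[1L], coords[[i]]$O[1L]),
               y = c(coords[[i]]$N[2L], coords[[i]]$CA[2L], coords[[i]]$C[2L], coords[[i]]$O[2L]),
               z = c(coords[[i]]$N[3L], coords[[i]]$CA[3L], coords[[i]]$C[3L], coords[[i]]$O[3L]),
               stringsAsFactors = FALSE)
  })
  model <- protein_model(do.call(rbind, rows), sequence)
  if (isTRUE(side_chains)) {
    for (i in seq_len(n)) model <- build_side_chain(model, i)
  }
  model
}

# CB direction bisecting N-CA and C-CA, tilted out of their plane; the
# tilt is solved so that angle(N, CA, CB) hits the ideal value exactly
cb_position <- function(N, CA, C) {
  u1 <- unitv(N - CA)
  u2 <- unitv(C - CA)
  b <- unitv(-(u1 + u2))
  nrm <- unitv(vcross(u2, u1))
  target <- cos(IDEAL$a_N_CA_CB * DEG)
  ca <- target / sum(b * u1)
  ca <- pmin(1, pmax(-1, ca))
  sa <- sqrt(1 - ca^2)
  CA + IDEAL$b_CA_CB * (b * ca + nrm * sa)
}

side_bond_length <- function(name) {
  if (grepl("^S", name)) IDEAL$b_S else IDEAL$b_side
}

#' Build (or rebuild) the reduced side chain of one residue
#'
#' @param model a [protein_model()] with backbone atoms for `res`.
#' @param res residue index.
#' @param chi chi angles in degrees (recycled/truncated to the residue's chi
#'   count; default extended, all 180; proline uses its fixed ring-like chi).
#' @return The model with side-chain atoms replaced.
#' @export
build_side_chain <- function(model, res, chi = NULL) {
  restype <- model$sequence[res]
  chain <- SIDE_CHAINS[[restype]]
  if (is.null(chain)) stop("residue type absent from side-chain topology: ",
                           restype)
  # drop existing side-chain atoms of this residue
  drop <- model$atoms$res == res & !model$atoms$atom %in% c("N", "CA", "C", "O")
  model$atoms <- model$atoms[!drop, , drop = FALSE]
  if (!length(chain)) return(reindex_atoms(model))
  N <- atom_coord(model, res, "N")
  CA <- atom_coord(model, res, "CA")
  C <- atom_coord(model, res, "C")
  if (is.null(N) || is.null(CA) || is.null(C)) {
    stop("backbone incomplete for residue ", res)
  }
  nchi <- length(chain) - 1L
  if (is.null(chi)) {
    chi <- if (restype == "P") c(-25, 35)[seq_len(nchi)] else rep(180, nchi)
  }
  chi <- rep_len(chi, max(nchi, 1L))
  pos <- list(cb_position(N, CA, C))
  frame <- list(N, CA, pos[[1L]])
  for (k in seq_len(nchi)) {
    newpos <- place_atom(frame[[1L]], frame[[2L]], frame[[3L]],
                         side_bond_length(chain[k + 1L]), IDEAL$a_side,
                         chi[k])
    pos[[k + 1L]] <- newpos
    frame <- list(frame[[2L]], frame[[3L]], newpos)
  }
  xyz <- do.call(rbind, pos)
  add <- data.frame(res = res, resname = restype, atom = chain,
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    stringsAsFactors = FALSE)
  model$atoms <- rbind(model$atoms, add)
  reindex_atoms(model)
}

reindex_atoms <- function(model) {
  model$atoms <- model$atoms[order(model$atoms$res,
                                   match(model$atoms$atom,
                                         c("N", "CA", "C", "O",
                                           unique(unlist(SIDE_CHAINS))))), ,
                             drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}
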