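# Torsion bookkeeping: measuring phi/psi/omega/chi, rotating about torsions,
# and enumerating the rotatable torsions of a model.

chain_segment_end <- function(model, res) {
  # last residue of the covalently connected segment containing `res`
  n <- n_residues(model)
  brks <- sort(model$breaks)
  after <- brks[brks >= res]
  if (length(after)) after[1L] else n
}

#' Backbone torsions of a model
#'
#' @param model a [protein_model()].
#' @return data.frame with columns `res`, `phi`, `psi`, `omega` (degrees;
#'   `NA` where undefined, e.g. chain ends or across breaks). `omega[i]` is
#'   the peptide torsion preceding residue i.
#' @export
backbone_torsions <- function(model) {
  n <- n_residues(model)
  out <- data.frame(res = seq_len(n), phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  get <- function(i, a) atom_coord(model, i, a)
  for (i in seq_len(n)) {
    N <- get(i, "N"); CA <- get(i, "CA"); C <- get(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1L && !((i - 1L) %in% model$breaks)) {
      Cp <- get(i - 1L, "C")
      CAp <- get(i - 1L, "CA")
      if (!is.null(Cp)) {
        out$phi[i] <- dihedral_angle(Cp, N, CA, C)
        if (!is.null(CAp)) out$omega[i] <- dihedral_angle(CAp, Cp, N, CA)
      }
    }
    if (i < n && !(i %in% model$breaks)) {
      Nn <- get(i + 1L, "N")
      if (!is.null(Nn)) out$psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  out
}

#' Side-chain chi angles of one residue
#'
#' @param model a [protein_model()].
#' @param res residue index.
#' @return Numeric vector of chi angles (degrees), length = the residue's
#'   chi count (possibly 0).
#' @export
chi_angles <- function(model, res) {
  restype <- model$sequence[res]
  chain <- SIDE_CHAINS[[restype]]
  k <- n_chi(restype)
  if (k == 0L) return(numeric(0))
  names_chain <- c("N", "CA", chain)
  out <- numeric(k)
  for (j in seq_len(k)) {
    atoms <- lapply(names_chain[j:(j + 3L)], function(a) atom_coord(model, res, a))
    if (any(vapply(atoms, is.null, TRUE))) return(rep(NA_real_, k))
    out[j] <- dihedral_angle(atoms[[1L]], atoms[[2L]], atoms[[3L]], atoms[[4L]])
  }
  out
}

# rows of model$atoms that move when the given torsion is rotated
torsion_moving_rows <- function(model, res, type, chi_index = 1L) {
  at <- model$atoms
  seg_end <- chain_segment_end(model, res)
  later <- at$res > res & at$res <= seg_end
  if (type == "phi") {
    own <- at$res == res & !at$atom %in% c("N", "CA")
    which(own | later)
  } else if (type == "psi") {
    own <- at$res == res & at$atom == "O"
    which(own | later)
  } else if (type == "omega") {
    own <- at$res == res & at$atom != "N"
    which(own | later)
  } else if (type == "chi") {
    chain <- SIDE_CHAINS[[model$sequence[res]]]
    moving <- chain[(chi_index + 1L):length(chain)]
    which(at$res == res & at$atom %in% moving)
  } else stop("unknown torsion type: ", type)
}

torsion_axis <- function(model, res, type, chi_index = 1L) {
  if (type == "phi") {
    list(a = atom_coord(model, res, "N"), b = atom_coord(model, res, "CA"))
  } else if (type == "psi") {
    list(a = atom_coord(model, res, "CA"), b = atom_coord(model, res, "C"))
  } else if (type == "omega") {
    list(a = atom_coord(model, res - 1L, "C"), b = atom_coord(model, res, "N"))
  } else {
    chain <- c("N", "CA", SIDE_CHAINS[[model$sequence[res]]])
    list(a = atom_coord(model, res, chain[chi_index + 1L]),
         b = atom_coord(model, res, chain[chi_index + 2L]))
  }
}

#' Rotate a torsion by a given increment
#'
#' Rotates all atoms downstream of the torsion (within the residue's chain
#' segment) by `delta` degrees about the bond axis. Bond lengths and angles
#' are untouched, which is the torsion-space guarantee.
#'
#' @param model a [protein_model()].
#' @param res residue index.
#' @param type `"phi"`, `"psi"`, `"omega"` or `"chi"`.
#' @param delta rotation increment in degrees.
#' @param chi_index which chi angle (for `type = "chi"`).
#' @return The rotated model.
#' @export
rotate_torsion <- function(model, res, type, delta, chi_index = 1L) {
  if (abs(delta) < 1e-12) return(model)
  ax <- torsion_axis(model, res, type, chi_index)
  rows <- torsion_moving_rows(model, res, type, chi_index)
  if (!length(rows)) return(model)
  xyz <- model_xyz(model)
  # measured dihedrals decrease under a right-handed rotation about the
  # bond axis, hence the sign flip
  xyz[rows, ] <- rotate_points(xyz[rows, , drop = FALSE], ax$a,
                               ax$b - ax$a, -delta)
  set_model_xyz(model, xyz)
}

# set a torsion to an absolute value (degrees)
set_torsion <- function(model, res, type, value, chi_index = 1L) {
  cur <- switch(type,
    phi = backbone_torsions(model)$phi[res],
    psi = backbone_torsions(model)$psi[res],
    omega = backbone_torsions(model)$omega[res],
    chi = chi_angles(model, res)[chi_index])
  if (is.na(cur)) stop("torsion undefined for residue ", res)
  rotate_torsion(model, res, type, value - cur, chi_index)
}

# enumerate rotatable torsions (phi/psi per residue plus chi chains;
# omega excluded; proline chi fixed); optionally limited to a residue span
rotatable_torsions <- function(model, span = NULL) {
  n <- n_residues(model)
  built <- sort(unique(model$atoms$res))
  res_set <- if (is.null(span)) built else intersect(built, span[1L]:span[2L])
  out <- list()
  for (i in res_set) {
    if (i > 1L && (i - 1L) %in% built && !((i - 1L) %in% model$breaks)) {
      out[[length(out) + 1L]] <- list(res = i, type = "phi", chi_index = 1L)
    }
    if (i < n && (i + 1L) %in% built && !(i %in% model$breaks)) {
      out[[length(out) + 1L]] <- list(res = i, type = "psi", chi_index = 1L)
    }
    if (model$sequence[i] != "P") {
      for (k in seq_len(n_chi(model$sequence[i]))) {
        out[[length(out) + 1L]] <- list(res = i, type = "chi", chi_index = k)
      }
    }
  }
  out
}
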