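# Reduced molecular-mechanics energy: harmonic bond/angle terms to ideal
# values, periodic chi and omega torsion terms, a repulsive-only soft
# nonbonded term, and a Kabsch-Sander hydrogen-bond term. Units kcal/mol.
# The H-bond term is scored but not differentiated; minimisers operate on
# the differentiable terms.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

atom_element <- function(name) substr(gsub("[0-9]", "", name), 1L, 1L)

#' Default reduced energy model
#'
#' @param k_bond,k_angle harmonic force constants (kcal/mol/A^2,
#'   kcal/mol/rad^2).
#' @param k_chi 3-fold chi torsion barrier height (kcal/mol).
#' @param k_omega 2-fold omega restraint (kcal/mol).
#' @param k_rep soft repulsion constant (kcal/mol/A^2), engaged below
#'   `rep_scale` times the summed van der Waals radii.
#' @param rep_scale clash-onset scale factor.
#' @param w_hbond weight on the Kabsch-Sander hydrogen-bond energies.
#' @return List of class `energy_model`.
#' @export
energy_model <- function(k_bond = 300, k_angle = 80, k_chi = 0.8,
                         k_omega = 8, k_rep = 25, rep_scale = 0.85,
                         w_hbond = 1) {
  structure(list(k_bond = k_bond, k_angle = k_angle, k_chi = k_chi,
                 k_omega = k_omega, k_rep = k_rep, rep_scale = rep_scale,
                 w_hbond = w_hbond),
            class = "energy_model")
}

ideal_bond_length <- function(a1, a2) {
  key <- paste(sort(c(a1, a2)), collapse = "-")
  known <- c("CA-N" = IDEAL$b_N_CA, "C-CA" = IDEAL$b_CA_C,
             "C-N" = IDEAL$b_C_N, "C-O" = IDEAL$b_C_O,
             "CA-CB" = IDEAL$b_CA_CB)
  if (!is.na(known[key])) return(unname(known[key]))
  if (atom_element(a1) == "S" || atom_element(a2) == "S") return(IDEAL$b_S)
  IDEAL$b_side
}

ideal_angle_value <- function(a1, a2, a3) {
  key <- paste(a1, a2, a3, sep = "-")
  key2 <- paste(a3, a2, a1, sep = "-")
  known <- c("N-CA-C" = IDEAL$a_N_CA_C, "CA-C-N" = IDEAL$a_CA_C_N,
             "C-N-CA" = IDEAL$a_C_N_CA, "CA-C-O" = IDEAL$a_CA_C_O,
             "O-C-N" = 123.0, "N-CA-CB" = IDEAL$a_N_CA_CB,
             "C-CA-CB" = IDEAL$a_N_CA_CB)
  v <- known[key]
  if (is.na(v)) v <- known[key2]
  if (is.na(v)) v <- IDEAL$a_side
  unname(v)
}

# bonds, angles, chi/omega torsion quadruples and nonbonded exclusions;
# cached on the model's atom table signature
model_topology <- function(model) {
  at <- model$atoms
  # cheap numeric signature: topology depends only on the atom table rows
  sig <- c(nrow(at), sum(at$res * seq_len(nrow(at))), sum(nchar(at$atom)),
           sum(utf8ToInt(paste(substr(at$atom, 1L, 1L), collapse = ""))),
           sum(utf8ToInt(paste(at$resname, collapse = "")) *
                 seq_len(sum(nchar(at$resname)))))
  cached <- .paraloop_cache$topology
  if (!is.null(cached) && identical(cached$sig, sig)) return(cached)

  n_at <- nrow(at)
  idx <- function(res, name) {
    i <- which(at$res == res & at$atom == name)
    if (length(i)) i[1L] else NA_integer_
  }
  built <- sort(unique(at$res))
  bonds <- list()
  add_bond <- function(i, j) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1L]] <<- c(i, j)
  }
  for (r in built) {
    iN <- idx(r, "N"); iCA <- idx(r, "CA"); iC <- idx(r, "C"); iO <- idx(r, "O")
    add_bond(iN, iCA); add_bond(iCA, iC); add_bond(iC, iO)
    chain <- SIDE_CHAINS[[model$sequence[r]]]
    if (length(chain)) {
      prev <- iCA
      for (a in chain) {
        ia <- idx(r, a)
        add_bond(prev, ia)
        prev <- ia
      }
    }
    if ((r + 1L) %in% built && !(r %in% model$breaks)) {
      add_bond(iC, idx(r + 1L, "N"))
    }
  }
  B <- do.call(rbind, bonds)
  # adjacency for angle enumeration and exclusions
  nb <- vector("list", n_at)
  for (k in seq_len(nrow(B))) {
    nb[[B[k, 1L]]] <- c(nb[[B[k, 1L]]], B[k, 2L])
    nb[[B[k, 2L]]] <- c(nb[[B[k, 2L]]], B[k, 1L])
  }
  angles <- list()
  for (j in seq_len(n_at)) {
    ns <- nb[[j]]
    if (length(ns) < 2L) next
    cmb <- utils::combn(sort(ns), 2L)
    for (c2 in seq_len(ncol(cmb))) {
      angles[[length(angles) + 1L]] <- c(cmb[1L, c2], j, cmb[2L, c2])
    }
  }
  A <- do.call(rbind, angles)
  b0 <- vapply(seq_len(nrow(B)), function(k) {
    ideal_bond_length(at$atom[B[k, 1L]], at$atom[B[k, 2L]])
  }, 0)
  a0 <- vapply(seq_len(nrow(A)), function(k) {
    ideal_angle_value(at$atom[A[k, 1L]], at$atom[A[k, 2L]], at$atom[A[k, 3L]])
  }, 0)
  # chi quadruples (rotatable side-chain torsions, proline excluded)
  chiq <- list()
  for (r in built) {
    if (model$sequence[r] == "P") next
    chain <- c("N", "CA", SIDE_CHAINS[[model$sequence[r]]])
    k <- n_chi(model$sequence[r])
    for (j in seq_len(k)) {
      q <- vapply(chain[j:(j + 3L)], function(a) idx(r, a), 0L)
      if (!anyNA(q)) chiq[[length(chiq) + 1L]] <- q
    }
  }
  # omega quadruples CA(i-1)-C(i-1)-N(i)-CA(i)
  omq <- list()
  for (r in built) {
    if (!((r + 1L) %in% built) || r %in% model$breaks) next
    q <- c(idx(r, "CA"), idx(r, "C"), idx(r + 1L, "N"), idx(r + 1L, "CA"))
    if (!anyNA(q)) omq[[length(omq) + 1L]] <- q
  }
  # exclusions: graph distance <= 3 (1-2, 1-3 and 1-4 pairs), as in
  # standard force-field practice; proline's ring closure (CD bonded to N)
  # exists only in the exclusion graph, not as an energy term
  nb_ex <- nb
  for (r in built) {
    if (model$sequence[r] != "P") next
    iN <- idx(r, "N"); iCD <- idx(r, "CD")
    if (!is.na(iN) && !is.na(iCD)) {
      nb_ex[[iN]] <- c(nb_ex[[iN]], iCD)
      nb_ex[[iCD]] <- c(nb_ex[[iCD]], iN)
    }
  }
  excl <- list()
  for (i in seq_len(n_at)) {
    n1 <- nb_ex[[i]]
    n2 <- unique(unlist(nb_ex[n1]))
    n3 <- unique(unlist(nb_ex[n2]))
    reach <- setdiff(unique(c(n1, n2, n3)), i)
    reach <- reach[reach > i]
    if (length(reach)) excl[[length(excl) + 1L]] <- cbind(i, reach)
  }
  excl <- do.call(rbind, excl)
  excl_mat <- matrix(FALSE, n_at, n_at)
  excl_mat[excl] <- TRUE
  excl_mat[excl[, c(2L, 1L), drop = FALSE]] <- TRUE
  radii <- VDW_RADII[atom_element(at$atom)]
  thr_mat <- outer(radii, radii, `+`)
  chiM <- if (length(chiq)) do.call(rbind, chiq) else NULL
  omM <- if (length(omq)) do.call(rbind, omq) else NULL
  topo <- list(sig = sig, bonds = B, b0 = b0, angles = A, a0 = a0,
               chi = chiM, omega = omM, excl_mat = excl_mat, radii = radii,
               thr_mat = thr_mat)
  .paraloop_cache$topology <- topo
  topo
}

# dihedral angles (radians) for a matrix of atom-index quadruples
dihedrals_rad <- function(xyz, Q) {
  b1 <- xyz[Q[, 2L], , drop = FALSE] - xyz[Q[, 1L], , drop = FALSE]
  b2 <- xyz[Q[, 3L], , drop = FALSE] - xyz[Q[, 2L], , drop = FALSE]
  b3 <- xyz[Q[, 4L], , drop = FALSE] - xyz[Q[, 3L], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2n)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

# clashing pair list: atoms closer than rep_scale * (ri + rj), excluding
# bonded (1-2) and angle (1-3) pairs
repulsive_pairs <- function(xyz, topo, rep_scale) {
  if (nrow(xyz) < 2L) return(NULL)
  hit <- .clash_pairs(xyz, topo$thr_mat, rep_scale, topo$excl_mat)
  if (!nrow(hit)) return(NULL)
  hit
}

#' Total model energy under the reduced energy model
#'
#' @param model a [protein_model()].
#' @param energy an [energy_model()].
#' @param terms `"all"` (default) or `"differentiable"` (drops the
#'   hydrogen-bond term, which the gradient-based minimiser ignores).
#' @param breakdown return per-term values instead of the total?
#' @return Energy in kcal/mol (or a named list when `breakdown = TRUE`).
#' @export
model_energy <- function(model, energy = energy_model(), terms = "all",
                         breakdown = FALSE) {
  topo <- model_topology(model)
  xyz <- model_xyz(model)
  B <- topo$bonds
  dv <- xyz[B[, 1L], , drop = FALSE] - xyz[B[, 2L], , drop = FALSE]
  blen <- sqrt(rowSums(dv^2))
  e_bond <- energy$k_bond * sum((blen - topo$b0)^2)
  A <- topo$angles
  u <- xyz[A[, 1L], , drop = FALSE] - xyz[A[, 2L], , drop = FALSE]
  v <- xyz[A[, 3L], , drop = FALSE] - xyz[A[, 2L], , drop = FALSE]
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) / DEG
  e_angle <- energy$k_angle * sum(((ang - topo$a0) * DEG)^2)
  e_chi <- 0
  if (!is.null(topo$chi)) {
    chi <- dihedrals_rad(xyz, topo$chi)
    e_chi <- energy$k_chi * sum(1 + cos(3 * chi))
  }
  e_om <- 0
  if (!is.null(topo$omega)) {
    om <- dihedrals_rad(xyz, topo$omega)
    e_om <- energy$k_omega * sum(1 - cos(2 * (om - pi)))
  }
  rp <- repulsive_pairs(xyz, topo, energy$rep_scale)
  e_rep <- 0
  if (!is.null(rp)) {
    d <- sqrt(rowSums((xyz[rp[, 1L], , drop = FALSE] -
                       xyz[rp[, 2L], , drop = FALSE])^2))
    e_rep <- energy$k_rep * sum((rp[, 3L] - d)^2)
  }
  e_hb <- 0
  if (terms == "all" && energy$w_hbond != 0) {
    hb <- backbone_hbonds(model)
    if (nrow(hb)) e_hb <- energy$w_hbond * sum(capped_hbonds(hb)$energy)
  }
  if (breakdown) {
    return(list(bond = e_bond, angle = e_angle, chi = e_chi, omega = e_om,
                repulsion = e_rep, hbond = e_hb,
                total = e_bond + e_angle + e_chi + e_om + e_rep + e_hb))
  }
  e_bond + e_angle + e_chi + e_om + e_rep + e_hb
}

# analytic gradient of the differentiable terms (natoms x 3, kcal/mol/A)
model_energy_gradient <- function(model, energy = energy_model()) {
  topo <- model_topology(model)
  xyz <- model_xyz(model)
  g <- matrix(0, nrow(xyz), 3L)
  accumulate <- function(idx, contrib) {
    rs <- rowsum(contrib, idx)
    rows <- as.integer(rownames(rs))
    g[rows, ] <<- g[rows, ] + rs
  }
  B <- topo$bonds
  dv <- xyz[B[, 1L], , drop = FALSE] - xyz[B[, 2L], , drop = FALSE]
  blen <- sqrt(rowSums(dv^2))
  gb <- dv * (2 * energy$k_bond * (blen - topo$b0) / blen)
  accumulate(c(B[, 1L], B[, 2L]), rbind(gb, -gb))
  A <- topo$angles
  rij <- xyz[A[, 1L], , drop = FALSE] - xyz[A[, 2L], , drop = FALSE]
  rlj <- xyz[A[, 3L], , drop = FALSE] - xyz[A[, 2L], , drop = FALSE]
  nij <- sqrt(rowSums(rij^2))
  nlj <- sqrt(rowSums(rlj^2))
  cosv <- pmin(1 - 1e-10, pmax(-1 + 1e-10, rowSums(rij * rlj) / (nij * nlj)))
  dE <- 2 * energy$k_angle * (acos(cosv) - topo$a0 * DEG)
  sinv <- sqrt(1 - cosv^2)
  di <- (rlj / (nij * nlj) - rij * (cosv / nij^2)) / (-sinv)
  dl <- (rij / (nij * nlj) - rlj * (cosv / nlj^2)) / (-sinv)
  accumulate(c(A[, 1L], A[, 3L], A[, 2L]),
             rbind(dE * di, dE * dl, -dE * (di + dl)))
  dihedral_grads <- function(Q, dV) {
    # dV = dE/dphi (per radian). Our measured dihedral is the negative of
    # the convention these derivative formulas assume, hence the flip.
    dV <- -dV
    cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                               a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                               a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
    b1 <- xyz[Q[, 2L], , drop = FALSE] - xyz[Q[, 1L], , drop = FALSE]
    b2 <- xyz[Q[, 3L], , drop = FALSE] - xyz[Q[, 2L], , drop = FALSE]
    b3 <- xyz[Q[, 4L], , drop = FALSE] - xyz[Q[, 3L], , drop = FALSE]
    m <- cr(b1, b2)
    nn <- cr(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    dpi <- m * (-nb2 / rowSums(m * m))
    dpl <- nn * (nb2 / rowSums(nn * nn))
    s12 <- rowSums(b1 * b2) / nb2^2
    s32 <- rowSums(b3 * b2) / nb2^2
    dpj <- dpi * (-1 - s12) + dpl * s32
    dpk <- dpi * s12 + dpl * (-1 - s32)
    accumulate(c(Q[, 1L], Q[, 2L], Q[, 3L], Q[, 4L]),
               rbind(dV * dpi, dV * dpj, dV * dpk, dV * dpl))
  }
  if (!is.null(topo$chi)) {
    chi <- dihedrals_rad(xyz, topo$chi)
    dihedral_grads(topo$chi, -3 * energy$k_chi * sin(3 * chi))
  }
  if (!is.null(topo$omega)) {
    om <- dihedrals_rad(xyz, topo$omega)
    dihedral_grads(topo$omega, 2 * energy$k_omega * sin(2 * (om - pi)))
  }
  rp <- repulsive_pairs(xyz, topo, energy$rep_scale)
  if (!is.null(rp)) {
    dv <- xyz[rp[, 1L], , drop = FALSE] - xyz[rp[, 2L], , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    gr <- dv * (-2 * energy$k_rep * (rp[, 3L] - d) / d)
    accumulate(c(rp[, 1L], rp[, 2L]), rbind(gr, -gr))
  }
  g
}

# at most one bond per donor and two per acceptor (the physically
# realisable amide capacity); keeps the H-bond energy term bounded and
# prevents bifurcated-bond pile-ups from dominating minimisation
capped_hbonds <- function(hb) {
  if (!nrow(hb)) return(hb)
  hb <- hb[order(hb$energy), , drop = FALSE]
  hb <- hb[!duplicated(hb$donor), , drop = FALSE]
  acc_count <- table(hb$acceptor)
  keep <- logical(nrow(hb))
  seen <- integer(0)
  cnt <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(hb))) {
    key <- as.character(hb$acceptor[i])
    n <- cnt[[key]] %||% 0L
    if (n < 2L) { keep[i] <- TRUE; cnt[[key]] <- n + 1L }
  }
  hb[keep, , drop = FALSE]
}

#' Backbone hydrogen bonds by the Kabsch-Sander electrostatic formula
#'
#' Amide H positions are built geometrically from the previous carbonyl C,
#' N and CA (models carry no hydrogens). Donor-acceptor pairs separated by
#' at least 2 residues are scored; proline has no donor.
#'
#' @param model a [protein_model()].
#' @param threshold report bonds with energy below this (kcal/mol).
#' @return data.frame with columns `donor`, `acceptor`, `energy`.
#' @export
backbone_hbonds <- function(model, threshold = -0.5) {
  n <- n_residues(model)
  at <- model$atoms
  coord_of <- function(name) {
    m <- matrix(NA_real_, n, 3L)
    sel <- at$atom == name
    m[at$res[sel], ] <- as.matrix(at[sel, c("x", "y", "z")])
    m
  }
  Nm <- coord_of("N"); CAm <- coord_of("CA")
  Cm <- coord_of("C"); Om <- coord_of("O")
  Hm <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    if (model$sequence[i] == "P") next
    if (i == 1L || (i - 1L) %in% model$breaks) next
    if (anyNA(Nm[i, ]) || anyNA(CAm[i, ]) || anyNA(Cm[i - 1L, ])) next
    Nv <- Nm[i, ]
    Hm[i, ] <- Nv + unitv(unitv(Nv - Cm[i - 1L, ]) + unitv(Nv - CAm[i, ])) * 0.98
  }
  donors <- which(!is.na(Hm[, 1L]))
  acceptors <- which(!is.na(Cm[, 1L]) & !is.na(Om[, 1L]))
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric())
  if (!length(donors) || !length(acceptors)) return(empty)
  q1q2f <- 27.888  # 0.42 * 0.20 * 332 kcal*A/mol
  dm <- function(A, B) {  # pairwise distances, donors x acceptors
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 1e-12))
  }
  Nd <- Nm[donors, , drop = FALSE]
  Hd <- Hm[donors, , drop = FALSE]
  Ca <- Cm[acceptors, , drop = FALSE]
  Oa <- Om[acceptors, , drop = FALSE]
  dON <- dm(Nd, Oa)
  dOH <- dm(Hd, Oa)
  e <- q1q2f * (1 / dON + 1 / dm(Hd, Ca) - 1 / dOH - 1 / dm(Nd, Ca))
  sep <- abs(outer(donors, acceptors, `-`))
  # compressed approaches are steric clashes, not bonds: geometrically
  # impossible once real amide hydrogens are present
  ok <- e < threshold & sep >= 2L & dON >= 2.7 & dOH >= 1.8
  hit <- which(ok, arr.ind = TRUE, useNames = FALSE)
  if (!nrow(hit)) return(empty)
  hb <- data.frame(donor = donors[hit[, 1L]],
                   acceptor = acceptors[hit[, 2L]], energy = e[hit])
  hb <- hb[order(hb$donor, hb$acceptor), , drop = FALSE]
  rownames(hb) <- NULL
  hb
}
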