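# Comparative model construction: threading onto a template, secondary-
# structure-preserving refinement, and the steps 1-7 driver.

#' Thread a target sequence onto a template structure
#'
#' Conserved residues copy the template's atoms; mutated residues keep the
#' template backbone and get a default-rotamer side chain; insertions in the
#' target become unbuilt segments; deletions close the chain with a break
#' annotation pending loop closure.
#'
#' @param target a one-row [sequence_set()] (or an id present in `alignment`).
#' @param template a [protein_model()].
#' @param alignment a [multiple_alignment()] containing rows for the target
#'   (`target$id`) and the template (`template_id`).
#' @param template_id id of the template row (default: the other row).
#' @return A [protein_model()] over the target sequence, with `unbuilt`
#'   spans for insertions and `breaks` at deletion junctions.
#' @export
thread_onto_template <- function(target, template, alignment,
                                 template_id = NULL) {
  tid <- if (is.data.frame(target)) target$id[1L] else target
  ids <- alignment$seqs$id
  if (!tid %in% ids) stop("target row not in alignment: ", tid)
  if (is.null(template_id)) template_id <- setdiff(ids, tid)[1L]
  tmap <- alignment_to_residue_map(alignment, tid)
  pmap <- alignment_to_residue_map(alignment, template_id)
  trow <- strsplit(alignment$aligned[match(tid, ids)], "")[[1L]]
  prow <- strsplit(alignment$aligned[match(template_id, ids)], "")[[1L]]
  target_seq <- strsplit(gsub("-", "", paste(trow, collapse = "")), "")[[1L]]
  n <- length(target_seq)
  if (max(pmap, na.rm = TRUE) > n_residues(template)) {
    stop("alignment template row longer than template structure")
  }
  atoms <- list()
  unbuilt <- list()
  breaks <- integer()
  mutated <- integer()
  pending_insert <- NULL
  last_built <- 0L
  deletion_open <- FALSE
  for (col in seq_along(trow)) {
    ti <- tmap[col]
    pi <- pmap[col]
    if (is.na(ti)) { deletion_open <- TRUE; next }  # deletion vs template
    if (is.na(pi)) {                                 # insertion in target
      if (is.null(pending_insert)) pending_insert <- c(ti, ti)
      else pending_insert[2L] <- ti
      next
    }
    # aligned pair: copy template residue ti <- pi
    if (!is.null(pending_insert)) {
      unbuilt[[length(unbuilt) + 1L]] <- pending_insert
      pending_insert <- NULL
    }
    if (deletion_open && last_built > 0L) {
      breaks <- c(breaks, last_built)
      deletion_open <- FALSE
    }
    deletion_open <- FALSE
    ta <- template$atoms[template$atoms$res == pi, , drop = FALSE]
    if (!all(c("N", "CA", "C", "O") %in% ta$atom)) {
      stop("template backbone incomplete at residue ", pi)
    }
    same <- trow[col] == prow[col]
    keep <- if (same) ta else ta[ta$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
    keep$res <- ti
    keep$resname <- target_seq[ti]
    atoms[[length(atoms) + 1L]] <- keep
    if (!same) mutated <- c(mutated, ti)
    last_built <- ti
  }
  if (!is.null(pending_insert)) unbuilt[[length(unbuilt) + 1L]] <- pending_insert
  model <- protein_model(do.call(rbind, atoms), target_seq,
                         breaks = breaks, unbuilt = unbuilt)
  model <- reindex_atoms(model)
  for (i in mutated) model <- build_side_chain(model, i)
  # terminal insertions cannot be closed; interior ones are flagged, and the
  # residues stay unbuilt until loop modelling
  model
}

#' Secondary-structure-preserving backbone refinement
#'
#' Resamples backbone phi/psi residue-by-residue from a small candidate set
#' (the original conformation always included). A move that reduces the
#' count of the input hydrogen bonds is accepted only if its energy gain
#' exceeds `hbond_penalty`; the penalised energy
#' `E + hbond_penalty * (bonds lost)` is monotone non-increasing.
#'
#' @param model a [protein_model()].
#' @param ss an [assign_secondary_structure()] result computed on `model`.
#' @param hbond_penalty energy penalty per broken hydrogen bond (kcal/mol).
#' @param energy an [energy_model()].
#' @param deltas candidate phi/psi perturbations (degrees).
#' @return Refined model with attribute `penalised_trace`.
#' @export
refine_secondary_structure <- function(model, ss, hbond_penalty = 10,
                                       energy = energy_model(),
                                       deltas = c(-10, -5, 5, 10)) {
  hb0 <- nrow(ss$hbonds)
  count_kept <- function(m) {
    hb <- backbone_hbonds(m)
    if (!nrow(hb) || !hb0) return(0L)
    sum(paste(ss$hbonds$donor, ss$hbonds$acceptor) %in%
          paste(hb$donor, hb$acceptor))
  }
  # strain terms plus a penalty per lost input bond: refinement preserves
  # the hydrogen-bond network rather than chasing deeper bond energies
  pen_energy <- function(m) {
    model_energy(m, energy, terms = "differentiable") +
      hbond_penalty * (hb0 - count_kept(m))
  }
  e <- pen_energy(model)
  trace <- e
  built <- sort(unique(model$atoms$res))
  for (i in built) {
    for (type in c("phi", "psi")) {
      tor <- backbone_torsions(model)
      if (is.na(tor[[type]][i])) next
      for (d in deltas) {
        m2 <- rotate_torsion(model, i, type, d)
        e2 <- pen_energy(m2)
        if (e2 < e - 1e-9) { model <- m2; e <- e2; trace <- c(trace, e) }
      }
    }
  }
  attr(model, "penalised_trace") <- trace
  model
}

#' Build a comparative model (threading through Cartesian finish, iterated)
#'
#' Executes the full protocol: thread onto the template, torsion-space
#' minimisation, loop modelling of insertions/deletions, rotamer side-chain
#' placement, secondary-structure-preserving refinement, Cartesian steepest
#' descent; the cycle repeats until the relative total-energy improvement
#' falls below `tol` or `max_cycles` is reached.
#'
#' @param target one-row [sequence_set()].
#' @param template a [protein_model()].
#' @param alignment a [multiple_alignment()] with target and template rows.
#' @param config list of overrides: `n_samples`, `seed`, `closure_tol`,
#'   `max_cycles`, `tol` (relative energy improvement), `cartesian_steps`,
#'   `hbond_penalty`.
#' @param energy an [energy_model()].
#' @param library a rotamer library.
#' @return List with `model` (final [protein_model()]), `report`
#'   (a [quality_report()]), and `cycles` (per-cycle energies).
#' @export
build_comparative_model <- function(target, template, alignment,
                                    config = list(),
                                    energy = energy_model(),
                                    library = default_rotamer_library()) {
  cfg <- utils::modifyList(list(n_samples = 200L, seed = 1L,
                                closure_tol = 0.3, max_cycles = 10L,
                                tol = 1e-4, cartesian_steps = 500L,
                                hbond_penalty = 10), config)
  model <- thread_onto_template(target, template, alignment)
  spans <- model$unbuilt
  # deletions: remodel a short span bridging each annotated break
  for (b in model$breaks) {
    spans[[length(spans) + 1L]] <- c(max(b - 1L, 2L),
                                     min(b + 2L, n_residues(model) - 1L))
  }
  cycles <- numeric(0)
  e_prev <- Inf
  for (cycle in seq_len(cfg$max_cycles)) {
    # relieve side-chain clashes by rotamer placement before any backbone
    # move, so minimisation polishes rather than bends the threaded fold
    model <- place_side_chains(model, library, energy = energy)
    model <- minimize_torsion(model, energy, max_steps = 2L)
    for (sp in spans) {
      n <- n_residues(model)
      if (sp[1L] <= 1L || sp[2L] >= n) next  # terminal segment: left open
      model <- model_loop(model, c(sp[1L], sp[2L]), library = library,
                          energy = energy, n_samples = cfg$n_samples,
                          seed = cfg$seed + cycle, tol = cfg$closure_tol)
    }
    model <- place_side_chains(model, library, energy = energy)
    ss <- assign_secondary_structure(model)
    model <- refine_secondary_structure(model, ss,
                                        hbond_penalty = cfg$hbond_penalty,
                                        energy = energy)
    model <- minimize_cartesian(model, energy, steps = cfg$cartesian_steps)
    e_now <- model_energy(model, energy, terms = "differentiable")
    cycles <- c(cycles, e_now)
    if (is.finite(e_prev) &&
        (e_prev - e_now) < cfg$tol * max(abs(e_prev), 1)) break
    e_prev <- e_now
    spans <- model$unbuilt  # anything still unbuilt gets another chance
  }
  report <- quality_report(model, template = template, energy = energy,
                           library = library)
  list(model = model, report = report, cycles = cycles)
}
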