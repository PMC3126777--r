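#' Torsion-space energy minimisation
#'
#' Cyclic coordinate descent over the rotatable torsions (phi/psi/chi; omega
#' and proline chi stay fixed): each torsion in turn is scanned coarsely over
#' the full circle and then refined by golden-section search, accepting only
#' energy decreases. Bond lengths and angles are untouched (torsion-space
#' guarantee). Terminates when the energy decrease per sweep falls below
#' `tol` or after `max_steps` sweeps.
#'
#' @param model a [protein_model()].
#' @param energy an [energy_model()].
#' @param max_steps maximum sweeps over all torsions.
#' @param tol absolute energy-decrease tolerance per sweep (kcal/mol).
#' @param span optional `c(start, end)` residue span to restrict the moving
#'   torsions.
#' @param coarse number of coarse scan points over the circle.
#' @return The minimised model, with attribute `energy_trace` (energy after
#'   each sweep, starting value first).
#' @export
minimize_torsion <- function(model, energy = energy_model(), max_steps = 5L,
                             tol = 0.01, span = NULL, coarse = 12L) {
  e0 <- model_energy(model, energy, terms = "all")
  if (!is.finite(e0)) stop("non-finite starting energy")
  tors <- rotatable_torsions(model, span)
  # chi torsions first: side-chain relief should not be bought with
  # backbone motion
  tors <- tors[order(vapply(tors, function(t) t$type != "chi", TRUE))]
  trace <- e0
  if (!length(tors)) {
    attr(model, "energy_trace") <- trace
    return(model)
  }
  for (sweep in seq_len(max_steps)) {
    e_start <- trace[length(trace)]
    for (tt in tors) {
      cur_e <- model_energy(model, energy, terms = "all")
      eval_delta <- function(d) {
        m2 <- rotate_torsion(model, tt$res, tt$type, d, tt$chi_index)
        model_energy(m2, energy, terms = "all")
      }
      deltas <- seq(0, 360 - 360 / coarse, by = 360 / coarse)
      es <- vapply(deltas, eval_delta, 0)
      best <- which.min(es)
      # converged torsion: zero rotation already optimal on the coarse grid
      if (best == 1L && es[1L] >= cur_e - 1e-10 &&
          min(es) >= cur_e - tol / 10) next
      centre <- deltas[best]
      lo <- centre - 360 / coarse
      hi <- centre + 360 / coarse
      gr <- (sqrt(5) - 1) / 2
      a <- lo; b <- hi
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- eval_delta(x1); f2 <- eval_delta(x2)
      for (it in 1:10) {
        if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a); f1 <- eval_delta(x1)
        } else { a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a); f2 <- eval_delta(x2) }
      }
      dbest <- if (f1 < f2) x1 else x2
      ebest <- min(f1, f2)
      if (ebest < cur_e - 1e-10) {
        model <- rotate_torsion(model, tt$res, tt$type, dbest, tt$chi_index)
      }
    }
    e_now <- model_energy(model, energy, terms = "all")
    trace <- c(trace, e_now)
    if (e_start - e_now < tol) break
  }
  attr(model, "energy_trace") <- trace
  model
}

#' Cartesian steepest-descent minimisation
#'
#' Steepest descent with backtracking step control on the differentiable
#' energy terms. The energy is non-increasing by construction; iteration
#' stops at `steps`, when the gradient norm vanishes, or when no downhill
#' step can be found.
#'
#' @param model a [protein_model()].
#' @param energy an [energy_model()].
#' @param steps maximum descent steps (default 500).
#' @param grad_tol gradient-norm convergence threshold (kcal/mol/A).
#' @return Minimised model with attribute `energy_trace` (one entry per
#'   accepted step, starting value first).
#' @export
minimize_cartesian <- function(model, energy = energy_model(), steps = 500L,
                               grad_tol = 1e-4) {
  e <- model_energy(model, energy, terms = "differentiable")
  if (!is.finite(e)) stop("non-finite starting energy")
  trace <- e
  alpha <- 0.01
  for (s in seq_len(steps)) {
    g <- model_energy_gradient(model, energy)
    if (!all(is.finite(g))) stop("non-finite gradient")
    gn <- sqrt(sum(g^2))
    if (gn < grad_tol) break
    dir <- -g / gn
    xyz <- model_xyz(model)
    accepted <- FALSE
    a <- alpha
    for (h in 1:20) {
      m2 <- set_model_xyz(model, xyz + a * dir)
      e2 <- model_energy(m2, energy, terms = "differentiable")
      if (is.finite(e2) && e2 < e) {
        model <- m2; e <- e2; accepted <- TRUE
        alpha <- a * 1.2
        break
      }
      a <- a / 2
    }
    if (!accepted) break
    trace <- c(trace, e)
  }
  attr(model, "energy_trace") <- trace
  model
}
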