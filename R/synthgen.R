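# Deterministic generators for every pipeline input: ortholog/paralog
# sequence families with an implanted divergent window, toy structures with
# known torsion geometry, and expression panels with specified correlation.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

mutate_residues <- function(chars, rate) {
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_CODES, chars[i]), 1L)
  }
  chars
}

#' Generate an ortholog/paralog family with an implanted divergent window
#'
#' The ancestor carries `window_seq` at `window_start`. In-group rows keep
#' the window fixed and mutate elsewhere at `background_rate`; out-group and
#' contrast-paralog rows mutate at `background_rate` outside the window and
#' at `window_divergence` inside it. All sequences stay equal length (no
#' indels), so the family is returned both as a [sequence_set()] and as a
#' ready-made gap-free [multiple_alignment()].
#'
#' @param n_ingroup,n_outgroup,n_paralog row counts (`n_paralog` per
#'   contrast paralog).
#' @param length sequence length.
#' @param window_start 1-based start of the implanted window.
#' @param window_seq in-group window sequence (default the 12-residue
#'   proline/arginine-rich site).
#' @param background_rate per-site substitution probability outside the
#'   window.
#' @param window_divergence per-site substitution probability inside the
#'   window for contrast rows.
#' @param target_paralog,in_group,out_group,contrast_paralogs labels.
#' @param seed RNG seed (generation is bit-reproducible per seed).
#' @return List with `seqs` ([sequence_set()]), `alignment`
#'   ([multiple_alignment()]), `truth` (`list(start, end, sequence)`).
#' @export
generate_protein_family <- function(n_ingroup = 8L, n_outgroup = 4L,
                                    n_paralog = 2L, length = 300L,
                                    window_start = 249L,
                                    window_seq = "FPPRGPRPVQSV",
                                    background_rate = 0.05,
                                    window_divergence = 0.9,
                                    target_paralog = "CDK4",
                                    in_group = "mammal",
                                    out_group = "nonmammal",
                                    contrast_paralogs = c("CDK6", "CDK2"),
                                    seed = 1L) {
  wlen <- nchar(window_seq)
  wend <- window_start + wlen - 1L
  if (window_start < 1L || wend > length) {
    stop("implanted window lies outside the sequence bounds")
  }
  stopifnot(background_rate >= 0, background_rate <= 1,
            window_divergence >= 0, window_divergence <= 1)
  with_seed(seed, {
    anc <- sample(AA_CODES, length, replace = TRUE)
    anc[window_start:wend] <- strsplit(window_seq, "")[[1L]]
    win <- window_start:wend
    outside <- setdiff(seq_len(length), win)
    make_row <- function(divergent) {
      s <- anc
      s[outside] <- mutate_residues(s[outside], background_rate)
      if (divergent) s[win] <- mutate_residues(s[win], window_divergence)
      paste(s, collapse = "")
    }
    ids <- character(0); res <- character(0)
    paralog <- character(0); group <- character(0)
    for (i in seq_len(n_ingroup)) {
      ids <- c(ids, sprintf("%s_%s_%02d", target_paralog, in_group, i))
      res <- c(res, make_row(FALSE))
      paralog <- c(paralog, target_paralog); group <- c(group, in_group)
    }
    for (i in seq_len(n_outgroup)) {
      ids <- c(ids, sprintf("%s_%s_%02d", target_paralog, out_group, i))
      res <- c(res, make_row(TRUE))
      paralog <- c(paralog, target_paralog); group <- c(group, out_group)
    }
    for (pl in contrast_paralogs) {
      for (i in seq_len(n_paralog)) {
        ids <- c(ids, sprintf("%s_%s_%02d", pl, in_group, i))
        res <- c(res, make_row(TRUE))
        paralog <- c(paralog, pl); group <- c(group, in_group)
      }
    }
    ss <- sequence_set(ids, res, paralog, group)
    list(seqs = ss, alignment = multiple_alignment(ss, ss$residues),
         truth = list(start = window_start, end = wend,
                      sequence = window_seq))
  })
}

#' Generate a toy protein structure with known torsion geometry
#'
#' Kinds: `"ideal_helix"` (phi -57, psi -47), `"ideal_strand"`
#' (phi -140, psi 135), `"helix_with_loop"` (helix with an embedded coil
#' segment of jittered extended torsions), and `"two_domain"` (two helices
#' as separate chain segments, antiparallel-packed at `separation`
#' Angstroms, with an annotated chain break).
#'
#' @param kind structure kind.
#' @param length residues per segment (total 2x for `two_domain`).
#' @param sequence optional one-letter sequence (default poly-Ala; recycled).
#' @param loop_span `c(start, end)` coil span for `helix_with_loop`.
#' @param jitter half-width of uniform torsion jitter, degrees.
#' @param separation helix-axis separation for `two_domain` (Angstroms).
#' @param burial_sequence for `two_domain`: assign hydrophobic residues to
#'   the packed interface and polar residues elsewhere (used to train the
#'   packaged statistical potential).
#' @param seed RNG seed.
#' @return A [protein_model()].
#' @export
generate_toy_structure <- function(kind = c("ideal_helix", "ideal_strand",
                                            "helix_with_loop", "two_domain"),
                                   length = 16L, sequence = NULL,
                                   loop_span = NULL, jitter = 0,
                                   separation = 9.5,
                                   burial_sequence = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(length)
  seq_of <- function(n) {
    if (is.null(sequence)) rep("A", n)
    else rep_len(strsplit(paste(sequence, collapse = ""), "")[[1L]], n)
  }
  with_seed(seed, {
    jit <- function(k) if (jitter > 0) runif(k, -jitter, jitter) else numeric(k)
    if (kind == "ideal_helix" || kind == "ideal_strand") {
      phi0 <- if (kind == "ideal_helix") -57 else -140
      psi0 <- if (kind == "ideal_helix") -47 else 135
      return(build_backbone(seq_of(n), phi = phi0 + jit(n),
                            psi = psi0 + jit(n)))
    }
    if (kind == "helix_with_loop") {
      if (is.null(loop_span)) {
        loop_span <- c(n %/% 2L - 2L, n %/% 2L + 3L)
      }
      phi <- rep(-57, n); psi <- rep(-47, n)
      span <- loop_span[1L]:loop_span[2L]
      phi[span] <- runif(base::length(span), -150, -60)
      psi[span] <- runif(base::length(span), 110, 170)
      m <- build_backbone(seq_of(n), phi = phi + jit(n), psi = psi + jit(n))
      attr(m, "loop_span") <- loop_span
      return(m)
    }
    # two_domain: two antiparallel helices with a chain break
    h1 <- build_backbone(seq_of(n), phi = rep(-57, n) + jit(n),
                         psi = rep(-47, n) + jit(n))
    h2 <- build_backbone(seq_of(n), phi = rep(-57, n) + jit(n),
                         psi = rep(-47, n) + jit(n))
    axis_of <- function(m) {
      ca <- do.call(rbind, lapply(seq_len(n), function(i) atom_coord(m, i, "CA")))
      pc <- stats::prcomp(ca)
      list(centre = colMeans(ca), axis = pc$rotation[, 1L])
    }
    a1 <- axis_of(h1)
    a2 <- axis_of(h2)
    # rotate helix 2 so its axis is antiparallel to helix 1
    v <- a2$axis; w <- -a1$axis
    cr <- vcross(v, w)
    if (vnorm(cr) < 1e-8) {
      R <- if (sum(v * w) > 0) diag(3) else -diag(3)
    } else {
      angle <- acos(pmin(1, pmax(-1, sum(v * w)))) / DEG
      R <- rotation_about_axis(cr, angle)
    }
    perp <- vcross(a1$axis, c(0, 0, 1))
    if (vnorm(perp) < 1e-6) perp <- vcross(a1$axis, c(0, 1, 0))
    perp <- unitv(perp)
    x2 <- model_xyz(h2)
    x2 <- sweep(x2, 2L, a2$centre)
    x2 <- x2 %*% t(R)
    x2 <- sweep(x2, 2L, a1$centre + separation * perp, `+`)
    h2 <- set_model_xyz(h2, x2)
    at2 <- h2$atoms
    at2$res <- at2$res + n
    model <- protein_model(rbind(h1$atoms, at2),
                           c(h1$sequence, h2$sequence), breaks = n)
    if (burial_sequence) {
      ca <- do.call(rbind, lapply(seq_len(2L * n),
                                  function(i) atom_coord(model, i, "CA")))
      newseq <- vapply(seq_len(2L * n), function(i) {
        other <- if (i <= n) (n + 1L):(2L * n) else seq_len(n)
        dmin <- min(sqrt(rowSums(sweep(ca[other, , drop = FALSE], 2L, ca[i, ])^2)))
        if (dmin < 8) sample(HYDROPHOBIC, 1L)
        else sample(setdiff(AA_CODES, HYDROPHOBIC), 1L)
      }, "")
      model$sequence <- newseq
      model$atoms$resname <- newseq[model$atoms$res]
      for (i in seq_len(2L * n)) model <- build_side_chain(model, i)
    }
    model
  })
}

#' Generate a synthetic expression panel with specified anchor correlations
#'
#' Anchor abundances are log-normal; each partner is `anchor + noise`, the
#' noise standard deviation solved so the expected Pearson correlation with
#' the anchor equals its target (`r = 0` partners are independent
#' log-normal draws, `r = 1` partners reproduce the anchor exactly).
#' Abundances are floored at a small positive value.
#'
#' @param n_lines number of cell lines (default 16).
#' @param anchor anchor protein name.
#' @param r named vector of target correlations for the partners.
#' @param seed RNG seed.
#' @return Object of class `expression_panel`: data.frame with `cell_line`
#'   plus one numeric column per protein.
#' @export
generate_expression_panel <- function(n_lines = 16L, anchor = "CDK1",
                                      r = c(CDK4 = 0.9, CDK6 = 0, CDK2 = 0),
                                      seed = 1L) {
  if (any(abs(r) > 1)) stop("target correlations must lie in [-1, 1]")
  if (n_lines < 3L) stop("need at least 3 cell lines")
  with_seed(seed, {
    a <- stats::rlnorm(n_lines, meanlog = log(5), sdlog = 0.5)
    out <- data.frame(cell_line = sprintf("LINE%02d", seq_len(n_lines)))
    out[[anchor]] <- a
    for (p in names(r)) {
      rt <- r[[p]]
      if (rt == 0) {
        out[[p]] <- stats::rlnorm(n_lines, meanlog = log(5), sdlog = 0.5)
      } else {
        sd_e <- stats::sd(a) * sqrt(1 / rt^2 - 1)
        v <- sign(rt) * a + stats::rnorm(n_lines, 0, sd_e)
        v <- v - min(v, 0) + 0.01 * (min(v) <= 0)
        out[[p]] <- v
      }
    }
    class(out) <- c("expression_panel", "data.frame")
    out
  })
}
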