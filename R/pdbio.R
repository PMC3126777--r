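# PDB reading and writing, backed by bio3d.

AA_ONE <- setNames(names(AA_THREE), AA_THREE)

#' Write a model to a PDB file
#'
#' ATOM/TER/END records; occupancy and B-factor are written as 1.00/0.00.
#'
#' @param model a [protein_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$res,
                   resid = AA_THREE[at$resname],
                   elety = at$atom,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read a protein model from a PDB file
#'
#' Reads ATOM records (first chain model), keeping the atoms this package's
#' reduced representation knows about. Chain breaks are annotated where the
#' C-N distance between consecutive residues exceeds 1.8 Angstroms.
#'
#' @param path PDB file.
#' @return A [protein_model()].
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  res_ids <- unique(at$resno)
  remap <- setNames(seq_along(res_ids), res_ids)
  one <- AA_ONE[at$resid]
  one[is.na(one)] <- "X"
  keep_names <- unique(c("N", "CA", "C", "O", unlist(SIDE_CHAINS)))
  keep <- at$elety %in% keep_names
  atoms <- data.frame(res = as.integer(remap[as.character(at$resno[keep])]),
                      resname = one[keep],
                      atom = at$elety[keep],
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      stringsAsFactors = FALSE)
  sequence <- vapply(seq_along(res_ids), function(i) {
    one[at$resno == res_ids[i]][1L]
  }, "")
  model <- protein_model(atoms, sequence)
  model <- reindex_atoms(model)
  # annotate breaks from geometry
  brks <- integer()
  for (i in seq_len(length(res_ids) - 1L)) {
    c1 <- atom_coord(model, i, "C")
    n2 <- atom_coord(model, i + 1L, "N")
    if (is.null(c1) || is.null(n2) || vnorm(c1 - n2) > 1.8) {
      brks <- c(brks, i)
    }
  }
  model$breaks <- brks
  model
}
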