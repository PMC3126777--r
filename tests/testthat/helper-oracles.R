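# Shared oracle implementations, deliberately independent of the package's
# own code paths.

# brute-force global alignment score with affine gaps (gap run of length L
# costs open + ext * L), small sequences only
nw_affine_score <- function(a, b, S, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force per-window divergence scan on a character matrix
brute_scan_score <- function(mat, in_rows, window_len) {
  nc <- ncol(mat)
  contrast <- setdiff(seq_len(nrow(mat)), in_rows)
  col_in <- sapply(seq_len(nc), function(j) {
    col <- mat[in_rows, j]
    pairs <- combn(length(col), 2)
    vals <- apply(pairs, 2, function(p) {
      x <- col[p[1]]; y <- col[p[2]]
      if (x == "-" && y == "-") return(NA)
      as.numeric(x == y && x != "-")
    })
    if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
  })
  cons <- sapply(seq_len(nc), function(j) {
    col <- mat[in_rows, j]
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tt <- table(col)
    sort(names(tt)[tt == max(tt)])[1]
  })
  col_cross <- sapply(seq_len(nc), function(j) {
    mean(mat[contrast, j] == cons[j] & mat[contrast, j] != "-" & cons[j] != "-")
  })
  d <- col_in - col_cross
  sapply(seq_len(nc - window_len + 1),
         function(s) mean(d[s:(s + window_len - 1)]))
}

# rigid-body transform of a model's coordinates
rigid_transform <- function(model, axis = c(1, 2, 3), theta = 63,
                            shift = c(7, -4, 11)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  u <- axis / sqrt(sum(axis^2))
  t <- theta * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(t) * K + (1 - cos(t)) * K %*% K
  xyz <- sweep(xyz %*% t(R), 2, shift, `+`)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

make_labelled_fasta <- function(path, ids, seqs) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
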