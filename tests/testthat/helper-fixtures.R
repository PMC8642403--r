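# Shared fixtures built in code. pdb_line() writes one fixed-column ATOM
# record for hand-crafted geometry tests.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resno, x, y, z, element)
}

# A minimal complex from a coordinate table (one atom per row).
complex_from_table <- function(df, source_id = "fixture") {
  df$serial <- seq_len(nrow(df))
  if (is.null(df$insert)) df$insert <- ""
  if (is.null(df$resname)) df$resname <- "ALA"
  if (is.null(df$name)) df$name <- "CA"
  if (is.null(df$element)) df$element <- "C"
  make_complex(df, source_id = source_id)
}

# Two single-atom chains separated by `dist` along x.
two_atom_complex <- function(dist) {
  complex_from_table(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L),
    x = c(0, dist), y = 0, z = 0))
}

ff_table <- read_forcefield()

# Brute-force superposition oracle: minimum RMSD over many random
# rotations with the optimal translation applied analytically
# (centering). Bounds the Kabsch result from above.
brute_min_rmsd <- function(P, Q, n_rot = 1e5, seed = 99) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)            # sum p q^T
  C <- sum(Pc^2) + sum(Qc^2)
  q <- ppirank:::with_seed(seed, matrix(stats::rnorm(4 * n_rot), ncol = 4))
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  R <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  tM <- as.vector(t(M))             # row-major M^T matches R's entry order
  cost <- C - 2 * (R %*% tM)
  sqrt(max(min(cost), 0) / nrow(P))
}

# Brute-force O(n^2) interface oracle used against the implementation.
brute_interface <- function(complex, cutoff) {
  at <- complex$atoms
  ia <- which(at$chain == complex$chain_ids[1])
  ib <- which(at$chain == complex$chain_ids[2])
  pairs <- list()
  for (i in ia) for (j in ib) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
              (at$z[i] - at$z[j])^2)
    if (d <= cutoff) pairs[[length(pairs) + 1]] <- c(i, j)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2)
  uid <- paste0(at$resno, at$insert)
  list(pairs = pairs,
       res_a = sort(unique(uid[pairs[, 1]])),
       res_b = sort(unique(uid[pairs[, 2]])))
}
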