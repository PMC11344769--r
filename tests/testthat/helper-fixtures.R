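# In-code fixtures shared across the suite: a literal handwritten PDB with
# altlocs, an insertion code and an MSE residue, plus small builders.

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1.00, b = 10.00, alt = " ", ins = " ",
                          type = "ATOM") {
  elesy <- substr(trimws(name), 1, 1)
  sprintf("%-6s%5d  %-3s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resid, chain, resno, ins,
          x, y, z, occ, b, elesy)
}

# 3 residues (ALA, GLY, MSE), one CA with two altlocs, one insertion code,
# plus a HOH HETATM that must be dropped
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.000, 0.000, 0.000, b = 10),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000,
                  occ = 0.60, b = 20, alt = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 1.500, 0.100, 0.000,
                  occ = 0.40, b = 21, alt = "B"),
    pdb_atom_line(4, "C",  "ALA", "A", 1, 2.009, 1.420, 0.000, b = 12),
    pdb_atom_line(5, "O",  "ALA", "A", 1, 1.251, 2.390, 0.000, b = 13),
    pdb_atom_line(6, "N",  "GLY", "A", 2, 3.332, 1.536, 0.000, b = 14),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 4.120, 2.750, 0.100, b = 30),
    pdb_atom_line(8, "C",  "GLY", "A", 2, 5.600, 2.500, 0.200, b = 15),
    pdb_atom_line(9, "O",  "GLY", "A", 2, 6.100, 1.400, 0.100, b = 16),
    pdb_atom_line(10, "N",  "MSE", "A", 2, 6.400, 3.600, 0.300, ins = "A",
                  type = "HETATM"),
    pdb_atom_line(11, "CA", "MSE", "A", 2, 7.800, 3.500, 0.400, ins = "A",
                  b = 40, type = "HETATM"),
    pdb_atom_line(12, "C",  "MSE", "A", 2, 8.500, 4.800, 0.500, ins = "A",
                  type = "HETATM"),
    pdb_atom_line(13, "O",  "MSE", "A", 2, 8.000, 5.900, 0.400, ins = "A",
                  type = "HETATM"),
    pdb_atom_line(14, "SE", "MSE", "A", 2, 9.000, 3.000, 2.000, ins = "A",
                  type = "HETATM"),
    pdb_atom_line(15, "O",  "HOH", "A", 100, 20.0, 20.0, 20.0,
                  type = "HETATM"),
    "END")
  writeLines(lines, path)
  path
}

# fs_structure holding only CA atoms at the given coordinates
ca_structure <- function(coords, id = "ca_toy", bf = 0) {
  n <- nrow(coords)
  atoms <- data.frame(res_index = seq_len(n), resno = seq_len(n), ins = "",
                      resid = "ALA", elety = "CA", elesy = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      b = rep_len(bf, n), o = 1, stringsAsFactors = FALSE)
  residues <- data.frame(res_index = seq_len(n), resno = seq_len(n),
                         ins = "", author = as.character(seq_len(n)),
                         resid = "ALA", aa1 = "A", stringsAsFactors = FALSE)
  structure(list(id = id, chain_id = "A", source_format = "SYNTH",
                 atoms = atoms, residues = residues,
                 sequence = strrep("A", n)),
            class = "fs_structure")
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rigid_move <- function(model, R, t) {
  X <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, t, "+")
  model$atoms$x <- X[, 1]; model$atoms$y <- X[, 2]; model$atoms$z <- X[, 3]
  model
}

# independent superposition oracle: coarse Euler-angle grid search followed
# by a Nelder-Mead polish on the best grid cell (no SVD involved)
grid_rmsd_oracle <- function(P, Q, step = 12) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    ca <- cos(a); sa <- sin(a)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(a) sqrt(mean(rowSums((Pc - Qc %*% t(rot(a)))^2)))
  grid <- seq(0, 2 * pi, by = step * pi / 180)
  gridb <- seq(0, pi, by = step * pi / 180)
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a1 in grid) for (a2 in gridb) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))$value
}
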