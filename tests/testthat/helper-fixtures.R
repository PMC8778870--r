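# Test helpers: a tiny PDB text writer (independent of the package's
# fixture writer) and brute-force oracles for the profile math.

# one PDB ATOM line; atom names placed in columns 13-16
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = " ", elem = substr(name, 1, 1),
                          record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, x, y, z, occ, b, elem)
}

write_tiny_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# an alanine residue: 5 heavy atoms around a centre
ala_lines <- function(chain = "A", resno = 1, cx = 0, cy = 0, cz = 0,
                      serial0 = 0) {
  nm <- c("N", "CA", "C", "O", "CB")
  dx <- c(-1.2, 0, 1.2, 2.0, -0.5); dy <- c(0.5, 0, 0.3, -0.6, 1.4)
  dz <- c(0, 0, 0.8, 1.0, -0.9)
  vapply(seq_along(nm), function(i)
    pdb_atom_line(serial0 + i, nm[i], "ALA", chain, resno,
                  cx + dx[i], cy + dy[i], cz + dz[i]),
    character(1))
}

# brute-force observed profile: explicit double loop over residue pairs
brute_o <- function(xyz, h, cutoff = 9, pair = "sum") {
  n <- nrow(xyz)
  raw <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r >= cutoff) next
    u2 <- (r / cutoff)^2
    k <- 1 - 0.5 * (7 * u2 - 9 * u2^2 + 5 * u2^3 - u2^4)
    raw[i] <- raw[i] + switch(pair,
                              sum = h[i] + h[j],
                              product = h[i] * h[j],
                              partner = h[j]) * k
  }
  raw / sum(raw)
}

# hand D_KL in bits, no epsilon tricks (for strictly positive q)
hand_dkl <- function(p, q) sum(ifelse(p > 0, p * log2(p / q), 0))

# random point on the rotation group (seeded by caller)
random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_simplex <- function(n) {
  x <- -log(runif(n))
  x / sum(x)
}

# shared small structure for metric tests
micelle_es <- function(seed = 1, n = 60)
  generate_structure(synthetic_spec(n, "two_layer_micelle", seed = seed))
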