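test_that("a single-residue file yields one residue with its heavy atoms", {
  path <- write_tiny_pdb(ala_lines())
  res <- read_structure(path)
  expect_s3_class(res, "fod_atoms")
  expect_equal(nrow(res), 5)
  expect_equal(unique(res$resno), 1)
  expect_equal(unique(res$aa), "A")
})

test_that("chains and residue identities survive parsing", {
  lines <- c(ala_lines("A", 1, 0, 0, 0, 0),
             ala_lines("A", 2, 4, 0, 0, 5),
             ala_lines("A", 3, 8, 0, 0, 10),
             ala_lines("B", 1, 0, 6, 0, 15),
             ala_lines("B", 2, 4, 6, 0, 20),
             ala_lines("B", 3, 8, 6, 0, 25))
  res <- read_structure(write_tiny_pdb(lines))
  es <- effective_atoms(res)
  expect_equal(nrow(es), 6)
  expect_equal(es$chain, rep(c("A", "B"), each = 3))
  expect_equal(es$resno, rep(1:3, 2))
})

test_that("multi-model files return only the requested model", {
  models <- unlist(lapply(1:10, function(m) {
    c(sprintf("MODEL     %4d", m),
      ala_lines("A", 1, cx = m * 10),      # coordinates differ per model
      ala_lines("A", 2, cx = m * 10 + 4, serial0 = 5),
      "ENDMDL")
  }))
  path <- write_tiny_pdb(models)
  r1 <- read_structure(path, model = 1)
  r3 <- read_structure(path, model = 3)
  expect_equal(nrow(r1), 10)               # atoms of one model only
  expect_equal(mean(r1$x[1:5]), 10 + mean(c(-1.2, 0, 1.2, 2.0, -0.5)))
  expect_equal(r3$x - r1$x, rep(20, 10))
  expect_error(read_structure(path, model = 11), class = "fodm_range_error")
})

test_that("waters, hetero groups and hydrogens are excluded; MSE is mapped", {
  lines <- c(ala_lines("A", 1),
             pdb_atom_line(90, "H", "ALA", "A", 1, 0, 0, 1, elem = "H"),
             pdb_atom_line(91, "O", "HOH", "A", 101, 9, 9, 9,
                           record = "HETATM"),
             pdb_atom_line(92, "C1", "LDA", "A", 102, 5, 5, 5,
                           record = "HETATM"),
             pdb_atom_line(93, "CA", "MSE", "A", 2, 4, 0, 0,
                           record = "HETATM"),
             pdb_atom_line(94, "SE", "MSE", "A", 2, 5, 1, 0, elem = "SE",
                           record = "HETATM"))
  res <- read_structure(write_tiny_pdb(lines))
  expect_equal(sort(unique(res$resid)), c("ALA", "MET"))
  expect_equal(nrow(res), 7)               # 5 ALA heavy + 2 MSE heavy
  expect_false(any(res$elety == "H"))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
                           alt = "A"),
             pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6,
                           alt = "B"),
             # tie: altloc letter order wins
             pdb_atom_line(3, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.5,
                           alt = "A"),
             pdb_atom_line(4, "CB", "ALA", "A", 1, 8, 8, 8, occ = 0.5,
                           alt = "B"))
  res <- read_structure(write_tiny_pdb(lines))
  expect_equal(nrow(res), 2)
  expect_equal(res$x[res$elety == "CA"], 9)   # occupancy 0.6 conformer
  expect_equal(res$x[res$elety == "CB"], 1)   # tie -> altloc "A"
})

test_that("effective atoms are per-residue centroids, order preserved", {
  at <- data.frame(chain = "A", resno = c(1, 1), aa = "A",
                   x = c(0, 2), y = c(0, 0), z = c(0, 0))
  expect_equal(unlist(effective_atoms(at)[1, c("x", "y", "z")],
                      use.names = FALSE), c(1, 0, 0))
  at1 <- data.frame(chain = "A", resno = 1, aa = "G",
                    x = 1, y = 2, z = 3)
  expect_equal(unlist(effective_atoms(at1)[1, c("x", "y", "z")],
                      use.names = FALSE), c(1, 2, 3))
  simplex <- data.frame(chain = "A", resno = 1, aa = "G",
                        x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  expect_equal(unlist(effective_atoms(simplex)[1, c("x", "y", "z")],
                      use.names = FALSE), rep(1 / 3, 3))
  expect_error(effective_atoms(data.frame()), class = "fodm_value_error")
})

test_that("effective atoms are invariant to atom order within a residue", {
  set.seed(4)
  at <- data.frame(chain = "A", resno = rep(1:5, each = 4), aa = "L",
                   x = rnorm(20), y = rnorm(20), z = rnorm(20))
  perm <- at[order(rep(1:5, each = 4), sample(20)), ]
  expect_equal(effective_atoms(at)[, c("x", "y", "z")],
               effective_atoms(perm)[, c("x", "y", "z")])
})

test_that("selection strings parse and resolve at all granularities", {
  expect_equal(parse_selection("A:18-116,B")$chain, c("A", "B"))
  expect_equal(parse_selection("A:18-116")$end, 116)
  expect_error(parse_selection("A:116-18"), class = "fodm_parse_error")
  expect_error(selection("bad", "A:1-5,A:3-8", mode = "chain"),
               class = "fodm_selection_error")

  lines <- unlist(lapply(c("A", "B"), function(ch)
    lapply(1:4, function(i) ala_lines(ch, i, i * 4, (ch == "B") * 20, 0,
                                      serial0 = i * 5))))
  es <- effective_atoms(read_structure(write_tiny_pdb(lines)))

  chainA <- resolve_selection(es, selection("chain A", "A", mode = "chain"))
  expect_equal(unique(chainA$chain), "A")
  expect_equal(nrow(chainA), 4)

  two <- resolve_selection(es, selection("two ranges", "A:1-2,A:4-4",
                                         mode = "domain_set"))
  expect_equal(two$resno, c(1, 2, 4))

  # identity: full selection returns the whole structure
  full <- resolve_selection(es, selection("all", "A,B", mode = "complex"))
  expect_equal(full[, c("chain", "resno", "x")], es[, c("chain", "resno", "x")])

  expect_error(resolve_selection(es, selection("z", "Z", mode = "chain")),
               class = "fodm_selection_error")
  expect_error(resolve_selection(es, selection("gap", "A:1-9", mode = "chain")),
               class = "fodm_selection_error")
  expect_warning(
    lenient <- resolve_selection(es, selection("gap", "A:1-9", mode = "chain"),
                                 lenient = TRUE),
    class = "fodm_warning")
  expect_equal(nrow(lenient), 4)
})
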