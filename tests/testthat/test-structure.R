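test_that("PDB write/parse round trip preserves the complex", {
  d <- make_toy_dimer(5, seed = 1)
  d2 <- parse_pdb(write_pdb(d))
  expect_equal(nrow(d2$atoms), nrow(d$atoms))
  expect_equal(coords(d2), coords(d), tolerance = 1e-9)
  expect_equal(d2$atoms$name, d$atoms$name)
  expect_equal(d2$atoms$resname, d$atoms$resname)
  expect_equal(d2$atoms$chain, d$atoms$chain)
})

test_that("toy dimer has the constructed bookkeeping", {
  d <- make_toy_dimer(5, seed = 3)
  expect_equal(length(d$chain_ids), 2)
  expect_equal(nrow(d$atoms), 40)  # 2 chains x 5 residues x 4 atoms
  for (ch in d$chain_ids)
    expect_equal(length(unique(d$atoms$resno[d$atoms$chain == ch])), 5)
})

test_that("PDB writing uses fixed columns at 3-decimal precision", {
  cx <- complex_from_table(data.frame(
    chain = c("A", "B"), resno = 1L, x = c(1.23456, 4), y = 0, z = 0))
  txt <- write_pdb(cx)
  lines <- strsplit(txt, "\n")[[1]]
  atom_lines <- lines[startsWith(lines, "ATOM")]
  expect_length(atom_lines, 2)
  expect_equal(trimws(lines[length(lines)]), "END")
  expect_equal(trimws(substr(atom_lines[1], 31, 38)), "1.235")
})

test_that("malformed and wrong-chain-count inputs are rejected", {
  three <- paste(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "B", 1, 5, 0, 0),
    pdb_line(3, "CA", "ALA", "C", 1, 9, 0, 0), sep = "\n")
  expect_error(parse_pdb(three), class = "ppi_structure_error")
  one <- pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0)
  expect_error(parse_pdb(one), class = "ppi_structure_error")
  bad <- paste(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               "ATOM      2  CA  ALA B   1        xx.x   0.000   0.000",
               sep = "\n")
  expect_error(parse_pdb(bad), "line 2", class = "ppi_parse_error")
  expect_error(write_pdb(complex_from_table(data.frame(
    chain = c("A", "B"), resno = 1L, x = c(0, 5), y = 0, z = 0,
    name = c("TOOLONG", "CA")))), class = "ppi_format_error")
})

test_that("interface cutoff boundary is inclusive", {
  inside <- interface_residues(two_atom_complex(5.4), 5.5)
  expect_equal(inside$residues_by_chain$A, "1")
  expect_equal(inside$residues_by_chain$B, "1")
  outside <- interface_residues(two_atom_complex(5.6), 5.5)
  expect_length(outside$residues_by_chain$A, 0)
  expect_length(outside$residues_by_chain$B, 0)
  at <- interface_residues(two_atom_complex(5.5), 5.5)
  expect_equal(at$residues_by_chain$A, "1")
})

test_that("interface selection equals the brute-force all-pairs scan", {
  d <- make_toy_dimer(6, seed = 4)
  for (cutoff in c(4, 5.5, 8)) {
    sel <- interface_residues(d, cutoff)
    oracle <- brute_interface(d, cutoff)
    expect_setequal(sel$residues_by_chain$A, oracle$res_a)
    expect_setequal(sel$residues_by_chain$B, oracle$res_b)
    expect_equal(nrow(sel$contact_atom_pairs), nrow(oracle$pairs))
  }
})

test_that("interface selection is monotone in the cutoff", {
  d <- make_toy_dimer(6, seed = 5)
  prev <- character(0)
  for (cutoff in c(3, 4.5, 5.5, 7, 10)) {
    sel <- interface_residues(d, cutoff)
    cur <- c(paste0("A", sel$residues_by_chain$A, recycle0 = TRUE),
             paste0("B", sel$residues_by_chain$B, recycle0 = TRUE))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("interface selection is invariant under rigid transforms", {
  d <- make_toy_dimer(5, seed = 6)
  sel <- interface_residues(d, 5.5)
  R <- ppirank:::random_rotation_matrix(42)
  dt <- transform_complex(d, R, translation = c(10, -3, 7),
                          center = c(1, 2, 3))
  selt <- interface_residues(dt, 5.5)
  expect_equal(selt$residues_by_chain, sel$residues_by_chain)
  expect_equal(selt$contact_atom_pairs, sel$contact_atom_pairs)
})

test_that("atomic contact pairs match enumerated distances", {
  # A1-B1 = 3, A1-B2 = 6, A2-B1 = 4, A2-B2 = 7
  cx <- complex_from_table(data.frame(
    chain = c("A", "A", "B", "B"), resno = c(1L, 2L, 1L, 2L),
    x = c(0, -1, 3, 6), y = 0, z = 0))
  pairs <- atomic_contact_pairs(cx, 5)
  expect_equal(nrow(pairs), 2)
  d <- cx$atoms
  dists <- sqrt((d$x[pairs[, 1]] - d$x[pairs[, 2]])^2)
  expect_true(all(dists <= 5))
  expect_equal(nrow(atomic_contact_pairs(cx, 0)), 0)
  # swapping chain labels leaves the pair set unchanged (as serial pairs)
  sw <- cx
  sw$atoms$chain <- ifelse(sw$atoms$chain == "A", "B", "A")
  sw$chain_ids <- rev(cx$chain_ids)
  sw <- make_complex(sw$atoms, "swapped")
  p2 <- atomic_contact_pairs(sw, 5)
  key <- function(p, c) apply(cbind(c$atoms$serial[p[, 1]],
                                    c$atoms$serial[p[, 2]]), 1,
                              function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key(pairs, cx), key(p2, sw))
})

test_that("interface residues are the residue projection of contact pairs", {
  d <- make_toy_dimer(7, seed = 9)
  sel <- interface_residues(d, 5.5)
  uid <- paste0(d$atoms$resno, d$atoms$insert)
  expect_setequal(sel$residues_by_chain$A,
                  unique(uid[sel$contact_atom_pairs[, 1]]))
  expect_setequal(sel$residues_by_chain$B,
                  unique(uid[sel$contact_atom_pairs[, 2]]))
})

test_that("receptor/ligand convention prefers the larger chain", {
  d <- make_toy_dimer(5, seed = 1)
  rl <- receptor_ligand(d)  # equal sizes: lexicographic tie-break
  expect_equal(rl$receptor, "A")
  expect_equal(rl$ligand, "B")
  big_a <- d$atoms[!(d$atoms$chain == "B" & d$atoms$resno > 3), ]
  rl2 <- receptor_ligand(make_complex(big_a, "uneven"))
  expect_equal(rl2$receptor, "A")
})
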