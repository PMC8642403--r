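test_that("element density channels count interface atoms by element", {
  # chain A residue: N + 2 C atoms; chain B residue: 1 C; all in contact
  cx <- complex_from_table(data.frame(
    chain = c("A", "A", "A", "B"), resno = 1L,
    name = c("N", "CA", "CB", "CA"), element = c("N", "C", "C", "C"),
    x = c(0, 1, 2, 4), y = 0, z = 0))
  sel <- interface_residues(cx, 5.5)
  dens <- atom_density_points(cx, sel, ff_table)
  expect_length(dens, 8)
  expect_equal(nrow(dens$density_N_A$points), 1)
  expect_equal(nrow(dens$density_C_A$points), 2)
  expect_equal(nrow(dens$density_C_B$points), 1)
  expect_equal(nrow(dens$density_S_A$points), 0)
  expect_true(all(dens$density_C_A$points$value == 1))
  expect_true(all(dens$density_C_A$points$sigma == 1.70))
  expect_true(all(dens$density_N_A$points$sigma == 1.55))
})

test_that("non-interface residues contribute no density points", {
  cx <- complex_from_table(data.frame(
    chain = c("A", "A", "B"), resno = c(1L, 2L, 1L),
    x = c(0, 50, 4), y = 0, z = 0))
  sel <- interface_residues(cx, 5.5)
  dens <- atom_density_points(cx, sel, ff_table)
  expect_equal(nrow(dens$density_C_A$points), 1)  # residue 2 excluded
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  s <- sasa(matrix(0, 1, 3), radii = 1.7, probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_equal(s$total, 120.7611, tolerance = 1e-4)
})

test_that("a fully caged atom has zero accessible area", {
  centers <- rbind(c(0, 0, 0),
                   2 * rbind(diag(3), -diag(3)))
  s <- sasa(centers, radii = rep(1.7, 7), n_points = 480)
  expect_equal(s$per_atom_area[1], 0)
})

test_that("two-sphere SASA agrees with a Monte-Carlo oracle", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))
  radii <- c(1.7, 1.5)
  s <- sasa(xyz, radii, probe = 1.4, n_points = 960)
  # oracle: 5e5 uniform random points per expanded sphere
  set.seed(101)
  mc_area <- function(i, j, n = 5e5) {
    ri <- radii[i] + 1.4; rj <- radii[j] + 1.4
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * ri, 2, xyz[i, ], "+")
    keep <- rowSums(sweep(pts, 2, xyz[j, ])^2) >= rj^2
    mean(keep) * 4 * pi * ri^2
  }
  oracle <- mc_area(1, 2) + mc_area(2, 1)
  expect_equal(s$total, oracle, tolerance = 0.02)
})

test_that("SASA converges as sphere sampling doubles", {
  d <- make_toy_dimer(5, seed = 1)
  radii <- vdw_radius(d$atoms$element, ff_table)
  s1 <- sasa(coords(d), radii, n_points = 480)
  s2 <- sasa(coords(d), radii, n_points = 960)
  expect_lt(abs(s2$total - s1$total) / s2$total, 0.01)
})

test_that("BSA is the half-sum formula, non-negative, and zero when apart", {
  d <- make_toy_dimer(5, seed = 2)
  b <- bsa(d, ff_table, n_points = 480)
  expect_equal(b$total,
               (b$asa_chain[[1]] + b$asa_chain[[2]] - b$asa_complex) / 2)
  expect_gt(b$total, 0)
  expect_true(all(b$per_residue >= 0))
  apart <- d
  bmask <- apart$atoms$chain == "B"
  apart$atoms$x[bmask] <- apart$atoms$x[bmask] + 100
  expect_equal(bsa(apart, ff_table, n_points = 480)$total, 0,
               tolerance = 1e-6)
})

test_that("BSA is invariant under rigid transforms", {
  d <- make_toy_dimer(4, seed = 3)
  b1 <- bsa(d, ff_table, n_points = 240)$total
  dt <- transform_complex(d, ppirank:::random_rotation_matrix(5),
                          translation = c(3, -2, 8))
  # quadrature uses a fixed sphere-point orientation, so invariance holds
  # to the sampling accuracy, not bit-exactly
  expect_equal(bsa(dt, ff_table, n_points = 240)$total, b1,
               tolerance = 0.01)
})

test_that("PSSM profiles round-trip and reject malformed rows", {
  d <- make_toy_dimer(5, seed = 4)
  p <- make_synthetic_pssm(d, "A", seed = 9)
  expect_equal(nrow(p$rows), 5)
  p2 <- read_pssm(write_pssm(p), chain_id = "A")
  expect_equal(p2$rows[ppirank:::PSSM_COLS],
               p$rows[ppirank:::PSSM_COLS])
  expect_equal(p2$rows$IC, p$rows$IC)
  txt <- strsplit(write_pssm(p), "\n")[[1]]
  txt[2] <- paste(strsplit(txt[2], "\t")[[1]][1:22], collapse = "\t")
  expect_error(read_pssm(txt), "22 fields", class = "ppi_format_error")
  expect_error(read_pssm(c("bad\theader", txt[-1])),
               class = "ppi_format_error")
})

test_that("PSSM feature points anchor each residue at its alpha carbon", {
  d <- make_toy_dimer(4, seed = 5)
  profs <- stats::setNames(
    lapply(c("A", "B"), function(ch) make_synthetic_pssm(d, ch, 9)),
    c("A", "B"))
  sel <- interface_residues(d, 5.5)
  fps <- pssm_feature_points(d, sel, profs, ff_table)
  expect_length(fps, 20)
  n_iface <- length(sel$residues_by_chain$A) +
    length(sel$residues_by_chain$B)
  for (fp in fps) {
    expect_equal(nrow(fp$points), n_iface)
    expect_true(all(fp$points$sigma == 1.70))
  }
  # values come from the profile rows of each residue
  ca <- d$atoms[d$atoms$chain == "A" & d$atoms$name == "CA" &
                d$atoms$resno == 1, ]
  pt <- fps$pssm_A$points
  row1 <- which(abs(pt$x - ca$x) < 1e-9)
  expect_equal(pt$value[row1],
               profs$A$rows$A[profs$A$rows$resnum == 1])
})

test_that("PSSM channels are shared: swapping chain labels changes nothing", {
  d <- make_toy_dimer(4, seed = 6)
  profs <- stats::setNames(
    lapply(c("A", "B"), function(ch) make_synthetic_pssm(d, ch, 3)),
    c("A", "B"))
  sel <- interface_residues(d, 5.5)
  fps <- pssm_feature_points(d, sel, profs, ff_table)
  sw_atoms <- d$atoms
  sw_atoms$chain <- ifelse(sw_atoms$chain == "A", "B", "A")
  sw <- make_complex(sw_atoms, "swapped")
  fps2 <- pssm_feature_points(sw, interface_residues(sw, 5.5),
                              stats::setNames(profs, c("B", "A")),
                              ff_table)
  for (nm in names(fps)) {
    o1 <- fps[[nm]]$points[order(fps[[nm]]$points$x), ]
    o2 <- fps2[[nm]]$points[order(fps2[[nm]]$points$x), ]
    expect_equal(o1$value, o2$value)
    expect_equal(o1$x, o2$x)
  }
})

test_that("PSSM alignment errors name the offending residue", {
  d <- make_toy_dimer(4, seed = 7)
  profs <- stats::setNames(
    lapply(c("A", "B"), function(ch) make_synthetic_pssm(d, ch, 3)),
    c("A", "B"))
  sel <- interface_residues(d, 5.5)
  short <- profs
  short$A$rows <- short$A$rows[-1, ]
  expect_error(pssm_feature_points(d, sel, short, ff_table),
               class = "ppi_alignment_error")
  wrong <- profs
  wrong$A$rows$resname[1] <- setdiff(ppirank:::PSSM_COLS,
                                     wrong$A$rows$resname[1])[1]
  expect_error(pssm_feature_points(d, sel, wrong, ff_table),
               "residue 1", class = "ppi_alignment_error")
  expect_error(pssm_feature_points(d, sel, profs["A"], ff_table),
               class = "ppi_alignment_error")
})

test_that("residue contact counts enumerate partner classes", {
  # A:1 contacts B:ASP (charged), B:LYS (charged), B:SER (polar)
  cx <- complex_from_table(data.frame(
    chain = c("A", "B", "B", "B"), resno = c(1L, 1L, 2L, 3L),
    resname = c("ALA", "ASP", "LYS", "SER"),
    x = c(0, 3, 0, -3), y = c(0, 0, 3, 0), z = 0))
  sel <- interface_residues(cx, 5.5)
  cc <- residue_contact_counts(cx, sel, table = ff_table)
  expect_length(cc, 6)
  expect_equal(cc$contacts_charged_A$points$value, 2)
  expect_equal(cc$contacts_polar_A$points$value, 1)
  expect_equal(cc$contacts_apolar_A$points$value, 0)
  # each contact counted once on each side: totals match
  tot_a <- sum(sapply(cc[grepl("_A$", names(cc))],
                      function(f) sum(f$points$value)))
  tot_b <- sum(sapply(cc[grepl("_B$", names(cc))],
                      function(f) sum(f$points$value)))
  expect_equal(tot_a, tot_b)
})
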