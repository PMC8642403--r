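test_that("superposition handles identity and pure translation", {
  P <- matrix(stats::rnorm(30), ncol = 3)
  s <- superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  s2 <- superpose(P, sweep(P, 2, c(5, 0, 0), "+"))
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(s2$translation, c(5, 0, 0), tolerance = 1e-8)
  expect_error(superpose(P[1:2, ], P[1:2, ]), class = "ppi_geometry_error")
})

test_that("Kabsch RMSD lower-bounds a random-rotation oracle", {
  set.seed(42)
  for (trial in 1:3) {
    P <- matrix(stats::rnorm(30), ncol = 3)
    Q <- matrix(stats::rnorm(30), ncol = 3)
    fit <- superpose(P, Q)
    oracle <- brute_min_rmsd(P, Q)
    expect_lte(fit$rmsd, oracle + 1e-12)
    expect_lt((oracle - fit$rmsd) / fit$rmsd, 0.05)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("lRMSD reports pure ligand translations exactly", {
  ref <- make_toy_dimer(6, seed = 1)
  expect_equal(lrmsd(ref, ref), 0, tolerance = 1e-10)
  model <- ref
  bmask <- model$atoms$chain == "B"
  model$atoms$x[bmask] <- model$atoms$x[bmask] + 2
  expect_equal(lrmsd(model, ref), 2.0, tolerance = 1e-9)
  rigid <- transform_complex(model, ppirank:::random_rotation_matrix(3),
                             translation = c(1, -4, 2))
  expect_equal(lrmsd(rigid, ref), 2.0, tolerance = 1e-8)
})

test_that("iRMSD is zero for rigid transforms and matches its oracle", {
  ref <- make_toy_dimer(6, seed = 2)
  expect_equal(irmsd(ref, ref), 0, tolerance = 1e-10)
  rigid <- transform_complex(ref, ppirank:::random_rotation_matrix(4),
                             translation = c(3, 3, -1))
  expect_equal(irmsd(rigid, ref), 0, tolerance = 1e-8)
  decoy <- make_decoys(ref, n_decoys = 1,
                       guarantee = c(near_native = 0, wrong = 0),
                       seed = 6)[[1]]$complex
  # independent recomputation: explicit residue lists + brute-force fit
  oracle_uids <- brute_interface(ref, 10)
  bb <- ref$atoms$name %in% c("N", "CA", "C", "O")
  sel_ref <- which(bb & ((ref$atoms$chain == "A" &
                          ref$atoms$resno %in% oracle_uids$res_a) |
                         (ref$atoms$chain == "B" &
                          ref$atoms$resno %in% oracle_uids$res_b)))
  P <- coords(decoy)[sel_ref, ]; Q <- coords(ref)[sel_ref, ]
  ir <- irmsd(decoy, ref)
  oracle <- brute_min_rmsd(P, Q, n_rot = 1e5)
  expect_lte(ir, oracle + 1e-12)
  # the random-rotation grid resolves the optimum to roughly 10%
  expect_lt((oracle - ir) / ir, 0.10)
})

test_that("FNAT counts preserved native contacts", {
  # four native residue pairs at 4.5 A; the model breaks exactly one
  ref <- complex_from_table(data.frame(
    chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2),
    x = rep(seq(0, 15, by = 5), 2), y = rep(c(0, 4.5), each = 4), z = 0))
  expect_equal(fnat(ref, ref), 1.0)
  model <- ref
  model$atoms$y[model$atoms$chain == "B" & model$atoms$resno == 4] <- 40
  expect_equal(fnat(model, ref), 0.75)
  far <- ref
  far$atoms$y[far$atoms$chain == "B"] <- 100
  expect_equal(fnat(far, ref), 0)
})

test_that("DockQ matches its closed form and is monotone", {
  expect_equal(dockq(1, 0, 0), 1.0)
  expect_equal(dockq(0.5, 8.5, 1.5), 0.5)
  expect_lt(dockq(0, 100, 100), 0.01)
  set.seed(7)
  for (i in 1:50) {
    f <- stats::runif(1); l <- stats::runif(1, 0, 20); r <- stats::runif(1, 0, 10)
    expect_gte(dockq(min(f + 0.1, 1), l, r), dockq(f, l, r))
    expect_gte(dockq(f, l, r), dockq(f, l + 1, r))
    expect_gte(dockq(f, l, r), dockq(f, l, r + 1))
  }
  expect_error(dockq(-0.1, 1, 1), class = "ppi_domain_error")
})

test_that("CAPRI classes respect their inclusive thresholds", {
  expect_equal(capri_class(1.0, 0, 0), "high")
  expect_equal(capri_class(0.05, 20, 8), "incorrect")
  expect_equal(capri_class(0.1, 10.0, 4.0), "acceptable")
  expect_equal(capri_class(0.5, 12, 1.0), "high")
  expect_equal(capri_class(0.3, 5.0, 3.0), "medium")
  expect_equal(capri_class(0.3, 5.0001, 2.0001), "acceptable")
})

test_that("the near-native label is inclusive at the 4 A threshold", {
  expect_equal(binary_label(4.0), "near-native")
  expect_equal(binary_label(4.0001), "wrong")
  expect_equal(binary_label(0), "near-native")
  expect_error(binary_label(-1), class = "ppi_domain_error")
})

test_that("decoy iRMSD tracks the applied displacement", {
  ref <- make_toy_dimer(8, seed = 11)
  decoys <- make_decoys(ref, n_decoys = 50, seed = 12,
                        guarantee = c(near_native = 5, wrong = 5))
  ir <- vapply(decoys, function(d) d$irmsd, numeric(1))
  disp <- vapply(decoys, function(d) d$displacement, numeric(1))
  expect_gt(stats::cor(ir, disp, method = "spearman"), 0.9)
  labs <- vapply(decoys, function(d) d$label, character(1))
  expect_gte(sum(labs == "near-native"), 5)
  expect_gte(sum(labs == "wrong"), 5)
})

test_that("all metrics survive a joint rigid transform of the model", {
  ref <- make_toy_dimer(6, seed = 13)
  decoy <- make_decoys(ref, 1, guarantee = c(near_native = 0, wrong = 0),
                       seed = 14)[[1]]$complex
  t0 <- compute_targets(decoy, ref)
  moved <- transform_complex(decoy, ppirank:::random_rotation_matrix(15),
                             translation = c(-5, 2, 9), center = c(1, 0, 0))
  t1 <- compute_targets(moved, ref)
  expect_equal(t1$irmsd, t0$irmsd, tolerance = 1e-8)
  expect_equal(t1$lrmsd, t0$lrmsd, tolerance = 1e-8)
  expect_equal(t1$fnat, t0$fnat)
  expect_equal(t1$dockq, t0$dockq, tolerance = 1e-8)
})
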