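test_that("HBD counts every H on non-anionic N/O in the requested charge state", {
  expect_equal(count_hbd(rec("CCO", "ethanol"), "neutral"), 1L)
  expect_equal(count_hbd(rec("CC[NH2+]C", "prot_amine"), "neutral"), 2L)
  expect_equal(count_hbd(rec("c1ccccc1[O-]", "phenolate"), "neutral"), 0L)
  # protonation at pH 7 adds the ammonium hydrogens
  amine <- rec("CCNCC", "dea2")
  expect_equal(count_hbd(amine, "neutral"), 1L)
  expect_equal(count_hbd(amine, "ph7"), 2L)
})

test_that("HBD gained at pH 7 equals the protons added by the protonation rules", {
  for (s in DRUGLIKE_SMILES) {
    r <- protonate_ph7(parse_structure(s, s))
    delta <- macrospace:::.ph7_charge_delta(r$mol_neutral)
    protons_added <- sum(delta[delta > 0])
    protons_removed <- sum(-delta[delta < 0])
    expect_equal(count_hbd(r, "ph7") - count_hbd(r, "neutral"),
                 protons_added - protons_removed, label = s)
  }
})

test_that("HBA counts N/O/F minus charged, oxidised and pyrrole-type nitrogens", {
  expect_equal(count_hba(rec("c1ccncc1", "pyridine"), "neutral"), 1L)
  expect_equal(count_hba(rec("c1cc[nH]c1", "pyrrole"), "neutral"), 0L)
  expect_equal(count_hba(rec("Cn1cccc1", "n_me_pyrrole"), "neutral"), 0L)
  expect_equal(count_hba(rec("C[N+](=O)[O-]", "nitromethane"), "neutral"), 2L)
  expect_equal(count_hba(rec("FC(F)(F)c1ccccc1", "btf"), "neutral"), 3L)
  # imidazole: pyridine-type N counts, pyrrole-type does not
  expect_equal(count_hba(rec("c1cnc[nH]1", "imidazole"), "neutral"), 1L)
  # HBA never counts carbon or sulfur
  expect_equal(count_hba(rec("CCSCC", "sulfide"), "neutral"), 0L)
})

test_that("counting is invariant under SMILES rewriting", {
  pairs <- list(c("OCC", "C(O)C"), c("c1ccncc1", "n1ccccc1"),
                c("NC(=O)c1ccccc1", "c1ccccc1C(N)=O"))
  for (p in pairs) {
    a <- parse_structure(p[1], "a"); b <- parse_structure(p[2], "b")
    expect_equal(count_hbd(a, "neutral"), count_hbd(b, "neutral"), info = p[1])
    expect_equal(count_hba(a, "neutral"), count_hba(b, "neutral"), info = p[1])
  }
})

test_that("molecular weight is additive over fragments before fragment selection", {
  combined <- ChemmineR::smiles2sdf(c(x = "CCO.CC(=O)O"))
  mw_all <- macrospace:::.mol_weight(macrospace:::.build_mol(combined[[1]]))
  mw_a <- macrospace:::.mol_weight(rec("CCO", "ethanol")$mol_neutral)
  mw_b <- macrospace:::.mol_weight(rec("CC(=O)O", "hac")$mol_neutral)
  expect_equal(mw_all, mw_a + mw_b, tolerance = 1e-9)
  expect_equal(mw_a, 46.069, tolerance = 1e-3)
})

test_that("rotatable bond counting follows the amide-excluded dialect", {
  expect_equal(macrospace:::.nrotb_mol(rec("CCCC", "butane")$mol_neutral), 1L)
  expect_equal(macrospace:::.nrotb_mol(rec("c1ccccc1", "benzene")$mol_neutral), 0L)
  # fully cyclic molecules have no rotatable bonds
  expect_equal(macrospace:::.nrotb_mol(rec("C1CCCCCCCCCCC1", "cdd")$mol_neutral), 0L)
  nma <- rec("CC(=O)NC", "nma")$mol_neutral
  expect_equal(macrospace:::.nrotb_mol(nma, exclude_amide = TRUE), 0L)
  expect_equal(macrospace:::.nrotb_mol(nma, exclude_amide = FALSE), 1L)
})

test_that("aromatic ring counting matches known ring systems", {
  cases <- list(c("c1ccccc1", 1), c("c1ccc2ccccc2c1", 2),
                c("c1ccc(-c2ccccc2)cc1", 2), c("C1CCCCC1", 0),
                c("c1ccncc1", 1), c("c1cc[nH]c1", 1),
                c("O=c1cccc[nH]1", 1))
  for (cs in cases) {
    m <- parse_structure(cs[[1]], cs[[1]])
    expect_equal(macrospace:::.nar_mol(m$mol_neutral), as.integer(cs[[2]]),
                 label = cs[[1]])
  }
})

test_that("Kier flexibility matches hand-evaluated kappa-alpha values", {
  # n-hexane: A=6, all sp3 C (alpha 0), P1=5, P2=4 -> 1k=6*25/25=6,
  # 2k=5*16/16=5, phi=6*5/6=5
  expect_equal(kier_phi(rec("CCCCCC", "hexane"), "neutral"), 5, tolerance = 1e-9)
  # cyclohexane: P1=6, P2=6 -> 1k=150/36, 2k=80/36, phi=1.54321
  expect_equal(kier_phi(rec("C1CCCCC1", "cyclohexane"), "neutral"),
               (6 * 25 / 36) * (5 * 16 / 36) / 6, tolerance = 1e-9)
  # benzene: alpha = 6*(0.67/0.77 - 1); frozen from the closed formula
  a <- 6 * (0.67 / 0.77 - 1)
  phi_benzene <- ((6 + a) * (5 + a)^2 / (6 + a)^2) *
    ((5 + a) * (4 + a)^2 / (6 + a)^2) / 6
  expect_equal(kier_phi(rec("c1ccccc1", "benzene"), "neutral"),
               phi_benzene, tolerance = 1e-9)
  expect_gt(kier_phi(rec("CCCCCC", "hexane"), "neutral"),
            kier_phi(rec("C1CCCCC1", "cyclohexane"), "neutral"))
})

test_that("the descriptor panel fills every field consistently", {
  p <- compute_panel(rec("c1ccccc1", "benzene"), "neutral")
  expect_equal(p$nC, 6L)
  expect_equal(p$NAR, 1L)
  expect_equal(p$NRotB, 0L)
  expect_equal(p$HBD, 0L)
  expect_equal(p$MW, 78.114, tolerance = 1e-3)
  expect_equal(p$TPSA, 0)
  expect_equal(p$charge_state, "neutral")

  g5 <- build_fixture_macrocycles("cyclo_glycine", 5)
  pg <- compute_panel(g5, "neutral")
  expect_equal(pg$HBD, 5L)
  expect_equal(pg$ring_size, 15L)
  expect_equal(pg$nC, 10L)
  expect_true(all(c("MW", "nC", "cLogP", "cLogS", "cLogD", "TPSA", "HBD",
                    "HBA", "NRotB", "NAR", "phi", "ring_size",
                    "n_stereocenters") %in% names(pg)))
})

test_that("tetrahedral stereocentre candidates are counted", {
  expect_equal(compute_panel(rec("CC(O)CC", "butan2ol"), "neutral")$n_stereocenters, 1L)
  expect_equal(compute_panel(rec("CC(C)O", "propan2ol"), "neutral")$n_stereocenters, 0L)
  expect_gt(compute_panel(rec(cyclosporin_a_smiles, "csa"), "neutral")$n_stereocenters, 5L)
})

test_that("descriptor_table carries labels and skips metal records with a warning", {
  recs <- list(parse_structure("CCO", "a", route = "oral"),
               parse_structure("CC[Hg]CC", "hg", route = "parenteral"),
               parse_structure("CCN", "b", route = "parenteral"))
  expect_warning(tab <- descriptor_table(recs, "neutral"), "metal")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$route, c("oral", "parenteral"))
})

test_that("AB-MPS implements |cLogD - 3| + NAR + NRotB with its cutoffs", {
  expect_equal(ab_mps(list(cLogD = 3, NAR = 0, NRotB = 0)), 0)
  expect_equal(ab_mps(list(cLogD = 5, NAR = 3, NRotB = 10)), 15)
  expect_equal(ab_mps(list(cLogD = -1, NAR = 2, NRotB = 11)), 17)
  expect_equal(ab_mps_class(15, 15), "oral")
  expect_equal(ab_mps_class(15, 14), "parenteral")
  expect_error(ab_mps(list(NAR = 1, NRotB = 2)), "cLogD")
  expect_error(ab_mps(list(cLogD = NA, NAR = 1, NRotB = 2)), "cLogD")
  # minimised exactly at cLogD = 3 for fixed NAR/NRotB
  grid <- seq(-5, 10, by = 0.25)
  scores <- vapply(grid, function(d) ab_mps(list(cLogD = d, NAR = 2, NRotB = 4)),
                   numeric(1))
  expect_equal(grid[which.min(scores)], 3)
})
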