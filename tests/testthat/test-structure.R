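test_that("toy helix has ideal alpha-helical geometry and is deterministic", {
  m <- toy_helix(10)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 10)
  steps <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(steps - 3.83) < 0.05))  # consecutive CA-CA ~3.8 A
  m2 <- toy_helix(10)
  expect_identical(m$atoms, m2$atoms)

  far <- generate_toy_structure(toy_structure_spec(list(
    list(length = 8, origin = c(0, 0, 0), direction = c(0, 0, 1)),
    list(length = 8, origin = c(30, 0, 0), direction = c(0, 0, 1)))))
  a1 <- far$atoms[far$atoms$resno <= 8, c("x", "y", "z")]
  a2 <- far$atoms[far$atoms$resno > 8, c("x", "y", "z")]
  dmin <- min(sqrt(outer(a1$x, a2$x, `-`)^2 +
                   outer(a1$y, a2$y, `-`)^2 +
                   outer(a1$z, a2$z, `-`)^2))
  expect_gt(dmin, 10)
})

test_that("PDB write/read round-trips a toy structure", {
  m <- toy_helix(8)
  path <- tempfile(fileext = ".pdb")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_equal(back$atoms$resno, m$atoms$resno)
  expect_equal(back$atoms$elety, m$atoms$elety)
  expect_equal(back$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_length(attr(back, "no_ca"), 0)
})

test_that("altloc atoms resolve to highest occupancy, ties to A", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60 20.00           C",
    "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_structure(path)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 2.0)    # B kept: higher occupancy
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(cb$x, 3.0)    # tie: altloc A kept
  expect_error(read_structure(tempfile()), "not found")
})

test_that("superposition recovers rigid motions exactly", {
  m <- toy_helix(12)
  fit0 <- superpose(m, m)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$R, diag(3), tolerance = 1e-10)

  R <- rotation_matrix("z", 90)
  moved <- perturb_structure(m, rigid = list(R = R, t = c(5, -3, 2)))
  fit <- superpose(moved, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)

  # RMSD invariant under any further rigid pre-transformation of the mobile
  moved2 <- perturb_structure(moved, rigid = list(R = rotation_matrix("x", 37),
                                                  t = c(-1, 8, 0.5)))
  expect_equal(superpose(moved2, m)$rmsd, fit$rmsd, tolerance = 1e-8)
  expect_error(superpose(toy_helix(4), toy_helix(12), selection = 1:2),
               "at least 3")
})

test_that("superposition agrees with the bio3d reference implementation", {
  m <- toy_helix(15)
  set.seed(3)
  jitter <- perturb_structure(
    m, displacements = setNames(lapply(1:15, function(i) runif(3, -0.3, 0.3)),
                                as.character(1:15)),
    rigid = list(R = rotation_matrix("y", 25), t = c(2, 2, 2)))
  fit <- superpose(jitter, m)
  ca_m <- jitter$atoms[jitter$atoms$elety == "CA", c("x", "y", "z")]
  ca_t <- m$atoms[m$atoms$elety == "CA", c("x", "y", "z")]
  xyz_m <- as.numeric(t(as.matrix(ca_m)))
  xyz_t <- as.numeric(t(as.matrix(ca_t)))
  fitted <- bio3d::fit.xyz(fixed = xyz_t, mobile = xyz_m,
                           fixed.inds = seq_along(xyz_t),
                           mobile.inds = seq_along(xyz_m))
  ref_rmsd <- bio3d::rmsd(xyz_t, fitted)
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-3)
  # a least-squares optimum can never sit above the reference fit
  expect_lte(fit$rmsd, ref_rmsd + 1e-9)
})

test_that("CA deviation recovers injected displacements after superposition", {
  wt <- toy_helix(20)
  # displace residue 5 by 2.0 A, fit on the others
  var <- perturb_structure(wt, displacements = list(`5` = c(0, 0, 2)))
  dev <- ca_deviation_profile(var, wt, fit_selection = setdiff(1:20, 5))
  expect_equal(dev$deviation[dev$resno == 5], 2.0, tolerance = 1e-3)
  expect_true(all(dev$deviation[dev$resno != 5] < 1e-6))

  # identical structures: all zero
  dev0 <- ca_deviation_profile(wt, wt)
  expect_true(all(dev0$deviation < 1e-9))

  # rigid-motion-only perturbation: all deviations vanish after fitting
  rigid <- perturb_structure(wt, rigid = list(R = rotation_matrix("x", 60),
                                              t = c(1, 2, 3)))
  devr <- ca_deviation_profile(rigid, wt)
  expect_true(all(devr$deviation < 1e-6))

  # report restriction and ordering
  devs <- ca_deviation_profile(var, wt, fit_selection = setdiff(1:20, 5),
                               report_selection = c(7, 5, 3))
  expect_equal(devs$resno, c(3L, 5L, 7L))
  expect_error(ca_deviation_profile(var, wt, report_selection = 999),
               "empty report")
})

test_that("hydrogen bonds obey distance and angle criteria", {
  m <- toy_helix(12)
  # make residue 2 a serine with OG 2.9 A from the backbone O of residue 9,
  # approached radially outward so no other backbone atom comes closer
  target <- as.numeric(m$atoms[m$atoms$resno == 9 & m$atoms$elety == "O",
                               c("x", "y", "z")])
  u <- (target - c(0, 0, target[3]))
  u <- u / sqrt(sum(u^2))
  og <- target + 2.9 * u
  cb <- og + 1.5 * u        # antecedent behind the donor: angle 180 deg
  m2 <- add_atom(m, 2, "CB", cb, resid = "SER")
  m2 <- add_atom(m2, 2, "OG", og)
  net <- detect_polar_contacts(m2, set_a = 1:3, set_b = 8:10)
  hb <- net[net$type == "hydrogen-bond" & net$atom_a == "OG", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$dist, 2.9, tolerance = 1e-6)
  expect_equal(hb$resno_b, 9L)

  # same geometry at 6.0 A: no edge
  m3 <- add_atom(m, 2, "CB", target + 7.5 * u, resid = "SER")
  m3 <- add_atom(m3, 2, "OG", target + 6.0 * u)
  net3 <- detect_polar_contacts(m3, set_a = 1:3, set_b = 8:10,
                                criteria = contact_criteria())
  expect_equal(nrow(net3[net3$atom_a == "OG", ]), 0)

  # acute antecedent angle fails the 90 degree criterion
  m4 <- add_atom(m, 2, "CB", og - 1.5 * u, resid = "SER")  # in front
  m4 <- add_atom(m4, 2, "OG", og)
  net4 <- detect_polar_contacts(m4, set_a = 1:3, set_b = 8:10)
  expect_equal(nrow(net4[net4$atom_a == "OG", ]), 0)
})

test_that("ionic contacts pair basic and acidic side chains, deduplicated", {
  m <- toy_helix(12)
  base <- c(20, 20, 20)
  m <- add_atom(m, 2, "CZ",  base + c(0, 0, -1.3), resid = "ARG")
  m <- add_atom(m, 2, "NH1", base)
  m <- add_atom(m, 2, "NH2", base + c(1.2, 0, -0.5))
  m <- add_atom(m, 9, "CG",  base + c(0, 1.0, 3.2 + 1.3), resid = "ASP")
  m <- add_atom(m, 9, "OD1", base + c(0, 0, 3.2))
  m <- add_atom(m, 9, "OD2", base + c(1.0, 0, 3.6))
  net <- detect_polar_contacts(m, set_a = 1:3, set_b = 8:10)
  ion <- net[net$type == "ionic", ]
  expect_equal(nrow(ion), 1)               # deduplicated to closest atom pair
  expect_equal(ion$dist, 3.2, tolerance = 1e-6)
  expect_equal(sort(c(ion$atom_a, ion$atom_b)), c("NH1", "OD1"))

  all_pairs <- detect_polar_contacts(m, set_a = 1:3, set_b = 8:10,
                                     criteria = contact_criteria(dedupe = FALSE))
  expect_gt(nrow(all_pairs[all_pairs$type == "ionic", ]), 1)
})

test_that("contact detection is symmetric and rigid-motion invariant", {
  m <- toy_helix(12)
  o9 <- as.numeric(m$atoms[m$atoms$resno == 9 & m$atoms$elety == "O",
                           c("x", "y", "z")])
  u <- o9 - c(0, 0, o9[3]); u <- u / sqrt(sum(u^2))
  m <- add_atom(m, 2, "CB", o9 + 4.4 * u, resid = "SER")
  m <- add_atom(m, 2, "OG", o9 + 2.9 * u)
  n_ab <- detect_polar_contacts(m, set_a = 1:3, set_b = 8:10)
  n_ba <- detect_polar_contacts(m, set_a = 8:10, set_b = 1:3)
  expect_equal(nrow(n_ab), nrow(n_ba))
  expect_equal(sort(n_ab$dist), sort(n_ba$dist))

  rot <- perturb_structure(m, rigid = list(R = rotation_matrix("y", 123),
                                           t = c(-4, 7, 1)))
  n_rot <- detect_polar_contacts(rot, set_a = 1:3, set_b = 8:10)
  expect_equal(nrow(n_rot), nrow(n_ab))
  expect_equal(sort(n_rot$dist), sort(n_ab$dist), tolerance = 1e-9)
})

test_that("helix network report counts engineered inter-helix bonds", {
  far <- generate_toy_structure(toy_structure_spec(list(
    list(length = 10, origin = c(0, 0, 0), direction = c(0, 0, 1)),
    list(length = 10, origin = c(25, 0, 0), direction = c(0, 0, 1)))))
  hx <- helix_annotation(c("h1", "h2"), "A", c(1, 11), c(10, 20))
  rep0 <- helix_network_report(far, hx)
  expect_equal(rep0$n_atom_pairs, 0)  # 25 A apart: nothing
  expect_equal(rep0$n_residue_pairs, 0)

  # engineer 3 hydrogen bonds bridging the two helices
  m <- far
  anchors <- list(c(12, 0, 2), c(12, 0, 8), c(12, 0, 14))
  donors <- c(2, 5, 8); acceptors <- c(12, 15, 18)
  for (k in 1:3) {
    p <- anchors[[k]]
    m <- add_atom(m, donors[k], "CB", p + c(-1.5, 0, 0), resid = "SER")
    m <- add_atom(m, donors[k], "OG", p)
    m <- add_atom(m, acceptors[k], "CG",  p + c(3.0 + 1.3, 0, 0), resid = "ASN")
    m <- add_atom(m, acceptors[k], "OD1", p + c(3.0, 0, 0))
  }
  rep3 <- helix_network_report(m, hx)
  expect_equal(rep3$n_residue_pairs, 3)
  expect_equal(unique(rep3$edges$helix_pair), "h1-h2")
  expect_true(all(rep3$edges$type == "hydrogen-bond"))

  # counts are monotone in the distance cutoffs
  grid <- contact_cutoff_grid(m, hx, h_grid = c(2.5, 3.0, 3.5), i_grid = 4.0)
  expect_true(all(diff(grid$n_atom_pairs) >= 0))

  expect_error(helix_network_report(m, helix_annotation(c("x", "y"), "A",
                                                        c(1, 5), c(8, 12))),
               "overlapping")
})

test_that("conservation painting sets scaled B-factors with sentinels", {
  m <- toy_helix(6)
  prof <- structure(data.frame(site = c(1, 2, 3, 5),
                               entropy = c(0, 0.5, 1, 0.25),
                               nongap_fraction = 1, consensus = "A",
                               n_observed = 10L),
                    class = c("conservation_profile", "data.frame"))
  painted <- map_scores_to_structure(m, prof, chain = "A", scale = 100)
  a <- painted$atoms
  expect_true(all(a$b[a$resno == 1] == 0))
  expect_true(all(a$b[a$resno == 2] == 50))
  expect_true(all(a$b[a$resno == 3] == 100))
  expect_true(all(a$b[a$resno == 4] == -1))   # no profile value: sentinel
  expect_equal(attr(painted, "unpainted"), c(4L, 6L))
  expect_error(map_scores_to_structure(m, prof, chain = "Z"), "chain")

  # round-trip through PDB keeps painted values to format precision
  path <- tempfile(fileext = ".pdb")
  write_structure(painted, path)
  back <- read_structure(path)
  expect_equal(back$atoms$b, painted$atoms$b, tolerance = 1e-2)
})

test_that("mutation overlap classifies network, CMT and conserved residues", {
  prof <- structure(data.frame(site = 1:10,
                               entropy = c(0.04, 0.5, 0.06, rep(0.5, 7)),
                               nongap_fraction = 1, consensus = "A",
                               n_observed = 10L),
                    class = c("conservation_profile", "data.frame"))
  net <- data.frame(chain_a = "A", resno_a = c(2L, 3L), resid_a = "ALA",
                    atom_a = "N", chain_b = "A", resno_b = c(7L, 8L),
                    resid_b = "ALA", atom_b = "O", dist = 3.0,
                    type = "hydrogen-bond", stringsAsFactors = FALSE)
  rep <- mutation_overlap_report(net, prof, cmt_sites = c(1, 2), s_max = 0.1,
                                 focus = 7:8)
  cls <- rep$classes
  expect_equal(cls$class[cls$resno == 1], "both")            # CMT + conserved
  expect_equal(cls$class[cls$resno == 2], "CMT-only")
  expect_equal(cls$class[cls$resno == 3], "conserved-only")
  expect_equal(cls$class[cls$resno == 7], "neither")         # network only
  expect_true(all(cls$in_network[cls$resno %in% c(2, 3, 7, 8)]))
  # residues contacting the focus segment, with their classes
  expect_equal(rep$focus_contacts$resno, c(2L, 3L))
  expect_equal(rep$focus_contacts$class, c("CMT-only", "conserved-only"))

  none <- mutation_overlap_report(net, prof, cmt_sites = integer(0), s_max = 0.1)
  expect_false(any(grepl("CMT", none$classes$class)))
})
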