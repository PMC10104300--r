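test_that("column frequencies treat gaps and ambiguity codes as missing", {
  d <- dist_from_column("AAAA")
  expect_equal(unname(d$freqs["A"]), 1)
  expect_equal(d$n_observed, 4L)
  expect_equal(d$nongap_fraction, 1)

  d <- dist_from_column("AA--")
  expect_equal(unname(d$freqs["A"]), 1)
  expect_equal(d$n_observed, 2L)
  expect_equal(d$nongap_fraction, 0.5)

  # X counts as missing for frequencies and against the non-gap fraction
  d <- dist_from_column("AAXC")
  expect_equal(unname(d$freqs["A"]), 2 / 3)
  expect_equal(unname(d$freqs["C"]), 1 / 3)
  expect_equal(d$n_observed, 3L)
  expect_equal(d$nongap_fraction, 3 / 4)
  expect_equal(sum(d$freqs), 1)
})

test_that("base-20 entropy matches closed forms and respects its bounds", {
  # fully conserved -> 0; uniform over 20 types -> 1
  expect_identical(site_entropy(dist_from_column("AAAA")), 0)
  uniform <- dist_from_column(paste(famcons:::AA20, collapse = ""))
  expect_equal(site_entropy(uniform), 1, tolerance = 1e-12)
  # 50/50 two types -> log20(2)
  expect_equal(site_entropy(dist_from_column("AACC")), log(2) / log(20),
               tolerance = 1e-12)
  # all-gap column is undefined, not zero
  expect_true(is.na(site_entropy(dist_from_column("----"))))
})

test_that("entropy profile: closed forms, tie-break, and row symmetry", {
  proj <- proj_from_strings(c(s1 = "AA", s2 = "AC", s3 = "AD", s4 = "AE"))
  prof <- entropy_profile(proj)
  expect_equal(prof$entropy, c(0, log(4) / log(20)), tolerance = 1e-12)
  expect_equal(prof$consensus, c("A", "A"))  # 4-way tie at site 2 -> alphabetical

  # permuting rows or duplicating every row leaves the profile unchanged
  perm <- proj_from_strings(c(s3 = "AD", s1 = "AA", s4 = "AE", s2 = "AC"))
  expect_equal(entropy_profile(perm)$entropy, prof$entropy)
  dup <- proj_from_strings(c(s1 = "AA", s2 = "AC", s3 = "AD", s4 = "AE",
                             t1 = "AA", t2 = "AC", t3 = "AD", t4 = "AE"))
  expect_equal(entropy_profile(dup)$entropy, prof$entropy)
  expect_equal(entropy_profile(dup)$consensus, prof$consensus)
})

test_that("entropy is 0 iff one residue type and 1 iff uniform over 20", {
  set.seed(7)
  for (i in 1:20) {
    letters_used <- sample(famcons:::AA20, sample(1:5, 1))
    col <- paste(sample(letters_used, 30, replace = TRUE), collapse = "")
    S <- site_entropy(dist_from_column(col))
    n_types <- length(unique(strsplit(col, "")[[1]]))
    expect_gte(S, 0)
    expect_lte(S, 1)
    expect_equal(S == 0, n_types == 1)
  }
})

test_that("conserved_sites filters on entropy and non-gap fraction", {
  prof <- structure(data.frame(site = 1:3,
                               entropy = c(0.05, 0.5, 0.08),
                               nongap_fraction = c(0.9, 0.9, 0.5),
                               consensus = c("A", "C", "D"),
                               n_observed = c(9L, 9L, 5L)),
                    class = c("conservation_profile", "data.frame"))
  tab <- conserved_sites(prof, s_max = 0.1, frac_min = 0.7)
  expect_equal(tab$residue, 1L)   # site 2 too variable, site 3 too gappy
  expect_equal(tab$amino_acid, "A")
  all_tab <- conserved_sites(prof, s_max = 1, frac_min = 0)
  expect_equal(nrow(all_tab), 3L)
  none <- conserved_sites(prof, s_max = 0.1, frac_min = 0.95)
  expect_equal(nrow(none), 0L)
  expect_error(conserved_sites(prof, s_max = 0), "s_max")
})

test_that("KL divergence matches closed form and brute-force smoothing oracle", {
  # shared support, no smoothing: 0.5 ln2 + 0.5 ln(2/3)
  p <- dist_from_column("AACC")
  q <- dist_from_column("ACCC")
  expect_equal(kl_divergence(p, q, pseudocount = 0),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence(p, q, pseudocount = 0), 0.14384, tolerance = 1e-5)

  # disjoint support with pseudocount 0.5: independent brute-force oracle
  pa <- dist_from_column(strrep("A", 10))
  qc <- dist_from_column(strrep("C", 10))
  expect_equal(kl_divergence(pa, qc, pseudocount = 0.5),
               brute_kl(pa$counts, qc$counts, 0.5), tolerance = 1e-12)

  # identical distributions -> 0; undefined column -> NA
  expect_equal(kl_divergence(pa, pa, pseudocount = 0.5), 0)
  expect_true(is.na(kl_divergence(pa, dist_from_column("----"), 0.5)))
})

test_that("KL is non-negative and asymmetric in general", {
  set.seed(11)
  for (i in 1:25) {
    p <- dist_from_column(paste(sample(famcons:::AA20[1:4], 12, TRUE), collapse = ""))
    q <- dist_from_column(paste(sample(famcons:::AA20[3:8], 12, TRUE), collapse = ""))
    expect_gte(kl_divergence(p, q, 0.5), -1e-12)
    expect_gte(kl_divergence(q, p, 0.5), -1e-12)
  }
  # an explicit asymmetric case
  p <- dist_from_column("AAAAAAAAAC")
  q <- dist_from_column("AAAAACCCCC")
  expect_false(isTRUE(all.equal(kl_divergence(p, q, 0.5),
                                kl_divergence(q, p, 0.5))))
})

test_that("entropy estimate converges to the true base-20 entropy", {
  true_p <- mix_dist(A = 0.4, C = 0.3, D = 0.2, E = 0.1)
  true_S <- site_entropy(true_p)
  tols <- c(`50` = 0.15, `500` = 0.05, `5000` = 0.02)
  errs <- numeric(0)
  for (n in c(50, 500, 5000)) {
    fam <- generate_family(family_spec(n, sites = rep(list(true_p), 4), seed = 101))
    prof <- entropy_profile(fam$proj)
    err <- max(abs(prof$entropy - true_S))
    errs[as.character(n)] <- err
    expect_lt(err, tols[[as.character(n)]])
  }
  expect_lt(errs[["5000"]], errs[["50"]])
})

test_that("divergence profile ranks injected divergent sites on top", {
  div <- list(`3` = list(point_dist("A"), point_dist("C")),
              `7` = list(point_dist("D"), point_dist("E")),
              `11` = list(point_dist("F"), point_dist("G")),
              `15` = list(point_dist("H"), point_dist("I")),
              `19` = list(point_dist("K"), point_dist("L")))
  gen <- generate_two_groups(
    family_spec(200, sites = rep(list(5), 20), seed = 202),
    divergent_sites = div)
  dp <- divergence_profile(gen$proj, "group1", "group2")
  top5 <- sort(dp$site[1:5])
  expect_equal(top5, c(3L, 7L, 11L, 15L, 19L))
  expect_true(all(dp$conserved_divergent[1:5]))

  # swapping the group labels swaps the two directions exactly
  dps <- divergence_profile(gen$proj, "group2", "group1")
  m <- match(dp$site, dps$site)
  expect_equal(dp$kl_1, dps$kl_2[m])
  expect_equal(dp$kl_2, dps$kl_1[m])
  expect_equal(dp$s_1, dps$s_2[m])
  expect_equal(dp$modal_1, dps$modal_2[m])
})

test_that("divergence is near zero when groups share one distribution", {
  gen <- generate_two_groups(family_spec(1000, sites = rep(list(2), 10), seed = 303))
  dp <- divergence_profile(gen$proj, "group1", "group2")
  expect_lt(max(dp$kl_1), 0.1)
  expect_lt(max(dp$kl_2), 0.1)
})

test_that("divergence profile validates groups", {
  proj <- proj_from_strings(c(a = "AC", b = "AD", c = "AE"))
  expect_error(divergence_profile(proj, c("a", "b"), c("b", "c")), "disjoint")
  expect_error(divergence_profile(proj, character(0), "c"), "non-empty|empty")
})

test_that("table exports render gap-majority groups as '-'", {
  proj <- proj_from_strings(
    c(g1a = "AC", g1b = "AC", g2a = "A-", g2b = "A-"),
    row_groups = c(g1a = "g1", g1b = "g1", g2a = "g2", g2b = "g2"))
  dp <- divergence_profile(proj, "g1", "g2")
  path <- tempfile(fileext = ".tsv")
  write_divergence_tsv(dp, path, group_names = c("g1", "g2"))
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(names(tab)[1:5], c("res num", "KL_1", "KL_2", "S_1", "S_2"))
  expect_equal(tab$g2[tab$`res num` == 2], "-")  # site 2 gap-majority in g2
  expect_equal(tab$g1[tab$`res num` == 2], "C")
})
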