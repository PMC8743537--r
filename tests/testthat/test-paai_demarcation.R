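test_that("global alignment handles matches, gaps and ties deterministically", {
  al <- global_align("MKV", "MKV")
  expect_equal(al$aligned_a, "MKV")
  expect_equal(al$aligned_b, "MKV")
  expect_equal(al$aligned_cols, 3)

  # hand 3x2 affine DP: M~M (+5), K against gap (-12), V~V (+4) = -3
  al2 <- global_align("MKV", "MV")
  expect_equal(al2$score, -3)
  expect_equal(al2$aligned_a, "MKV")
  expect_equal(al2$aligned_b, "M-V")

  # score symmetry
  set.seed(51)
  for (rep in 1:5) {
    a <- random_protein_seq(sample(20:60, 1))
    b <- random_protein_seq(sample(20:60, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("global alignment scores agree with the Biostrings oracle", {
  set.seed(52)
  for (rep in 1:6) {
    a <- random_protein_seq(sample(30:150, 1))
    b <- crude_mutate(random_protein_seq(nchar(a)), 0.6)
    expect_equal(global_align(a, b)$score, biostrings_score(a, b, "global"))
  }
})

test_that("PAAI follows the terminal-gap-exclusion column rule", {
  expect_equal(paai("MKVLLA", "MKVLLA"), 100)
  # gapless global alignment, 3 of 4 columns identical
  expect_equal(paai("AAAA", "AAAT"), 75)
  # hand DP: the ungapped frame-shifted alignment (score -3) beats the
  # double-terminal-gap alignment (score -12); no column is identical
  al <- global_align("MKVL", "KVLA")
  expect_equal(al$score, -3)
  expect_equal(paai("MKVL", "KVLA"), 0)
  # terminal overhangs excluded from the denominator: MKVLLA vs KVLLA
  # aligns with one leading gap; 5 of 5 interior columns identical
  expect_equal(paai("MKVLLA", "KVLLA"), 100)
})

test_that("PAAI is symmetric and 100 only for identity", {
  set.seed(53)
  for (rep in 1:5) {
    a <- random_protein_seq(80)
    b <- crude_mutate(a, 0.8)
    expect_equal(paai(a, b), paai(b, a))
    expect_lt(paai(a, b), 100)
  }
})

test_that("the PAAI matrix is symmetric with planted divergences realized", {
  p <- c(a = "MKVLLAGG", b = "MKVLLAGG")
  m <- paai_matrix(p)
  expect_true(all(m == 100))

  set.seed(54)
  base <- random_protein_seq(300)
  prots <- c(x = base, y = crude_mutate(base, 0.9),
             z = crude_mutate(base, 0.4))
  m2 <- paai_matrix(prots)
  expect_equal(m2, t(m2))
  expect_equal(unname(diag(m2)), rep(100, 3))
  expect_equal(m2["x", "y"], 90, tolerance = 0.06)
  expect_lt(m2["x", "z"], 55)
  expect_error(paai_matrix(c(a = "MK", a = "MV")), "duplicate")
})

test_that("threshold clustering is single linkage over the PAAI graph", {
  m <- matrix(90, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_length(cluster_at_threshold(m, 80), 1)

  m2 <- matrix(10, 3, 3, dimnames = dimnames(m)); diag(m2) <- 100
  expect_length(cluster_at_threshold(m2, 80), 3)

  # chain a-b 85, b-c 85, a-c 70: single-linkage transitivity at 80
  m3 <- matrix(c(100, 85, 70, 85, 100, 85, 70, 85, 100), 3, 3,
               dimnames = dimnames(m))
  cl <- cluster_at_threshold(m3, 80)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], c("a", "b", "c"))
})

test_that("species clusters always refine genus clusters", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    m <- matrix(runif(n * n, 0, 100), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 100
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    d <- demarcate(m)
    for (sp in d$species) {
      genus_of <- unique(d$assignments[sp, "genus_id"])
      expect_length(genus_of, 1)  # every species inside a single genus
    }
    # genus partition = components at 50 irrespective of species step
    expect_equal(d$genera, cluster_at_threshold(m, 50))
  }
})

test_that("demarcation recovers planted two-level structure", {
  set.seed(56)
  # two groups: intra ~90 %, inter ~30 % -> 2 genera, each one species
  anc1 <- random_protein_seq(240); anc2 <- random_protein_seq(240)
  prots <- c(a1 = crude_mutate(anc1, 0.95), a2 = crude_mutate(anc1, 0.95),
             b1 = crude_mutate(anc2, 0.95), b2 = crude_mutate(anc2, 0.95))
  d <- demarcate(paai_matrix(prots))
  expect_length(d$genera, 2)
  expect_length(d$species, 2)

  # one genus holding several species plus a singleton species
  g_anc <- random_protein_seq(300)
  sp_anc <- lapply(1:4, function(i) crude_mutate(g_anc, 0.84))
  prots2 <- c(s1a = crude_mutate(sp_anc[[1]], 0.97),
              s1b = crude_mutate(sp_anc[[1]], 0.97),
              s2a = crude_mutate(sp_anc[[2]], 0.97),
              s2b = crude_mutate(sp_anc[[2]], 0.97),
              s3a = crude_mutate(sp_anc[[3]], 0.97),
              s3b = crude_mutate(sp_anc[[3]], 0.97),
              s4a = crude_mutate(sp_anc[[4]], 0.97))
  d2 <- demarcate(paai_matrix(prots2))
  expect_length(d2$genera, 1)
  expect_equal(length(d2$species), 4)
  expect_equal(sort(as.integer(table(d2$assignments$species_id))),
               c(1L, 2L, 2L, 2L))

  expect_error(demarcate(paai_matrix(prots), 80, 50), "species_threshold")
})

test_that("distinct unrelated sequences each found their own taxa", {
  set.seed(57)
  prots <- setNames(replicate(5, random_protein_seq(150)), paste0("u", 1:5))
  d <- demarcate(paai_matrix(prots))
  expect_length(d$genera, 5)
  expect_length(d$species, 5)
  expect_true(all(d$assignments$is_genus_exemplar))
})

test_that("exemplar selection follows the archival priority ladder", {
  members <- c("m1", "m2", "m3")
  meta <- data.frame(id = members,
                     ictv_archived = c(FALSE, TRUE, FALSE),
                     genbank_deposited = c(TRUE, FALSE, TRUE),
                     contig_length = c(4000, 1000, 5000))
  expect_equal(select_exemplar(members, meta), "m2")      # rule (i)
  meta$ictv_archived <- FALSE
  meta$genbank_deposited <- c(FALSE, FALSE, TRUE)
  expect_equal(select_exemplar(members, meta), "m3")      # rule (ii)
  meta$genbank_deposited <- FALSE
  meta$contig_length <- c(1200, 3400, 900)
  expect_equal(select_exemplar(members, meta), "m2")      # rule (iii)
  # ties break by id; missing metadata counts as nothing
  expect_equal(select_exemplar(c("b", "a"), NULL), "a")
})
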