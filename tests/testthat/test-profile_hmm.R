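test_that("build_profile turns alignment columns into match states", {
  h <- build_profile(c(s1 = "MKV"), name = "t")
  expect_equal(h$M, 3)
  # one observation per column dominates after the background pseudocount
  expect_equal(colnames(h$match_emissions)[apply(h$match_emissions, 1,
                                                 which.max)],
               c("M", "K", "V"))

  # duplicated rows renormalise to the same distributions
  h2 <- build_profile(c(a = "MKV", b = "MKV"), name = "t")
  expect_equal(h2$match_emissions, h$match_emissions, tolerance = 1e-12)

  # column census under the 50 % rule: column 2 is gap-majority
  msa <- c(a = "M-V", b = "M-V", c = "MK-")
  h3 <- build_profile(msa, name = "t", match_fraction = 0.5)
  expect_equal(h3$M, 2)  # hand census: cols 1 and 3 qualify, col 2 does not

  expect_error(build_profile(c(a = "--", b = "K-"), match_fraction = 1),
               "match state")
})

test_that("profile normalisation invariants hold on random alignments", {
  set.seed(101)
  for (rep in 1:15) {
    msa <- random_small_msa(sample(2:6, 1), sample(4:12, 1))
    h <- tryCatch(build_profile(msa, name = "r"), error = function(e) NULL)
    if (is.null(h)) next  # all-gap-majority alignments are rejected
    expect_equal(unname(rowSums(h$match_emissions)), rep(1, h$M),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(h$insert_emissions)), rep(1, h$M),
                 tolerance = 1e-9)
    tr <- h$transitions
    expect_equal(unname(tr[, "MM"] + tr[, "MI"] + tr[, "MD"]),
                 rep(1, h$M + 1), tolerance = 1e-9)
    expect_equal(unname(tr[, "IM"] + tr[, "II"]), rep(1, h$M + 1),
                 tolerance = 1e-9)
    expect_equal(unname(tr[, "DM"] + tr[, "DD"]), rep(1, h$M + 1),
                 tolerance = 1e-9)
    expect_true(all(h$background > 0))
  }
})

test_that("build_profile is invariant to row order", {
  set.seed(31)
  msa <- random_small_msa(5, 10, gap_p = 0.15)
  h1 <- build_profile(msa, name = "a")
  h2 <- build_profile(rev(msa), name = "a")
  expect_equal(h1$match_emissions, h2$match_emissions)
  expect_equal(h1$transitions, h2$transitions)
  q <- random_protein_seq(12)
  expect_equal(viterbi_bits(h1, q)$bits, viterbi_bits(h2, q)$bits)
})

test_that("Viterbi and forward match exhaustive path enumeration", {
  set.seed(202)
  for (rep in 1:10) {
    M <- sample(1:3, 1)
    msa <- random_small_msa(sample(1:3, 1), M, gap_p = 0)
    h <- build_profile(msa, name = "tiny")
    for (L in 1:3) {
      q <- random_protein_seq(L)
      oracle <- enumerate_hmm_bits(h, q)
      expect_equal(viterbi_bits(h, q)$bits, oracle$viterbi,
                   tolerance = 1e-9)
      expect_equal(forward_bits(h, q), oracle$forward, tolerance = 1e-9)
    }
  }
  # the M = 1, L = 1 closed case, including an X query
  h1 <- build_profile(c(a = "A"), name = "one")
  o <- enumerate_hmm_bits(h1, "A")
  expect_equal(viterbi_bits(h1, "A")$bits, o$viterbi, tolerance = 1e-12)
  expect_equal(forward_bits(h1, "A"), o$forward, tolerance = 1e-12)
  ox <- enumerate_hmm_bits(h1, "X")
  expect_equal(viterbi_bits(h1, "X")$bits, ox$viterbi, tolerance = 1e-12)
})

test_that("forward dominates Viterbi and scores ignore sequence names", {
  set.seed(77)
  for (rep in 1:8) {
    msa <- random_small_msa(4, sample(5:15, 1), gap_p = 0.1)
    h <- tryCatch(build_profile(msa, name = "r"), error = function(e) NULL)
    if (is.null(h)) next
    q <- random_protein_seq(sample(5:20, 1))
    v <- viterbi_bits(h, q)$bits
    f <- forward_bits(h, q)
    expect_gte(f, v - 1e-12)
  }
  h <- build_profile(c(a = "MKVLLA"), name = "t")
  expect_equal(viterbi_bits(h, list(id = "x", sequence = "MKVLLA"))$bits,
               viterbi_bits(h, list(id = "y", sequence = "MKVLLA"))$bits)
  expect_error(viterbi_bits(h, ""), "empty")
})

test_that("scanning assigns proteins to their source cluster", {
  sim <- simulate_reference_set(2, 1, 2, 1, 2, seed = 5)
  lib <- build_profile_library(sim$msas)
  set.seed(88)
  # a fresh protein at ~95 % identity to a CP cluster member
  cp <- sim$msas[["CP_o1f1"]]
  q <- crude_mutate(cp[[1]], 0.95)
  hits <- scan_proteins(c(query = q), lib)
  best <- hits[hits$best & hits$role == "CP", ]
  expect_equal(nrow(best), 1)
  expect_equal(best$hmm_name, "CP_o1f1")

  # all-X protein passes nothing: background-equal emissions give <= 0 bits
  hx <- scan_proteins(c(x = strrep("X", 100)), lib)
  expect_false(any(hx$passes))

  # empty protein list -> empty table
  he <- scan_proteins(data.frame(id = character(), sequence = character()),
                      lib)
  expect_equal(nrow(he), 0)
})
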