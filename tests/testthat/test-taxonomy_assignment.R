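orf_stub <- function(len) list(length_aa = len)

test_that("coding-completeness thresholds are inclusive minima", {
  cfg <- demarcation_config()
  ok <- check_completeness(list(MP = orf_stub(350), CP = orf_stub(130),
                                RdRP = orf_stub(500)), cfg)
  expect_true(ok$complete)
  expect_length(ok$reasons, 0)

  short_rdrp <- check_completeness(list(MP = orf_stub(350),
                                        CP = orf_stub(130),
                                        RdRP = orf_stub(499)), cfg)
  expect_false(short_rdrp$complete)
  expect_match(short_rdrp$reasons, "RdRP below 500")

  short_mp <- check_completeness(list(MP = orf_stub(349), CP = orf_stub(130),
                                      RdRP = orf_stub(500)), cfg)
  expect_false(short_mp$complete)
  expect_match(short_mp$reasons, "MP below 350")

  no_cp <- check_completeness(list(MP = orf_stub(400), RdRP = orf_stub(520)),
                              cfg)
  expect_false(no_cp$complete)
  expect_match(no_cp$reasons, "CP not found")
})

test_that("RdRP clusters map to their orders", {
  expect_equal(assign_order("RdRP_A"), "Norzivirales")
  expect_equal(assign_order("RdRP_B"), "Timlovirales")
  expect_equal(assign_order(NA), "Unassigned")
  expect_error(assign_order("RdRP_Z"), "absent from the cluster map")
})

test_that("the incongruence rule unassigns both order and family", {
  res <- assign_family("CP_A", "Norzivirales")
  expect_equal(res$family, "Fiersviridae")
  expect_equal(res$order, "Norzivirales")
  expect_false(res$incongruent)

  # Blumeviridae (parent Timlovirales) against a Norzivirales RdRP
  bad <- assign_family("CP_E", "Norzivirales")
  expect_true(bad$incongruent)
  expect_equal(bad$family, "Unassigned")
  expect_equal(bad$order, "Unassigned")

  none <- assign_family(NA, "Norzivirales")
  expect_equal(none$family, "Unassigned")
  expect_equal(none$order, "Norzivirales")
  expect_false(none$incongruent)

  novel <- assign_family("CP_unseen", "Norzivirales")
  expect_equal(novel$family, "Unassigned")
  expect_match(novel$note, "novel family candidate")
})

test_that("random cluster pairs never leak an incongruent rank", {
  map <- default_cluster_taxon_map()
  cp_ids <- map$cluster_id[map$role == "CP"]
  rd_ids <- map$cluster_id[map$role == "RdRP"]
  fam_parent <- setNames(map$parent_order[map$role == "CP"], cp_ids)
  rd_order <- setNames(map$taxon_name[map$role == "RdRP"], rd_ids)
  set.seed(71)
  for (i in 1:200) {
    cp <- sample(cp_ids, 1)
    rd <- sample(rd_ids, 1)
    res <- assign_family(cp, assign_order(rd, map), map)
    if (fam_parent[cp] == rd_order[rd]) {
      expect_false(res$incongruent)
      expect_equal(res$order, rd_order[[rd]])
    } else {
      expect_true(res$incongruent)
      expect_equal(res$family, "Unassigned")
      expect_equal(res$order, "Unassigned")
    }
  }
})

test_that("genus/species adoption follows the PAAI ladder", {
  set.seed(72)
  ref_seq <- random_protein_seq(300)
  reference <- data.frame(id = "r1", sequence = ref_seq,
                          genus_id = "G001", species_id = "G001.S01",
                          stringsAsFactors = FALSE)
  # identical query adopts genus and species
  hit <- assign_genus_species(ref_seq, reference)
  expect_equal(hit$genus_id, "G001")
  expect_equal(hit$species_id, "G001.S01")

  # ~60 % PAAI: same genus, new species
  mid <- assign_genus_species(crude_mutate(ref_seq, 0.62), reference)
  expect_equal(mid$genus_id, "G001")
  expect_match(mid$species_id, "^novel_species_")

  # unrelated: new genus and species
  far <- assign_genus_species(random_protein_seq(300), reference)
  expect_match(far$genus_id, "^novel_genus_")

  # empty reference
  none <- assign_genus_species(ref_seq, NULL)
  expect_match(none$genus_id, "^novel_genus_")
  expect_match(none$species_id, "^novel_species_")
})

test_that("the full classifier recovers planted taxonomy end to end", {
  sim <- simulate_reference_set(2, 1, 2, 2, 2, seed = 19)
  lib <- build_profile_library(sim$msas)
  ref <- sim_reference(sim)
  cfg <- demarcation_config(cluster_taxon_map = sim$map)
  calls <- classify_genomes(sim$genomes, lib, ref, cfg)
  expect_equal(nrow(calls), 16)
  expect_true(all(calls$complete))
  expect_false(any(calls$incongruent))
  expect_equal(calls$order, sim$truth$order)
  expect_equal(calls$family, sim$truth$family)
  # classifying the reference against itself is idempotent
  expect_equal(calls$genus_id, sim$truth$genus_id)
  expect_equal(calls$species_id, sim$truth$species_id)
})

test_that("a genome missing its MP is flagged incomplete but keeps evidence", {
  sim <- simulate_reference_set(1, 1, 1, 1, 2, seed = 23)
  lib <- build_profile_library(sim$msas)
  cfg <- demarcation_config(cluster_taxon_map = sim$map)
  g <- sim$genomes[1, ]
  orfs <- find_orfs(g, min_len_aa = 100)
  mp <- orfs[order(-orfs$length_aa), ][2, ]  # MP is the second-longest ORF
  expect_equal(mp$length_aa, 400)
  g$sequence <- paste0(substr(g$sequence, 1, mp$start),
                       substr(g$sequence, mp$end + 1, nchar(g$sequence)))
  calls <- classify_genomes(g, lib, sim_reference(sim), cfg)
  expect_false(calls$complete)
  expect_match(calls$notes, "MP not found")
  expect_equal(calls$order, sim$truth$order[1])     # evidence retained
  expect_equal(calls$family, sim$truth$family[1])
  expect_true(is.na(calls$genus_id))                # but no demarcation
})

test_that("classification output is byte-identical across runs", {
  sim <- simulate_reference_set(1, 1, 1, 1, 2, seed = 29)
  lib <- build_profile_library(sim$msas)
  cfg <- demarcation_config(cluster_taxon_map = sim$map)
  ref <- sim_reference(sim)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_calls_tsv(classify_genomes(sim$genomes, lib, ref, cfg), f1)
  write_calls_tsv(classify_genomes(sim$genomes, lib, ref, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("relaxing the RdRP length floor never shrinks the complete set", {
  sim <- simulate_reference_set(1, 1, 2, 1, 2, seed = 31)
  lib <- build_profile_library(sim$msas)
  strict <- classify_genomes(sim$genomes, lib, NULL,
                             demarcation_config(min_rdrp_len_aa = 541,
                                                cluster_taxon_map = sim$map))
  relaxed <- classify_genomes(sim$genomes, lib, NULL,
                              demarcation_config(min_rdrp_len_aa = 400,
                                                 cluster_taxon_map = sim$map))
  expect_true(all(strict$genome_id[strict$complete] %in%
                  relaxed$genome_id[relaxed$complete]))
  expect_true(sum(relaxed$complete) >= sum(strict$complete))
})
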