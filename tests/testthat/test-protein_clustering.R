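test_that("similarity graph edges are local-alignment scores", {
  set.seed(21)
  p <- random_protein_seq(100)
  g <- all_vs_all_similarity(c(a = p, b = p, w = strrep("W", 100)))
  self <- biostrings_score(p, p, "local")
  e_ab <- g$edges[g$edges$id_a == "a" & g$edges$id_b == "b", ]
  expect_equal(e_ab$weight, self)   # identical pair = self-alignment score

  # dissimilar homopolymers fall under the noise floor: the best local
  # alignment of AAAA vs WWWW is a single A/W column (BLOSUM62 -3) or empty
  g2 <- all_vs_all_similarity(c(a = "AAAA", b = "AAAA", w = "WWWW"),
                              score_floor = 30)
  expect_false(any((g2$edges$id_a == "w") | (g2$edges$id_b == "w")))

  # two related + one random protein -> exactly one edge above the floor
  set.seed(22)
  base <- random_protein_seq(150)
  rel <- crude_mutate(base, 0.85)
  g3 <- all_vs_all_similarity(c(x = base, y = rel,
                                z = random_protein_seq(60)),
                              score_floor = 60)
  expect_equal(nrow(g3$edges), 1)
  expect_setequal(c(g3$edges$id_a, g3$edges$id_b), c("x", "y"))
})

test_that("local alignment scores agree with the Biostrings oracle", {
  set.seed(23)
  sub <- levitax:::get_substitution_matrix("BLOSUM62")
  for (rep in 1:6) {
    a <- random_protein_seq(sample(30:120, 1))
    b <- random_protein_seq(sample(30:120, 1))
    expect_equal(levitax:::sw_score_cpp(a, b, sub, 11, 1),
                 biostrings_score(a, b, "local"))
  }
})

test_that("MCL separates components and merges cliques", {
  tri <- function(ids) data.frame(
    id_a = ids[c(1, 1, 2)], id_b = ids[c(2, 3, 3)], weight = 1)
  g <- similarity_graph(letters[1:6], rbind(tri(letters[1:3]),
                                            tri(letters[4:6])))
  cs <- mcl(g)
  expect_length(cs$clusters, 2)  # disconnected components never merge
  expect_setequal(cs$clusters[[1]], letters[1:3])

  # complete graph K5 collapses to one cluster
  pairs <- t(combn(letters[1:5], 2))
  k5 <- similarity_graph(letters[1:5],
                         data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                                    weight = 1))
  expect_length(mcl(k5, inflation = 2)$clusters, 1)
  expect_error(mcl(k5, inflation = 1), "inflation")
})

barbell_graph <- function(bridge_weight = 0.1) {
  k4 <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(id_a = p[, 1], id_b = p[, 2], weight = 1)
  }
  nodes <- c(paste0("l", 1:4), paste0("r", 1:4))
  edges <- rbind(k4(nodes[1:4]), k4(nodes[5:8]),
                 data.frame(id_a = "l1", id_b = "r1",
                            weight = bridge_weight))
  similarity_graph(nodes, edges)
}

test_that("MCL splits a weakly bridged barbell, matching an oracle", {
  g <- barbell_graph(0.1)
  cs <- mcl(g, inflation = 4)
  expect_length(cs$clusters, 2)
  expect_setequal(cs$clusters[[1]], paste0("l", 1:4))
  # independent dense-iteration oracle
  adj <- matrix(0, 8, 8, dimnames = list(g$nodes, g$nodes))
  for (i in seq_len(nrow(g$edges))) {
    adj[g$edges$id_a[i], g$edges$id_b[i]] <- g$edges$weight[i]
    adj[g$edges$id_b[i], g$edges$id_a[i]] <- g$edges$weight[i]
  }
  comp <- mcl_oracle(adj, inflation = 4)
  expect_equal(length(unique(comp)), 2)
  expect_equal(rand_index(comp, rep(1:2, each = 4)), 1.0)
})

test_that("more inflation never coarsens the barbell clustering", {
  g <- barbell_graph(0.4)
  n_clusters <- vapply(c(1.3, 2, 4, 6), function(inf)
    length(mcl(g, inflation = inf)$clusters), 0L)
  expect_true(!is.unsorted(n_clusters))
})

test_that("MCL output is a partition, invariant to node permutation", {
  set.seed(33)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    nodes <- paste0("n", sample(100, n))
    p <- t(combn(nodes, 2))
    keep <- runif(nrow(p)) < 0.4
    edges <- data.frame(id_a = p[keep, 1], id_b = p[keep, 2],
                        weight = runif(sum(keep), 0.2, 2))
    g <- similarity_graph(nodes, edges)
    cs <- mcl(g)
    members <- unlist(cs$clusters)
    expect_setequal(members, nodes)          # covering
    expect_equal(anyDuplicated(members), 0L) # disjoint
    expect_true(all(lengths(cs$clusters) > 0))
    # permuting node order changes nothing but ordering
    perm <- sample(n)
    g2 <- similarity_graph(nodes[perm], edges)
    cs2 <- mcl(g2)
    key <- function(cl) sort(vapply(cl, paste, "", collapse = "|"))
    expect_equal(key(lapply(cs$clusters, sort)),
                 key(lapply(cs2$clusters, sort)))
  }
})

test_that("anchor labelling follows the original cluster names", {
  cs <- structure(list(clusters = list(c("p1", "p2"), c("p3", "p4"), "p5"),
                       labels = paste0("cluster_", 1:3)),
                  class = "cluster_set")
  lab <- label_clusters(cs, c(p3 = "CP_C"), role = "CP")
  expect_equal(lab$labels[2], "CP_C")
  expect_equal(lab$labels[c(1, 3)], c("novel_CP_1", "novel_CP_2"))

  none <- label_clusters(cs, role = "MP")
  expect_true(all(grepl("^novel_MP_", none$labels)))

  expect_error(label_clusters(cs, c(p1 = "CP_A", p2 = "CP_B")),
               "conflicting")
  expect_error(label_clusters(cs, c(zz = "CP_A")), "0 clusters")
})

test_that("well-separated protein families are recovered exactly", {
  set.seed(44)
  n_fam <- 3
  members <- 4
  seqs <- character(); truth <- integer()
  for (f in seq_len(n_fam)) {
    anc <- random_protein_seq(200)
    for (m in seq_len(members)) {
      seqs <- c(seqs, crude_mutate(anc, 0.7))
      truth <- c(truth, f)
    }
  }
  names(seqs) <- sprintf("f%d_m%d", truth, seq_along(seqs))
  g <- all_vs_all_similarity(seqs)
  cs <- mcl(g, inflation = 2)
  expect_length(cs$clusters, n_fam)
  got <- integer(length(seqs))
  for (i in seq_along(cs$clusters)) {
    got[match(cs$clusters[[i]], names(seqs))] <- i
  }
  expect_equal(rand_index(got, truth), 1.0)
})
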