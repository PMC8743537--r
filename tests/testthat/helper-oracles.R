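# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ---------------------------------------------------------------------------
# Exhaustive path enumeration for small profile HMMs. Enumerates every legal
# state path (left flank length, core path through the nodes, right flank)
# and returns the max (Viterbi) and log-sum (forward) of per-path log2-odds.
# ---------------------------------------------------------------------------
enumerate_hmm_bits <- function(hmm, protein) {
  q <- strsplit(protein, "")[[1]]
  L <- length(q)
  M <- hmm$M
  lt <- log2(hmm$transitions)
  lbg <- log2(hmm$background)
  lem <- log2(hmm$match_emissions)
  lin <- log2(hmm$insert_emissions)
  emit <- function(tab, k, i) {
    # log2-odds of residue i emitted at node k; X emits background (0 bits)
    if (q[i] == "X") return(0)
    tab[k, q[i]] - lbg[q[i]]
  }
  colnames(lem) <- colnames(lin) <- names(hmm$background)
  scores <- numeric()
  # recursive walk: at `state` of node k, having consumed residues up to pos
  walk <- function(state, k, pos, acc) {
    if (k == M && state %in% c("M", "D")) {
      exit <- if (state == "M") lt[M + 1, "MM"] else lt[M + 1, "DM"]
      scores[length(scores) + 1] <<- acc + exit  # rest of seq = right flank
    }
    if (state == "M" || state == "I") {
      row <- k + 1
      if (state == "M" && k < M) {
        if (pos < L) {
          walk("M", k + 1, pos + 1,
               acc + lt[row, "MM"] + emit(lem, k + 1, pos + 1))
        }
        if (pos < L) {
          walk("I", k, pos + 1, acc + lt[row, "MI"] + emit(lin, k, pos + 1))
        }
        walk("D", k + 1, pos, acc + lt[row, "MD"])
      } else if (state == "I") {
        if (pos < L) {
          walk("I", k, pos + 1, acc + lt[row, "II"] + emit(lin, k, pos + 1))
        }
        if (k < M && pos < L) {
          walk("M", k + 1, pos + 1,
               acc + lt[row, "IM"] + emit(lem, k + 1, pos + 1))
        }
      }
    } else if (state == "D" && k < M) {
      row <- k + 1
      if (pos < L) {
        walk("M", k + 1, pos + 1,
             acc + lt[row, "DM"] + emit(lem, k + 1, pos + 1))
      }
      walk("D", k + 1, pos, acc + lt[row, "DD"])
    }
  }
  for (c0 in 0:L) {
    # enter at M1 (consumes residue c0+1) or D1
    if (c0 < L) {
      walk("M", 1, c0 + 1, lt[1, "MM"] + emit(lem, 1, c0 + 1))
    }
    walk("D", 1, c0, lt[1, "MD"])
  }
  scores <- scores[is.finite(scores)]
  mx <- max(scores)
  list(viterbi = mx, forward = mx + log2(sum(2 ^ (scores - mx))))
}

random_small_msa <- function(n_rows, n_cols, gap_p = 0.2) {
  rows <- replicate(n_rows, {
    chars <- sample(AA20, n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_p
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  })
  names(rows) <- paste0("s", seq_len(n_rows))
  rows
}

random_protein_seq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# ---------------------------------------------------------------------------
# Biostrings is the independent alignment-score oracle (same gap convention:
# a gap of length L costs gapOpening + L * gapExtension).
# ---------------------------------------------------------------------------
biostrings_score <- function(a, b, type) {
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = type, substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

# ---------------------------------------------------------------------------
# Random additive distance matrix from a known random tree.
# ---------------------------------------------------------------------------
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 0.4))
  tree <- ape::unroot(tree)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# Rand index between two partitions given as label vectors over the same ids
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

# ---------------------------------------------------------------------------
# Independent straightforward MCL oracle: dense matrix iteration written
# without the package's pruning/self-loop conventions (unit self-loops).
# ---------------------------------------------------------------------------
mcl_oracle <- function(adj, inflation, iters = 200) {
  diag(adj) <- pmax(diag(adj), 1)
  m <- adj %*% diag(1 / colSums(adj))
  for (i in seq_len(iters)) {
    m <- m %*% m
    m <- m ^ inflation
    m <- m %*% diag(1 / colSums(m))
    m[m < 1e-8] <- 0
    cs <- colSums(m); cs[cs == 0] <- 1
    m <- m %*% diag(1 / cs)
  }
  supp <- (m > 0) | t(m > 0)
  diag(supp) <- TRUE
  # components by BFS
  n <- nrow(supp)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      queue <- v
      while (length(queue) > 0) {
        w <- queue[1]; queue <- queue[-1]
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, which(supp[w, ] & comp == 0L))
        }
      }
    }
  }
  comp
}

# mutate a protein by simple uniform substitution (independent of the
# package's BLOSUM-weighted mutator)
crude_mutate <- function(seq, identity_frac) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) > identity_frac
  chars[hit] <- vapply(chars[hit], function(a)
    sample(setdiff(AA20, a), 1), "")
  paste(chars, collapse = "")
}

# reference set data.frame from a simulate_reference_set() result
sim_reference <- function(sim) {
  rd <- sim$proteins[sim$proteins$role == "RdRP", , drop = FALSE]
  data.frame(
    id = rd$id, sequence = rd$sequence,
    genus_id = sim$truth$genus_id[match(rd$genome_id, sim$truth$id)],
    species_id = sim$truth$species_id[match(rd$genome_id, sim$truth$id)],
    stringsAsFactors = FALSE)
}
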