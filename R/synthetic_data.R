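#' Random protein sequence at background composition
#'
#' @param length_aa Length in residues; the first residue is always `M` so
#'   the back-translated gene carries a canonical start.
#' @param seed Optional RNG seed (`NULL` = use the current stream).
#' @export
random_protein <- function(length_aa, seed = NULL) {
  gen <- function() {
    aa <- sample(AA_ALPHABET, length_aa, replace = TRUE,
                 prob = AA_BACKGROUND)
    aa[1] <- "M"
    paste(aa, collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# cached 20x20 substitution-sampling weights: row a -> P(replacement b),
# b != a, proportional to 2^(BLOSUM62[a,b]/2)
.mutation_weights <- function() {
  if (!is.null(.levitax_env$mutw)) return(.levitax_env$mutw)
  b62 <- get_substitution_matrix("BLOSUM62")[AA_ALPHABET, AA_ALPHABET]
  w <- 2 ^ (b62 / 2)
  diag(w) <- 0
  w <- w / rowSums(w)
  .levitax_env$mutw <- w
  w
}

#' Mutate a protein toward a target identity
#'
#' Substitutes a Bernoulli fraction `1 - target_identity/100` of positions
#' with a different residue drawn by BLOSUM62-weighted sampling; optional
#' single-residue indels. The realised gapless identity to the input is
#' recorded as attribute `realized_identity`.
#'
#' @param seq Protein sequence (string).
#' @param target_identity Target percent identity in (10, 100].
#' @param seed Optional RNG seed (`NULL` = current stream).
#' @param indel_rate Expected indels per position (default 0; at most
#'   ~2 % of length is meaningful).
#' @param keep_first Never mutate the first residue (preserves the start
#'   codon of the back-translated gene).
#' @export
mutate_protein <- function(seq, target_identity, seed = NULL,
                           indel_rate = 0, keep_first = TRUE) {
  if (target_identity <= 10 || target_identity > 100) {
    stop("target_identity must be in (10, 100]")
  }
  run <- function() {
    aa <- strsplit(seq, "")[[1]]
    n <- length(aa)
    p <- 1 - target_identity / 100
    hit <- runif(n) < p
    if (keep_first) hit[1] <- FALSE
    w <- .mutation_weights()
    for (i in which(hit)) {
      a <- aa[i]
      if (a %in% AA_ALPHABET) {
        aa[i] <- sample(AA_ALPHABET, 1, prob = w[a, ])
      }
    }
    if (indel_rate > 0) {
      n_ind <- rbinom(1, n, min(indel_rate, 0.02))
      for (k in seq_len(n_ind)) {
        pos <- sample(2:length(aa), 1)
        if (runif(1) < 0.5 && length(aa) > 2) {
          aa <- aa[-pos]                          # deletion
        } else {
          ins <- sample(AA_ALPHABET, 1, prob = AA_BACKGROUND)
          aa <- append(aa, ins, after = pos - 1)  # insertion
        }
      }
    }
    out <- paste(aa, collapse = "")
    ref <- strsplit(seq, "")[[1]]
    new <- strsplit(out, "")[[1]]
    L <- min(length(ref), length(new))
    attr(out, "realized_identity") <- 100 * mean(ref[1:L] == new[1:L])
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# codons per amino acid under the given table (stops excluded)
.synonymous_codons <- function(table = "11") {
  key <- paste0("syncod_", table)
  if (!is.null(.levitax_env[[key]])) return(.levitax_env[[key]])
  code <- Biostrings::getGeneticCode(table)
  syn <- split(names(code), unname(code))
  .levitax_env[[key]] <- syn
  syn
}

#' Back-translate a protein with uniform synonymous codon choice
#'
#' @param protein Protein string (no stops).
#' @param table Genetic-code table id.
#' @return Nucleotide CDS (no stop codon appended).
#' @export
back_translate <- function(protein, table = "11") {
  syn <- .synonymous_codons(table)
  aa <- strsplit(protein, "")[[1]]
  cods <- vapply(aa, function(a) {
    ch <- syn[[a]]
    if (is.null(ch)) stop("cannot back-translate residue '", a, "'")
    ch[sample.int(length(ch), 1)]
  }, "")
  paste(cods, collapse = "")
}

# spacer providing an in-frame stop immediately before the next gene, so
# planted ORFs cannot extend upstream; C-only elsewhere (no start codons)
.SPACER <- "CCCCCCTAA"
.LEADER <- "CCCCCCCCCTAA"
.TRAILER <- "CCCCCCCCC"

#' Simulate a leviviricete-like reference set with planted taxonomy
#'
#' Generates genomes carrying the MP-CP-RdRP core-gene architecture with a
#' planted taxonomic hierarchy. Per order there is one RdRP cluster and
#' one MP cluster; per family one CP cluster. Cluster ancestor proteins
#' are drawn at background composition (MP ~400 aa, CP ~130 aa, RdRP
#' ~540 aa); genus ancestors are mutated so they are pairwise ~40 %
#' identical within their cluster, species ancestors ~70 % within genus,
#' and members ~90 % within species -- bracketing the 50 %/80 % genus and
#' species thresholds with ~10-point margins. Proteins are back-translated
#' with uniform synonymous codons (code 11) and concatenated MP-CP-RdRP
#' with stop codons and short spacers. Generation asserts the planted
#' margins (inter-genus RdRP identity < 50, within-genus cross-species in
#' (50, 80), within-species > 80) and regenerates up to `max_attempts`
#' times on violation.
#'
#' @param n_orders,families_per_order,genera_per_family,species_per_genus,members_per_species
#'   Counts per rank (all >= 1).
#' @param seed RNG seed; identical seeds give identical output.
#' @param lengths Named list of core-protein lengths in aa
#'   (`MP`, `CP`, `RdRP`).
#' @param max_attempts Regeneration attempts when planted margins fail.
#' @return List with `genomes` (data.frame as [read_fasta()]), `proteins`
#'   (id, sequence, length_aa, role, genome_id), `truth` (per-genome
#'   planted taxonomy), `msas` (per-cluster named alignment vectors),
#'   `map` (synthetic `cluster_taxon_map`), and `params`.
#' @export
simulate_reference_set <- function(n_orders = 2, families_per_order = 3,
                                   genera_per_family = 4,
                                   species_per_genus = 3,
                                   members_per_species = 2,
                                   seed = 1,
                                   lengths = list(MP = 400, CP = 130,
                                                  RdRP = 540),
                                   max_attempts = 5) {
  stopifnot(n_orders >= 1, families_per_order >= 1, genera_per_family >= 1,
            species_per_genus >= 1, members_per_species >= 1)
  # per-branch identities realising the ~40/70/90 pairwise ladder
  branch <- c(genus = 100 * sqrt(0.40), species = 100 * sqrt(0.70),
              member = 100 * sqrt(0.90))
  for (attempt in seq_len(max_attempts)) {
    out <- with_seed(seed + (attempt - 1L) * 1000003L,
                     .simulate_once(n_orders, families_per_order,
                                    genera_per_family, species_per_genus,
                                    members_per_species, lengths, branch))
    if (.margins_ok(out)) {
      out$params <- list(seed = seed, attempt = attempt,
                         n_orders = n_orders,
                         families_per_order = families_per_order,
                         genera_per_family = genera_per_family,
                         species_per_genus = species_per_genus,
                         members_per_species = members_per_species,
                         branch_identity = branch)
      return(out)
    }
  }
  stop("planted identity margins not achieved in ", max_attempts,
       " attempts")
}

.simulate_once <- function(n_orders, nf, ng, ns, nm, lengths, branch) {
  genomes <- list(); proteins <- list(); truth <- list()
  msas <- list(); map_rows <- list()
  for (o in seq_len(n_orders)) {
    order_name <- sprintf("Order_%d", o)
    rdrp_cl <- sprintf("RdRP_o%d", o)
    mp_cl <- sprintf("MP_o%d", o)
    map_rows[[length(map_rows) + 1]] <- data.frame(
      cluster_id = rdrp_cl, role = "RdRP", taxon_rank = "order",
      taxon_name = order_name, parent_order = "", stringsAsFactors = FALSE)
    rdrp_anc <- random_protein(lengths$RdRP)
    mp_anc <- random_protein(lengths$MP)
    for (f in seq_len(nf)) {
      family_name <- sprintf("Family_%d_%d", o, f)
      cp_cl <- sprintf("CP_o%df%d", o, f)
      map_rows[[length(map_rows) + 1]] <- data.frame(
        cluster_id = cp_cl, role = "CP", taxon_rank = "family",
        taxon_name = family_name, parent_order = order_name,
        stringsAsFactors = FALSE)
      cp_anc <- random_protein(lengths$CP)
      for (g in seq_len(ng)) {
        genus_id <- sprintf("g_o%df%d_%02d", o, f, g)
        g_rdrp <- mutate_protein(rdrp_anc, branch["genus"])
        g_mp <- mutate_protein(mp_anc, branch["genus"])
        g_cp <- mutate_protein(cp_anc, branch["genus"])
        for (s in seq_len(ns)) {
          species_id <- sprintf("%s_s%02d", genus_id, s)
          s_rdrp <- mutate_protein(g_rdrp, branch["species"])
          s_mp <- mutate_protein(g_mp, branch["species"])
          s_cp <- mutate_protein(g_cp, branch["species"])
          for (m in seq_len(nm)) {
            gid <- sprintf("lv_o%df%dg%02ds%02dm%d", o, f, g, s, m)
            p_rdrp <- as.character(mutate_protein(s_rdrp, branch["member"]))
            p_mp <- as.character(mutate_protein(s_mp, branch["member"]))
            p_cp <- as.character(mutate_protein(s_cp, branch["member"]))
            genome_seq <- paste0(
              .LEADER, back_translate(p_mp), "TAA",
              .SPACER, back_translate(p_cp), "TAA",
              .SPACER, back_translate(p_rdrp), "TAA", .TRAILER)
            genomes[[gid]] <- data.frame(
              id = gid, description = sprintf("synthetic %s %s",
                                              order_name, species_id),
              sequence = genome_seq, source = "synthetic",
              stringsAsFactors = FALSE)
            for (role in CORE_ROLES) {
              pseq <- switch(role, MP = p_mp, CP = p_cp, RdRP = p_rdrp)
              pid <- paste0(gid, "_", role)
              proteins[[pid]] <- data.frame(
                id = pid, sequence = pseq, length_aa = nchar(pseq),
                role = role, genome_id = gid, stringsAsFactors = FALSE)
              cl <- switch(role, MP = mp_cl, CP = cp_cl, RdRP = rdrp_cl)
              msas[[cl]] <- c(msas[[cl]], setNames(pseq, pid))
            }
            truth[[gid]] <- data.frame(
              id = gid, order = order_name, family = family_name,
              mp_cluster = mp_cl, cp_cluster = cp_cl,
              rdrp_cluster = rdrp_cl, genus_id = genus_id,
              species_id = species_id, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  list(genomes = do.call(rbind, unname(genomes)),
       proteins = do.call(rbind, unname(proteins)),
       truth = do.call(rbind, unname(truth)),
       msas = msas,
       map = validate_cluster_taxon_map(do.call(rbind, map_rows)))
}

# gapless positional identity matrix over equal-length sequences
.positional_identity <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  out <- matrix(100, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- 100 * mean(mat[i, ] == mat[j, ])
      out[i, j] <- v; out[j, i] <- v
    }
  }
  out
}

.margins_ok <- function(out) {
  rdrp <- out$proteins[out$proteins$role == "RdRP", , drop = FALSE]
  if (nrow(rdrp) < 2) return(TRUE)
  pid <- .positional_identity(rdrp$sequence)
  genus <- out$truth$genus_id[match(rdrp$genome_id, out$truth$id)]
  species <- out$truth$species_id[match(rdrp$genome_id, out$truth$id)]
  n <- nrow(rdrp)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pid[i, j]
      if (species[i] == species[j]) {
        if (v <= 80) return(FALSE)
      } else if (genus[i] == genus[j]) {
        if (v <= 50 || v >= 80) return(FALSE)
      } else {
        if (v >= 50) return(FALSE)
      }
    }
  }
  TRUE
}

#' Build a profile library from per-cluster alignments
#'
#' Convenience wrapper around [build_profile()] for the alignment list
#' produced by [simulate_reference_set()] (or any named list of aligned
#' member vectors).
#'
#' @param msas Named list: cluster label -> named character vector of
#'   aligned member sequences.
#' @param ... Passed to [build_profile()].
#' @return List of `profile_hmm`.
#' @export
build_profile_library <- function(msas, ...) {
  lapply(names(msas), function(cl) build_profile(msas[[cl]], name = cl, ...))
}
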