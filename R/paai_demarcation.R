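#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' 11, extend 1 by default). Traceback tie-breaking is deterministic: on
#' equal score a substitution column is preferred over a gap in `a`, which
#' is preferred over a gap in `b`.
#'
#' @param a,b Protein sequences (strings or records with `$sequence`).
#' @param matrix Substitution matrix id.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return List with `score`, `aligned_a`, `aligned_b`, `paai`,
#'   `aligned_cols`, `identical_cols`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  a <- if (is.list(a) || is.data.frame(a)) a$sequence else a
  b <- if (is.list(b) || is.data.frame(b)) b$sequence else b
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  sub <- get_substitution_matrix(matrix)
  nw_align_cpp(toupper(a), toupper(b), sub, gap_open, gap_extend)
}

#' Pairwise amino-acid identity (PAAI)
#'
#' The demarcation statistic: 100 x identical columns / aligned columns of
#' the global alignment, where aligned columns exclude terminal-gap
#' overhangs (so incomplete contig ends are not penalised) but include
#' internal gap columns. Note that this denominator choice can move
#' borderline cluster memberships; it is applied consistently throughout
#' the package.
#'
#' @inheritParams global_align
#' @return PAAI percentage in `[0, 100]`.
#' @export
paai <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  global_align(a, b, matrix, gap_open, gap_extend)$paai
}

#' Full pairwise PAAI matrix
#'
#' @param proteins Protein table (`id`, `sequence`) or named character
#'   vector of at least two sequences.
#' @inheritParams global_align
#' @return Symmetric matrix of PAAI percentages with 100 on the diagonal,
#'   dimnames = protein ids.
#' @export
paai_matrix <- function(proteins, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  if (!is.data.frame(proteins)) {
    proteins <- data.frame(id = names(proteins), sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein id: ",
         proteins$id[duplicated(proteins$id)][1])
  }
  sub <- get_substitution_matrix(matrix)
  m <- paai_matrix_cpp(proteins$sequence, sub, gap_open, gap_extend)
  dimnames(m) <- list(proteins$id, proteins$id)
  m
}

#' Single-linkage clustering of a PAAI matrix at a threshold
#'
#' The partition is the set of connected components of the graph with an
#' edge wherever PAAI >= threshold (inclusive, as the demarcation criteria
#' are stated). Clusters are numbered deterministically by their smallest
#' member id.
#'
#' @param m PAAI matrix (symmetric, ids as dimnames).
#' @param threshold Percentage in (0, 100].
#' @return List of member-id vectors (each sorted), ordered by smallest
#'   member id.
#' @export
cluster_at_threshold <- function(m, threshold) {
  stopifnot(threshold > 0, threshold <= 100)
  ids <- rownames(m)
  adj <- m >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(ids, comp), sort)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1))]
  names(clusters) <- NULL
  clusters
}

#' Select the exemplar sequence of a cluster
#'
#' Exemplars are chosen by decreasing priority: (i) an ICTV-archived
#' virus, (ii) a GenBank-deposited sequence, (iii) otherwise the longest
#' contig. Ties within a tier break by contig length (descending), then
#' lexicographic id. Members without metadata count as neither archived
#' nor deposited, length 0.
#'
#' @param members Member ids of the cluster.
#' @param metadata data.frame with columns `id`, `ictv_archived`,
#'   `genbank_deposited`, `contig_length` (may be `NULL` or partial).
#' @return The exemplar id.
#' @export
select_exemplar <- function(members, metadata = NULL) {
  stopifnot(length(members) >= 1)
  arch <- dep <- setNames(rep(FALSE, length(members)), members)
  len <- setNames(rep(0, length(members)), members)
  if (!is.null(metadata) && nrow(metadata) > 0) {
    i <- match(members, metadata$id)
    ok <- !is.na(i)
    arch[ok] <- isTRUE_vec(metadata$ictv_archived[i[ok]])
    dep[ok] <- isTRUE_vec(metadata$genbank_deposited[i[ok]])
    len[ok] <- ifelse(is.na(metadata$contig_length[i[ok]]), 0,
                      metadata$contig_length[i[ok]])
  }
  tier <- ifelse(arch, 0L, ifelse(dep, 1L, 2L))
  ord <- order(tier, -len, members)
  members[ord[1]]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Demarcate genera and species from a PAAI matrix
#'
#' Genera are single-linkage clusters at `genus_threshold` (default 50 %);
#' species are single-linkage clusters at `species_threshold` (default
#' 80 %) computed within each genus, so every species is nested in exactly
#' one genus by construction. One exemplar is selected per cluster.
#'
#' @param m PAAI matrix.
#' @param genus_threshold,species_threshold Demarcation percentages
#'   (species must be at least the genus threshold).
#' @param metadata Optional exemplar metadata (see [select_exemplar()]).
#' @return Object of class `demarcation`: `genera` and `species` (lists of
#'   member vectors), `assignments` (data.frame `id`, `genus_id`,
#'   `species_id`, `is_genus_exemplar`, `is_species_exemplar`).
#' @export
demarcate <- function(m, genus_threshold = 50, species_threshold = 80,
                      metadata = NULL) {
  if (species_threshold < genus_threshold) {
    stop("species_threshold must be >= genus_threshold")
  }
  ids <- rownames(m)
  genera <- cluster_at_threshold(m, genus_threshold)
  species <- list()
  assignments <- data.frame(id = ids, genus_id = NA_character_,
                            species_id = NA_character_,
                            is_genus_exemplar = FALSE,
                            is_species_exemplar = FALSE,
                            stringsAsFactors = FALSE)
  rownames(assignments) <- ids
  for (gi in seq_along(genera)) {
    g_members <- genera[[gi]]
    g_label <- sprintf("G%03d", gi)
    assignments[g_members, "genus_id"] <- g_label
    assignments[select_exemplar(g_members, metadata),
                "is_genus_exemplar"] <- TRUE
    if (length(g_members) == 1) {
      sp <- list(g_members)
    } else {
      sp <- cluster_at_threshold(m[g_members, g_members, drop = FALSE],
                                 species_threshold)
    }
    for (si in seq_along(sp)) {
      s_label <- sprintf("%s.S%02d", g_label, si)
      assignments[sp[[si]], "species_id"] <- s_label
      assignments[select_exemplar(sp[[si]], metadata),
                  "is_species_exemplar"] <- TRUE
      species[[length(species) + 1]] <- sp[[si]]
    }
  }
  structure(list(genera = genera, species = species,
                 assignments = assignments,
                 genus_threshold = genus_threshold,
                 species_threshold = species_threshold),
            class = "demarcation")
}

#' @export
print.demarcation <- function(x, ...) {
  cat(sprintf(
    "PAAI demarcation: %d genera (>= %g%%), %d species (>= %g%%), %d sequences\n",
    length(x$genera), x$genus_threshold, length(x$species),
    x$species_threshold, nrow(x$assignments)))
  invisible(x)
}

#' Write a demarcation result as TSV
#'
#' @param d A `demarcation`.
#' @param path Output path.
#' @export
write_demarcation_tsv <- function(d, path) {
  utils::write.table(d$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
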