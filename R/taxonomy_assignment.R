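#' Classification configuration
#'
#' Thresholds of the classification ladder: coding-completeness requires
#' all three core proteins with MP >= 350 aa and RdRP >= 500 aa
#' (inclusive); genera and species are demarcated at 50 % and 80 % RdRP
#' PAAI.
#'
#' @param min_mp_len_aa Minimum maturation-protein length (aa).
#' @param min_rdrp_len_aa Minimum polymerase length (aa).
#' @param genus_paai,species_paai PAAI demarcation thresholds (percent).
#' @param min_orf_len_aa Minimum ORF length considered before HMM scanning.
#' @param cluster_taxon_map A `cluster_taxon_map` (default: the packaged
#'   ICTV 2021 map).
#' @return List of class `demarcation_config`.
#' @export
demarcation_config <- function(min_mp_len_aa = 350, min_rdrp_len_aa = 500,
                               genus_paai = 50, species_paai = 80,
                               min_orf_len_aa = 30,
                               cluster_taxon_map = NULL) {
  stopifnot(min_mp_len_aa > 0, min_rdrp_len_aa > 0, genus_paai > 0,
            species_paai >= genus_paai)
  if (is.null(cluster_taxon_map)) {
    cluster_taxon_map <- default_cluster_taxon_map()
  }
  structure(list(min_mp_len_aa = min_mp_len_aa,
                 min_rdrp_len_aa = min_rdrp_len_aa,
                 genus_paai = genus_paai, species_paai = species_paai,
                 min_orf_len_aa = min_orf_len_aa,
                 cluster_taxon_map = cluster_taxon_map),
            class = "demarcation_config")
}

#' Coding-completeness check
#'
#' A genome is coding-complete when MP, CP and RdRP are all found and the
#' MP and RdRP meet their minimum lengths (inclusive).
#'
#' @param role_orfs Named list mapping roles (`MP`, `CP`, `RdRP`) to ORF
#'   rows (anything with a `length_aa` field); absent roles omitted.
#' @param cfg A `demarcation_config`.
#' @return List with `complete` (logical) and `reasons` (character vector
#'   of failed conditions, empty when complete).
#' @export
check_completeness <- function(role_orfs, cfg = demarcation_config()) {
  reasons <- character()
  for (role in CORE_ROLES) {
    if (is.null(role_orfs[[role]])) {
      reasons <- c(reasons, sprintf("%s not found", role))
    }
  }
  if (!is.null(role_orfs$MP) && role_orfs$MP$length_aa < cfg$min_mp_len_aa) {
    reasons <- c(reasons, sprintf("MP below %d aa (%d)",
                                  cfg$min_mp_len_aa, role_orfs$MP$length_aa))
  }
  if (!is.null(role_orfs$RdRP) &&
      role_orfs$RdRP$length_aa < cfg$min_rdrp_len_aa) {
    reasons <- c(reasons, sprintf("RdRP below %d aa (%d)",
                                  cfg$min_rdrp_len_aa,
                                  role_orfs$RdRP$length_aa))
  }
  list(complete = length(reasons) == 0, reasons = reasons)
}

#' Order assignment from the RdRP cluster
#'
#' `RdRP_A` maps to *Norzivirales* and `RdRP_B` to *Timlovirales* in the
#' packaged map; no passing RdRP hit leaves the order `"Unassigned"`.
#'
#' @param rdrp_cluster RdRP cluster label (best passing hit), or `NA`.
#' @param map A `cluster_taxon_map`.
#' @return Order name or `"Unassigned"`.
#' @export
assign_order <- function(rdrp_cluster, map = default_cluster_taxon_map()) {
  if (is.null(rdrp_cluster) || is.na(rdrp_cluster)) return("Unassigned")
  hit <- map[map$cluster_id == rdrp_cluster & map$taxon_rank == "order", ,
             drop = FALSE]
  if (nrow(hit) == 0) {
    stop("RdRP cluster '", rdrp_cluster, "' absent from the cluster map")
  }
  hit$taxon_name[1]
}

#' Family assignment from the CP cluster, with the incongruence rule
#'
#' The CP cluster implies a family whose parent order must agree with the
#' RdRP-derived order. When both are assigned but disagree the genome is
#' incongruent and BOTH order and family are set to `"Unassigned"` (such
#' combinations were left without order or family rank). A missing CP hit
#' leaves the family unassigned but keeps the order; a CP cluster absent
#' from the map is flagged as a novel family candidate.
#'
#' @param cp_cluster CP cluster label or `NA`.
#' @param order_from_rdrp Order name from [assign_order()].
#' @param map A `cluster_taxon_map`.
#' @return List with `family`, `order`, `incongruent`, `note`.
#' @export
assign_family <- function(cp_cluster, order_from_rdrp,
                          map = default_cluster_taxon_map()) {
  if (is.null(cp_cluster) || is.na(cp_cluster)) {
    return(list(family = "Unassigned", order = order_from_rdrp,
                incongruent = FALSE, note = ""))
  }
  hit <- map[map$cluster_id == cp_cluster & map$taxon_rank == "family", ,
             drop = FALSE]
  if (nrow(hit) == 0) {
    return(list(family = "Unassigned", order = order_from_rdrp,
                incongruent = FALSE,
                note = sprintf("novel family candidate (CP cluster %s unmapped)",
                               cp_cluster)))
  }
  family <- hit$taxon_name[1]
  parent <- hit$parent_order[1]
  if (!is.na(order_from_rdrp) && order_from_rdrp != "Unassigned" &&
      parent != order_from_rdrp) {
    return(list(family = "Unassigned", order = "Unassigned",
                incongruent = TRUE,
                note = sprintf(
                  "CP cluster %s (family %s, order %s) conflicts with RdRP order %s",
                  cp_cluster, family, parent, order_from_rdrp)))
  }
  list(family = family,
       order = if (order_from_rdrp == "Unassigned") parent else
         order_from_rdrp,
       incongruent = FALSE, note = "")
}

#' Genus and species adoption against a demarcated reference set
#'
#' The query polymerase is compared (PAAI) with every reference RdRP. If
#' the best match reaches the genus threshold the query adopts that
#' member's genus; within the adopted genus, a match at the species
#' threshold adopts that member's species, otherwise the query founds a
#' new species in the genus. With no match at the genus threshold the
#' query founds a new genus and species (labels `novel_genus_<k>` /
#' `novel_species_<k>`, numbered deterministically per run).
#'
#' @param query_rdrp Query polymerase sequence.
#' @param reference data.frame with `id`, `sequence`, `genus_id`,
#'   `species_id` (may be empty or `NULL`).
#' @param cfg A `demarcation_config`.
#' @param novel_counter Integer; the next free index for novel labels.
#' @return List `genus_id`, `species_id`, `novel_genus`, `novel_species`,
#'   `best_paai`, `novel_counter`.
#' @export
assign_genus_species <- function(query_rdrp, reference,
                                 cfg = demarcation_config(),
                                 novel_counter = 1L) {
  if (is.null(reference) || nrow(reference) == 0) {
    return(list(genus_id = sprintf("novel_genus_%d", novel_counter),
                species_id = sprintf("novel_species_%d", novel_counter),
                novel_genus = TRUE, novel_species = TRUE,
                best_paai = NA_real_,
                novel_counter = novel_counter + 1L))
  }
  sub <- get_substitution_matrix("BLOSUM62")
  pa <- paai_vec_cpp(toupper(query_rdrp), reference$sequence, sub, 11, 1)
  best <- which.max(pa)
  if (pa[best] < cfg$genus_paai) {
    return(list(genus_id = sprintf("novel_genus_%d", novel_counter),
                species_id = sprintf("novel_species_%d", novel_counter),
                novel_genus = TRUE, novel_species = TRUE,
                best_paai = pa[best],
                novel_counter = novel_counter + 1L))
  }
  genus <- reference$genus_id[best]
  in_genus <- reference$genus_id == genus
  pa_g <- pa[in_genus]
  best_g <- which.max(pa_g)
  if (pa_g[best_g] >= cfg$species_paai) {
    list(genus_id = genus, species_id = reference$species_id[in_genus][best_g],
         novel_genus = FALSE, novel_species = FALSE, best_paai = pa[best],
         novel_counter = novel_counter)
  } else {
    out <- list(genus_id = genus,
                species_id = sprintf("novel_species_%d", novel_counter),
                novel_genus = FALSE, novel_species = TRUE,
                best_paai = pa[best], novel_counter = novel_counter + 1L)
    out
  }
}

# best passing ORF per role: highest bit score, ties by longer ORF then
# smaller start coordinate
.best_role_orfs <- function(orfs, hits) {
  best <- list()
  pass <- hits[hits$passes & !is.na(hits$role), , drop = FALSE]
  if (nrow(pass) == 0) return(best)
  pass <- merge(pass, orfs[, c("orf_id", "start", "length_aa")],
                by.x = "protein_id", by.y = "orf_id")
  for (role in unique(pass$role)) {
    h <- pass[pass$role == role, , drop = FALSE]
    h <- h[order(-h$bit_score, -h$length_aa, h$start), , drop = FALSE]
    o <- orfs[orfs$orf_id == h$protein_id[1], , drop = FALSE]
    best[[role]] <- list(orf_id = o$orf_id, length_aa = o$length_aa,
                         protein = o$protein, start = o$start,
                         cluster = h$hmm_name[1], bit_score = h$bit_score[1])
  }
  best
}

#' End-to-end classification of genomes
#'
#' For each genome: ORF calling, HMM scan against the profile library,
#' role assignment by best passing hit, coding-completeness filter, order
#' from the RdRP cluster, family from the CP cluster with the incongruence
#' rule, and (for coding-complete genomes with an assigned order) genus
#' and species adoption against the reference set. Per-genome failures are
#' recorded in the call, never fatal.
#'
#' @param genomes Genome table from [read_fasta()] (or
#'   [simulate_reference_set()]).
#' @param library List of `profile_hmm` objects covering the three roles.
#' @param reference Optional demarcated reference set: data.frame `id`,
#'   `sequence` (RdRP), `genus_id`, `species_id`.
#' @param cfg A `demarcation_config`.
#' @return data.frame of class `levitax_calls`, one row per genome:
#'   `genome_id`, `complete`, `mp_len`, `cp_len`, `rdrp_len`,
#'   `rdrp_cluster`, `cp_cluster`, `order`, `family`, `genus_id`,
#'   `species_id`, `incongruent`, `notes`.
#' @export
classify_genomes <- function(genomes, library, reference = NULL,
                             cfg = demarcation_config()) {
  roles <- unique(stats::na.omit(vapply(library, function(h)
    hmm_role(h$name), "")))
  if (!all(CORE_ROLES %in% roles)) {
    stop("profile library must cover MP, CP and RdRP (has: ",
         paste(roles, collapse = ", "), ")")
  }
  map <- cfg$cluster_taxon_map
  novel_counter <- 1L
  all_orfs <- find_orfs_all(genomes, min_len_aa = cfg$min_orf_len_aa)
  all_hits <- if (!is.null(all_orfs) && nrow(all_orfs) > 0) {
    scan_proteins(
      data.frame(id = all_orfs$orf_id, sequence = all_orfs$protein,
                 stringsAsFactors = FALSE), library)
  } else NULL
  rows <- vector("list", nrow(genomes))
  for (i in seq_len(nrow(genomes))) {
    g <- genomes[i, ]
    orfs <- all_orfs[all_orfs$genome_id == g$id, , drop = FALSE]
    notes <- character()
    if (is.null(orfs) || nrow(orfs) == 0) {
      best <- list()
      notes <- c(notes, "no ORFs found")
    } else {
      hits <- all_hits[all_hits$protein_id %in% orfs$orf_id, , drop = FALSE]
      best <- .best_role_orfs(orfs, hits)
    }
    comp <- check_completeness(best, cfg)
    if (!comp$complete) notes <- c(notes, comp$reasons)
    order_name <- tryCatch(
      assign_order(best$RdRP$cluster %||% NA_character_, map),
      error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        "Unassigned"
      })
    fam <- assign_family(best$CP$cluster %||% NA_character_, order_name, map)
    if (nzchar(fam$note)) notes <- c(notes, fam$note)
    genus_id <- NA_character_; species_id <- NA_character_
    if (comp$complete && fam$order != "Unassigned") {
      gs <- assign_genus_species(best$RdRP$protein, reference, cfg,
                                 novel_counter)
      novel_counter <- gs$novel_counter
      genus_id <- gs$genus_id
      species_id <- gs$species_id
      if (isTRUE(gs$novel_genus)) notes <- c(notes, "novel genus")
      else if (isTRUE(gs$novel_species)) notes <- c(notes, "novel species")
    }
    rows[[i]] <- data.frame(
      genome_id = g$id, complete = comp$complete,
      mp_len = best$MP$length_aa %||% NA_integer_,
      cp_len = best$CP$length_aa %||% NA_integer_,
      rdrp_len = best$RdRP$length_aa %||% NA_integer_,
      rdrp_cluster = best$RdRP$cluster %||% NA_character_,
      cp_cluster = best$CP$cluster %||% NA_character_,
      order = fam$order, family = fam$family,
      genus_id = genus_id, species_id = species_id,
      incongruent = fam$incongruent,
      notes = paste(notes, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    calls <- data.frame(genome_id = character(), complete = logical(),
                        mp_len = integer(), cp_len = integer(),
                        rdrp_len = integer(), rdrp_cluster = character(),
                        cp_cluster = character(), order = character(),
                        family = character(), genus_id = character(),
                        species_id = character(), incongruent = logical(),
                        notes = character(), stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  class(calls) <- c("levitax_calls", "data.frame")
  calls
}

#' @export
print.levitax_calls <- function(x, ...) {
  cat(sprintf("levitax calls: %d genomes, %d coding-complete, %d incongruent\n",
              nrow(x), sum(x$complete), sum(x$incongruent)))
  print.data.frame(head(as.data.frame(x)[, c("genome_id", "complete",
                                             "order", "family", "genus_id",
                                             "species_id")], 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
summary.levitax_calls <- function(object, ...) {
  cat(sprintf("genomes: %d\ncoding-complete: %d\nincongruent: %d\n",
              nrow(object), sum(object$complete), sum(object$incongruent)))
  cat("\nby order:\n")
  print(table(object$order))
  cat("\nby family:\n")
  print(table(object$family))
  invisible(object)
}

#' Write taxonomy calls as a deterministic TSV
#'
#' @param calls A `levitax_calls` table.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
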