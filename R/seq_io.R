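#' Read a FASTA file into a sequence record table
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file. Nucleotide
#' sequences are uppercased and U is normalised to T on ingest, so RNA-virus
#' genomes and DNA-alphabet database deposits are handled identically;
#' protein sequences may use the 20 amino-acid letters plus `X`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param source Provenance tag stored with nucleotide records
#'   (`"user"`, `"synthetic"` or `"external"`).
#' @return A `data.frame` with columns `id`, `description`, `sequence` and,
#'   for nucleotide input, `source`; for protein input, `length_aa`.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein"),
                       source = "user") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (any(!nzchar(seqs))) {
    stop("record with empty sequence: ", ids[!nzchar(seqs)][1])
  }
  if (alphabet == "nucleotide") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    bad <- regexpr(sprintf("[^%s]", paste(NT_ALPHABET, collapse = "")), seqs)
  } else {
    bad <- regexpr(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), seqs)
  }
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                 alphabet, substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (alphabet == "nucleotide") {
    data.frame(id = ids, description = desc, sequence = seqs,
               source = source, stringsAsFactors = FALSE)
  } else {
    data.frame(id = ids, description = desc, sequence = seqs,
               length_aa = nchar(seqs), stringsAsFactors = FALSE)
  }
}

#' Write sequences to a FASTA file
#'
#' @param records A data.frame with `id` and `sequence` columns (as produced
#'   by [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line-wrapping width.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$sequence, records$id)
  } else {
    seqs <- records
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write open reading frames as GFF3
#'
#' Internal coordinates are 0-based half-open on the forward strand; GFF3
#' output is 1-based inclusive, feature type `CDS`.
#'
#' @param orfs ORF table from [find_orfs()].
#' @param path Output path.
#' @param genome_lengths Optional named vector of genome lengths (nt); when
#'   supplied, ORFs extending beyond their genome raise an error.
#' @export
write_gff3 <- function(orfs, path, genome_lengths = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(orfs) && nrow(orfs) > 0) {
    if (!is.null(genome_lengths)) {
      glen <- genome_lengths[orfs$genome_id]
      over <- which(!is.na(glen) & orfs$end > glen)
      if (length(over) > 0) {
        stop(sprintf("ORF %s ends at %d beyond genome %s length %d",
                     orfs$orf_id[over[1]], orfs$end[over[1]],
                     orfs$genome_id[over[1]], glen[over[1]]))
      }
    }
    role <- if ("role" %in% names(orfs)) orfs$role else rep(NA, nrow(orfs))
    attrs <- ifelse(is.na(role) | !nzchar(ifelse(is.na(role), "", role)),
                    sprintf("ID=%s", orfs$orf_id),
                    sprintf("ID=%s;role=%s", orfs$orf_id, role))
    lines <- c(lines, sprintf("%s\tlevitax\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              orfs$genome_id, orfs$start + 1L, orfs$end,
                              orfs$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a cluster-to-taxon mapping table
#'
#' The map links protein-cluster labels to taxa: each RdRP cluster to an
#' order and each CP cluster to a family (with its parent order). The
#' packaged default encodes the ICTV 2021 scheme: CP clusters C,
#' AP205-like, \{A, B, H\} and G map to *Atkinsviridae*, *Duinviridae*,
#' *Fiersviridae* and *Solspiviridae* within *Norzivirales*; E and
#' \{D, F\} map to *Blumeviridae* and *Steitzviridae* within *Timlovirales*;
#' RdRP_A and RdRP_B map to the two orders.
#'
#' @param path Path to a tab-separated file with columns `cluster_id`,
#'   `role`, `taxon_rank`, `taxon_name`, `parent_order`. Defaults to the
#'   packaged map.
#' @return A validated `data.frame` of class `cluster_taxon_map`.
#' @export
read_cluster_taxon_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cluster_taxon_map.tsv",
                        package = "levitax", mustWork = TRUE)
  }
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_cluster_taxon_map(map)
}

#' @rdname read_cluster_taxon_map
#' @export
default_cluster_taxon_map <- function() read_cluster_taxon_map(NULL)

#' Validate an in-memory cluster-to-taxon map
#'
#' @param map A data.frame with the columns of a cluster-taxon map.
#' @export
validate_cluster_taxon_map <- function(map) {
  need <- c("cluster_id", "role", "taxon_rank", "taxon_name", "parent_order")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0) {
    stop("cluster-taxon map missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(map$role %in% c("MP", "CP", "RdRP"))) {
    stop("cluster-taxon map role must be one of MP, CP, RdRP")
  }
  if (!all(map$taxon_rank %in% c("order", "family"))) {
    stop("cluster-taxon map taxon_rank must be order or family")
  }
  cp <- map[map$role == "CP", , drop = FALSE]
  if (anyDuplicated(cp$cluster_id)) {
    stop("CP cluster mapped to two families: ",
         cp$cluster_id[duplicated(cp$cluster_id)][1])
  }
  rd <- map[map$role == "RdRP", , drop = FALSE]
  if (anyDuplicated(rd$cluster_id)) {
    stop("RdRP cluster mapped to two orders: ",
         rd$cluster_id[duplicated(rd$cluster_id)][1])
  }
  orders <- map$taxon_name[map$taxon_rank == "order"]
  fam <- map[map$taxon_rank == "family", , drop = FALSE]
  bad <- setdiff(fam$parent_order, orders)
  if (length(bad) > 0) {
    stop("family with unknown parent order: ", paste(bad, collapse = ", "))
  }
  class(map) <- c("cluster_taxon_map", "data.frame")
  map
}

#' Look up the taxon for a cluster label
#'
#' @param map A `cluster_taxon_map`.
#' @param cluster_id Cluster label, e.g. `"CP_A"` or `"RdRP_B"`.
#' @return One-row data.frame, or `NULL` when the label is not in the map.
#' @export
lookup_cluster <- function(map, cluster_id) {
  hit <- map[map$cluster_id == cluster_id, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit[1, , drop = FALSE]
}
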