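#' Translate a nucleotide sequence
#'
#' Standard codon translation under a numbered genetic-code table (default
#' 11, bacterial). Stop codons are rendered as `*`; codons containing `N`
#' (or any other ambiguity) translate to `X`.
#'
#' @param nt Nucleotide string; length must be divisible by 3.
#' @param table Genetic-code table id (passed to
#'   [Biostrings::getGeneticCode()]).
#' @return The translated protein string.
#' @export
translate_nt <- function(nt, table = "11") {
  nt <- toupper(gsub("U", "T", nt, fixed = TRUE))
  n <- nchar(nt)
  if (n %% 3 != 0) {
    stop("sequence length ", n, " is not divisible by 3")
  }
  if (n == 0) return("")
  code <- Biostrings::getGeneticCode(table)
  codons <- substring(nt, seq(1, n, by = 3), seq(3, n, by = 3))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

reverse_complement <- function(nt) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

# Scan one linear sequence (already oriented in reading direction) for
# maximal start..stop ORFs in its three frames. Returns local 0-based
# half-open coordinates on the scanned strand.
.scan_orfs_one_strand <- function(seq, min_len_aa, starts, code) {
  n <- nchar(seq)
  out <- list()
  stops <- names(code)[code == "*"]
  for (frame in 0:2) {
    last <- frame + 3 * ((n - frame) %/% 3)
    if (last - frame < 3) next
    cod_start <- seq.int(frame + 1, last - 2, by = 3)
    codons <- substring(seq, cod_start, cod_start + 2)
    is_stop <- codons %in% stops
    is_start <- codons %in% starts
    # segments between stops (stop codon closes the segment)
    seg_begin <- 1L
    k <- length(codons)
    boundaries <- c(which(is_stop), NA)  # NA marks the run-off segment
    for (b in boundaries) {
      seg_end <- if (is.na(b)) k else b  # index of stop codon, or k (no stop)
      lim <- if (is.na(b)) k else b - 1L
      if (lim >= seg_begin) {
        s_idx <- which(is_start[seg_begin:lim])
        if (length(s_idx) > 0) {
          first_start <- seg_begin + s_idx[1] - 1L
          has_stop <- !is.na(b)
          aa_len <- (if (has_stop) b - first_start else k - first_start + 1L)
          if (aa_len >= min_len_aa) {
            s0 <- cod_start[first_start] - 1L        # 0-based
            e0 <- if (has_stop) cod_start[b] + 2L else cod_start[k] + 2L
            out[[length(out) + 1]] <- list(start = s0, end = e0,
                                           frame = frame,
                                           has_stop = has_stop)
          }
        }
      }
      if (is.na(b)) break
      seg_begin <- b + 1L
    }
  }
  out
}

#' Find open reading frames on a genome
#'
#' Reports every maximal start-to-stop ORF whose protein is at least
#' `min_len_aa` residues, in all three frames and (by default) on both
#' strands -- metatranscriptomic contigs are frequently assembled in reverse
#' orientation. Reverse-strand coordinates are projected onto the forward
#' strand; internally all coordinates are 0-based half-open. ORFs running
#' off the contig end without an in-frame stop are reported with
#' `has_stop = FALSE` so that truncated polymerases remain visible (the
#' length filters applied later guard completeness).
#'
#' @param genome One genome: a single-row data.frame from [read_fasta()], or
#'   a list/vector with `id` and `sequence`.
#' @param min_len_aa Minimum protein length in residues (default 30).
#' @param starts Start codons (default `ATG`, `GTG`, `TTG` -- leviviricete
#'   genes use alternative starts).
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @param table Genetic-code table id for translation.
#' @return A data.frame with columns `genome_id`, `orf_id`, `start`, `end`
#'   (0-based half-open, forward strand), `strand`, `frame`, `protein`,
#'   `length_aa`, `has_stop`, sorted by ascending `start`.
#' @export
find_orfs <- function(genome, min_len_aa = 30, starts = c("ATG", "GTG", "TTG"),
                      both_strands = TRUE, table = "11") {
  if (is.data.frame(genome)) genome <- as.list(genome[1, ])
  seq <- toupper(gsub("U", "T", genome$sequence, fixed = TRUE))
  if (!nzchar(seq)) stop("empty genome sequence")
  stopifnot(min_len_aa >= 1)
  code <- Biostrings::getGeneticCode(table)
  n <- nchar(seq)
  hits <- .scan_orfs_one_strand(seq, min_len_aa, starts, code)
  rows <- lapply(hits, function(h) {
    data.frame(start = h$start, end = h$end, strand = "+", frame = h$frame,
               has_stop = h$has_stop, stringsAsFactors = FALSE)
  })
  if (both_strands) {
    rc <- reverse_complement(seq)
    hits_rc <- .scan_orfs_one_strand(rc, min_len_aa, starts, code)
    rows <- c(rows, lapply(hits_rc, function(h) {
      # project [s, e) on the reverse complement back to forward coords
      data.frame(start = n - h$end, end = n - h$start, strand = "-",
                 frame = h$frame, has_stop = h$has_stop,
                 stringsAsFactors = FALSE)
    }))
  }
  if (length(rows) == 0) {
    return(data.frame(genome_id = character(), orf_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      protein = character(), length_aa = integer(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  ord <- order(orfs$start, orfs$end, orfs$strand, orfs$frame)
  orfs <- orfs[ord, , drop = FALSE]
  orfs$genome_id <- genome$id
  prot <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    sub <- substr(seq, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] == "-") sub <- reverse_complement(sub)
    p <- translate_nt(sub, table)
    prot[i] <- sub("\\*$", "", p)
  }
  orfs$protein <- prot
  orfs$length_aa <- nchar(prot)
  orfs$orf_id <- sprintf("%s_orf%02d", genome$id, seq_len(nrow(orfs)))
  rownames(orfs) <- NULL
  orfs[, c("genome_id", "orf_id", "start", "end", "strand", "frame",
           "protein", "length_aa", "has_stop")]
}

#' Find ORFs across a collection of genomes
#'
#' @param genomes Genome table from [read_fasta()].
#' @inheritParams find_orfs
#' @export
find_orfs_all <- function(genomes, min_len_aa = 30,
                          starts = c("ATG", "GTG", "TTG"),
                          both_strands = TRUE, table = "11") {
  res <- lapply(seq_len(nrow(genomes)), function(i) {
    find_orfs(genomes[i, ], min_len_aa = min_len_aa, starts = starts,
              both_strands = both_strands, table = table)
  })
  do.call(rbind, res)
}
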