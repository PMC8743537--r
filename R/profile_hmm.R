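#' Construct a protein multiple alignment object
#'
#' @param aligned Named character vector of equal-length aligned rows
#'   (gap character `-`).
#' @return An object of class `protein_msa`.
#' @export
protein_msa <- function(aligned) {
  if (length(aligned) < 1) stop("alignment needs at least one row")
  if (is.null(names(aligned)) || any(!nzchar(names(aligned)))) {
    stop("alignment rows must be named with member ids")
  }
  w <- unique(nchar(aligned))
  if (length(w) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  if (all(colSums(mat != "-") == 0)) stop("alignment has no non-gap column")
  structure(list(ids = names(aligned), rows = unname(toupper(aligned)),
                 ncol = w), class = "protein_msa")
}

# transition column order used throughout (matches the HMMER3 node table)
HMM_TRANS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Build a profile HMM from a multiple alignment
#'
#' Plan7-style architecture: alignment columns whose non-gap fraction is at
#' least `match_fraction` become match states; the rest are insert columns.
#' Match emissions are weighted residue counts plus
#' `pseudocount_weight * background`, normalised; insert states emit the
#' background distribution. Transition probabilities are estimated from the
#' per-sequence gap patterns with Laplace (+1) smoothing per outgoing group.
#' Sequence weights are uniform.
#'
#' @param msa A [protein_msa()] (or named character vector of aligned rows).
#' @param name Profile name; the protein role (MP/CP/RdRP) is derived from
#'   its prefix by [hmm_role()].
#' @param match_fraction Minimum non-gap column fraction for a match state.
#' @param pseudocount_weight Weight of the background pseudocount added to
#'   the observed match-emission counts.
#' @param score_threshold_bits Acceptance bit-score cutoff stored with the
#'   profile (default 25).
#' @return An object of class `profile_hmm` with fields `name`, `M`,
#'   `match_emissions` (M x 20), `insert_emissions`, `transitions`
#'   ((M+1) x 7, rows = nodes 0..M), `background`, `score_threshold_bits`.
#' @export
build_profile <- function(msa, name = "profile", match_fraction = 0.5,
                          pseudocount_weight = 1.0,
                          score_threshold_bits = 25) {
  if (!inherits(msa, "protein_msa")) msa <- protein_msa(msa)
  stopifnot(match_fraction > 0, match_fraction <= 1, pseudocount_weight > 0)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  nongap_frac <- colMeans(mat != "-")
  is_match <- nongap_frac >= match_fraction
  M <- sum(is_match)
  if (M == 0) {
    stop("no column qualifies as a match state at match_fraction = ",
         match_fraction)
  }
  bg <- AA_BACKGROUND
  # match emissions
  em <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  mcols <- which(is_match)
  for (k in seq_len(M)) {
    col <- mat[, mcols[k]]
    col <- col[col %in% AA_ALPHABET]   # gaps and X carry no count
    if (length(col) > 0) {
      tab <- table(factor(col, levels = AA_ALPHABET))
      em[k, ] <- as.numeric(tab)
    }
  }
  # pseudocounts act on observed frequencies (not raw counts), so the
  # emission profile is invariant to duplicating alignment rows
  tot <- rowSums(em)
  em[tot > 0, ] <- em[tot > 0, , drop = FALSE] / tot[tot > 0]
  if (any(tot == 0)) {
    em[tot == 0, ] <- matrix(bg, nrow = sum(tot == 0), ncol = 20,
                             byrow = TRUE)
  }
  em <- em + pseudocount_weight * matrix(bg, nrow = M, ncol = 20, byrow = TRUE)
  em <- em / rowSums(em)
  ins <- matrix(bg, nrow = M, ncol = 20, byrow = TRUE,
                dimnames = list(NULL, AA_ALPHABET))
  # transition counts from per-sequence state paths
  cnt <- matrix(0, nrow = M + 1, ncol = 7, dimnames = list(NULL, HMM_TRANS))
  col_node <- cumsum(is_match)          # node owning each column's M/D state
  bump <- function(node, move) {
    # Plan7 has no I->D or D->I moves; such gap patterns carry no count
    if (move %in% HMM_TRANS) cnt[node + 1L, move] <<- cnt[node + 1L, move] + 1
  }
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    state <- "M"; node <- 0L            # node 0 = begin
    for (c in seq_len(ncol(mat))) {
      if (is_match[c]) {
        nxt <- if (row[c] == "-") "D" else "M"
        bump(node, paste0(state, nxt))
        state <- nxt
        node <- col_node[c]
      } else if (row[c] != "-") {       # insert residue at current node
        bump(node, paste0(state, "I"))
        state <- "I"
      }
    }
    # exit to E counted as a final M-type move out of the last node
    bump(node, paste0(state, "M"))
  }
  # Laplace smoothing and normalisation per outgoing group
  tr <- matrix(0, nrow = M + 1, ncol = 7, dimnames = list(NULL, HMM_TRANS))
  for (k in seq_len(M + 1)) {
    if (k == M + 1) {
      # node M: exits are forced (M->E, D->E); no inserts after last match
      tr[k, ] <- c(1, 0, 0, 1, 0, 1, 0)
    } else if (k == 1) {
      g <- cnt[1, c("MM", "MD")] + 1    # begin: B->M1 / B->D1 only
      tr[1, c("MM", "MD")] <- g / sum(g)
      tr[1, c("MI")] <- 0
      gi <- cnt[1, c("IM", "II")] + 1
      tr[1, c("IM", "II")] <- gi / sum(gi)
      tr[1, c("DM", "DD")] <- c(1, 0)
    } else {
      g <- cnt[k, c("MM", "MI", "MD")] + 1
      tr[k, c("MM", "MI", "MD")] <- g / sum(g)
      gi <- cnt[k, c("IM", "II")] + 1
      tr[k, c("IM", "II")] <- gi / sum(gi)
      gd <- cnt[k, c("DM", "DD")] + 1
      tr[k, c("DM", "DD")] <- gd / sum(gd)
    }
  }
  structure(list(name = name, M = M, match_emissions = em,
                 insert_emissions = ins, transitions = tr,
                 background = bg,
                 score_threshold_bits = score_threshold_bits),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM '%s': %d match states, threshold %.1f bits\n",
              x$name, x$M, x$score_threshold_bits))
  invisible(x)
}

#' Role (MP/CP/RdRP) implied by a profile name
#'
#' Cluster labels follow the `<role>_<letter>` convention (`CP_A`,
#' `RdRP_B`, `MP_1`, `novel_CP_3`); `AP205-like` is the one CP cluster the
#' original description never lettered.
#' @param name Profile/cluster name.
#' @return `"MP"`, `"CP"`, `"RdRP"` or `NA`.
#' @export
hmm_role <- function(name) {
  ifelse(grepl("(^|_)RdRP([_-]|$)", name), "RdRP",
  ifelse(grepl("(^|_)CP([_-]|$)", name), "CP",
  ifelse(grepl("(^|_)MP([_-]|$)", name), "MP",
  ifelse(name == "AP205-like", "CP", NA_character_))))
}

.validate_hmm <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"), hmm$M >= 1)
  if (any(abs(rowSums(hmm$match_emissions) - 1) > 1e-6)) {
    stop("match emissions do not normalise")
  }
  invisible(hmm)
}

.query_indices <- function(protein) {
  if (is.list(protein) || is.data.frame(protein)) protein <- protein$sequence
  if (!nzchar(protein)) stop("empty protein sequence")
  chars <- strsplit(toupper(protein), "")[[1]]
  idx <- match(chars, AA_ALPHABET) - 1L
  idx[is.na(idx)] <- -1L               # X (or unknown) emits background
  idx
}

.log2_safe <- function(p) ifelse(p > 0, log2(p), -Inf)

.hmm_log_parts <- function(hmm) {
  lbg <- log2(hmm$background)
  list(lm = sweep(.log2_safe(hmm$match_emissions), 2, lbg),
       li = sweep(.log2_safe(hmm$insert_emissions), 2, lbg),
       lt = .log2_safe(hmm$transitions))
}

#' Viterbi bit score of a protein against a profile
#'
#' Score of the best path, in bits:
#' `log2(P(path, seq | hmm) / P(seq | background))`. Alignment is global in
#' the model and local in the sequence: flanking residues are emitted at
#' background frequency and contribute zero bits.
#'
#' @param hmm A `profile_hmm`.
#' @param protein Protein sequence (string, or record with `$sequence`).
#' @param want_path Also return the optimal core state path (e.g. `"M1"`,
#'   `"I1"`, `"D2"`).
#' @return List with `bits` and, when requested, `path`.
#' @export
viterbi_bits <- function(hmm, protein, want_path = TRUE) {
  .validate_hmm(hmm)
  parts <- .hmm_log_parts(hmm)
  res <- hmm_viterbi_cpp(parts$lm, parts$li, parts$lt,
                         .query_indices(protein), want_path)
  res
}

#' Forward bit score of a protein against a profile
#'
#' As [viterbi_bits()] but summing probability over all paths
#' (log-sum-exp); always at least the Viterbi score.
#' @inheritParams viterbi_bits
#' @return Bit score (numeric scalar).
#' @export
forward_bits <- function(hmm, protein) {
  .validate_hmm(hmm)
  parts <- .hmm_log_parts(hmm)
  hmm_forward_cpp(parts$lm, parts$li, parts$lt, .query_indices(protein))
}

#' Scan proteins against a profile library
#'
#' Every protein is scored against every profile with [viterbi_bits()]. A
#' hit passes when its bit score reaches the profile's
#' `score_threshold_bits`; per protein and role, the passing hit with the
#' highest bit score is flagged as best. The role of a protein is the role
#' of its best passing profile.
#'
#' @param proteins Protein table (columns `id`, `sequence`) or named
#'   character vector.
#' @param library List of `profile_hmm` objects.
#' @return Long-format data.frame of hits: `protein_id`, `hmm_name`,
#'   `role`, `bit_score`, `passes`, `best` (best passing hit for that
#'   protein and role). Proteins with no passing hit have no `best` row.
#' @export
scan_proteins <- function(proteins, library) {
  if (length(library) == 0) stop("empty profile library")
  if (!is.data.frame(proteins)) {
    proteins <- data.frame(id = names(proteins),
                           sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  if (nrow(proteins) == 0) {
    return(data.frame(protein_id = character(), hmm_name = character(),
                      role = character(), bit_score = numeric(),
                      passes = logical(), best = logical(),
                      stringsAsFactors = FALSE))
  }
  parts <- lapply(library, .hmm_log_parts)
  queries <- lapply(proteins$sequence, .query_indices)
  bits <- hmm_scan_cpp(parts, queries)
  np <- nrow(proteins); nh <- length(library)
  hmm_names <- vapply(library, function(h) h$name, "")
  thresholds <- vapply(library, function(h) h$score_threshold_bits, 0)
  hits <- data.frame(
    protein_id = rep(proteins$id, times = nh),
    hmm_name = rep(hmm_names, each = np),
    role = rep(hmm_role(hmm_names), each = np),
    bit_score = as.vector(bits),
    passes = as.vector(bits) >= rep(thresholds, each = np),
    stringsAsFactors = FALSE)
  hits$best <- FALSE
  pass <- which(hits$passes)
  if (length(pass) > 0) {
    key <- paste(hits$protein_id[pass], hits$role[pass], sep = "\r")
    ord <- pass[order(key, -hits$bit_score[pass], hits$hmm_name[pass])]
    keep <- ord[!duplicated(paste(hits$protein_id[ord], hits$role[ord],
                                  sep = "\r"))]
    hits$best[keep] <- TRUE
  }
  rownames(hits) <- NULL
  hits
}
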