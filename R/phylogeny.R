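#' Convert a PAAI matrix to an evolutionary distance matrix
#'
#' `d = 1 - PAAI/100`; the diagonal is forced to zero.
#'
#' @param m PAAI matrix.
#' @return Symmetric distance matrix with the same dimnames.
#' @export
paai_to_distance <- function(m) {
  d <- 1 - m / 100
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (exact on additive matrices).
#' Negative branch-length estimates are clamped to zero with the deficit
#' transferred to the adjacent branch, the usual correction for NJ's
#' unconstrained least-squares estimates.
#'
#' @param d Symmetric distance matrix (>= 3 taxa, ids as dimnames).
#' @return An [ape::ape-package] `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix needs id dimnames")
  tree <- ape::nj(d)
  clamp_negative_branches(tree)
}

# Zero out negative branch lengths, moving each deficit onto the adjacent
# branch toward the root of ape's internal representation.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0) break
    e <- neg[1]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    up <- which(tree$edge[, 2] == parent)
    if (length(up) == 1) {
      tree$edge.length[up] <- tree$edge.length[up] + deficit
    } else {
      sib <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sib) > 0) {
        tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Write / read Newick
#'
#' Thin wrappers with branch lengths preserved to full precision.
#' @param tree A `phylo` tree.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

# leaf sets below each edge of a phylo tree (list indexed by edge row)
.edge_leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  sets <- vector("list", n_node)
  assemble <- function(node) {
    if (node <= n_tip) return(node)
    if (!is.null(sets[[node]])) return(sets[[node]])
    kids <- children[[as.character(node)]]
    out <- unlist(lapply(tree$edge[kids, 2], assemble))
    sets[[node]] <<- out
    out
  }
  lapply(seq_len(nrow(tree$edge)), function(e) assemble(tree$edge[e, 2]))
}

#' Concordance between tree clades and taxon labels
#'
#' For each label, tests whether its leaves form a clade on the unrooted
#' tree (a bipartition separating exactly that leaf set; re-rooting
#' invariant). For a non-monophyletic label the minimal set of leaves
#' whose removal restores monophyly is computed exactly by scanning all
#' bipartitions: removing the symmetric difference between the label set
#' and a bipartition side makes the remaining labelled leaves a clade of
#' the induced tree, and every repair corresponds to such a side.
#'
#' @param tree A `phylo` tree.
#' @param labels Named character vector: leaf id -> taxon label (every
#'   leaf must be labelled).
#' @return data.frame (`label`, `n_leaves`, `monophyletic`, `outliers`)
#'   with attribute `disagreements` = number of distinct outlier leaves
#'   across labels.
#' @export
clade_concordance <- function(tree, labels) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(labels))
  if (length(miss) > 0) {
    stop("unlabelled leaf: ", paste(head(miss, 3), collapse = ", "))
  }
  lab <- labels[tips]
  n <- length(tips)
  leafsets <- .edge_leafsets(tree)
  # candidate bipartition sides as logical masks (both orientations)
  sides <- lapply(leafsets, function(s) {
    mask <- rep(FALSE, n); mask[s] <- TRUE; mask
  })
  sides <- c(sides, lapply(sides, `!`))
  sides <- c(sides, list(rep(TRUE, n)))
  ulab <- sort(unique(lab))
  out <- data.frame(label = ulab, n_leaves = 0L, monophyletic = NA,
                    outliers = "", stringsAsFactors = FALSE)
  all_outliers <- character()
  for (i in seq_along(ulab)) {
    inlab <- lab == ulab[i]
    out$n_leaves[i] <- sum(inlab)
    if (sum(inlab) <= 1) {
      out$monophyletic[i] <- TRUE
      next
    }
    best_cost <- Inf
    best_rm <- character()
    for (s in sides) {
      if (!any(s & inlab)) next
      rm_mask <- xor(s, inlab)
      cost <- sum(rm_mask)
      if (cost < best_cost ||
          (cost == best_cost &&
           paste(tips[rm_mask], collapse = ",") <
           paste(best_rm, collapse = ","))) {
        best_cost <- cost
        best_rm <- sort(tips[rm_mask])
      }
    }
    out$monophyletic[i] <- best_cost == 0
    out$outliers[i] <- paste(best_rm, collapse = ",")
    all_outliers <- union(all_outliers, best_rm)
  }
  attr(out, "disagreements") <- length(all_outliers)
  out
}
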