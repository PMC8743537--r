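#' All-vs-all protein similarity graph
#'
#' Builds the undirected weighted graph fed to Markov clustering: edge
#' weights are Smith-Waterman local-alignment scores with affine gaps
#' (BLOSUM62, gap open 11, extend 1 by default); pairs scoring below the
#' noise floor get no edge.
#'
#' @param proteins Protein table (`id`, `sequence`) or named character
#'   vector; at least two proteins.
#' @param matrix Substitution matrix id (a matrix shipped with Biostrings).
#' @param gap_open,gap_extend Affine gap penalties (gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param score_floor Minimum score for an edge (default 30).
#' @return An object of class `similarity_graph`: `nodes` (ids) and
#'   `edges` (data.frame `id_a`, `id_b`, `weight`, `id_a < id_b` rows only;
#'   local-alignment scores are symmetric).
#' @export
all_vs_all_similarity <- function(proteins, matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1,
                                  score_floor = 30) {
  if (!is.data.frame(proteins)) {
    proteins <- data.frame(id = names(proteins), sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  if (anyDuplicated(proteins$id)) stop("duplicate protein ids")
  sub <- get_substitution_matrix(matrix)
  scores <- sw_matrix_cpp(proteins$sequence, sub, gap_open, gap_extend)
  n <- nrow(proteins)
  idx <- which(upper.tri(scores) & scores >= score_floor, arr.ind = TRUE)
  edges <- data.frame(id_a = proteins$id[idx[, 1]],
                      id_b = proteins$id[idx[, 2]],
                      weight = scores[idx], stringsAsFactors = FALSE)
  structure(list(nodes = proteins$id, edges = edges,
                 self_scores = setNames(diag(scores), proteins$id)),
            class = "similarity_graph")
}

#' Construct a similarity graph from an explicit edge list
#'
#' @param nodes Node ids.
#' @param edges data.frame with `id_a`, `id_b`, `weight` (weights >= 0).
#' @export
similarity_graph <- function(nodes, edges) {
  stopifnot(all(c("id_a", "id_b", "weight") %in% names(edges)))
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    stop("edge weights must be finite and non-negative")
  }
  if (!all(c(edges$id_a, edges$id_b) %in% nodes)) {
    stop("edge endpoint not among nodes")
  }
  key <- paste(pmin(edges$id_a, edges$id_b), pmax(edges$id_a, edges$id_b))
  if (anyDuplicated(key)) stop("duplicate edges")
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Classic MCL: the weighted adjacency matrix (with self-loops weighted by
#' each node's maximum incident weight) is made column-stochastic, then
#' expansion (matrix squaring) and inflation (elementwise power, column
#' renormalisation, pruning of entries below `prune_below`) alternate until
#' the maximum entry change falls under `convergence_tol` or `max_iter` is
#' reached. Clusters are the connected components of the attractor support.
#'
#' @param graph A `similarity_graph`.
#' @param inflation Inflation exponent (> 1; default 2).
#' @param max_iter Iteration cap.
#' @param prune_below Entries below this are zeroed after inflation.
#' @param convergence_tol Convergence threshold on the max entry change.
#' @return An object of class `cluster_set`: list of member-id vectors
#'   (each sorted; clusters ordered by smallest member id) and `labels`.
#' @export
mcl <- function(graph, inflation = 2, max_iter = 100, prune_below = 1e-5,
                convergence_tol = 1e-6) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (inflation <= 1) stop("inflation must be > 1")
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0) {
    ia <- match(e$id_a, nodes); ib <- match(e$id_b, nodes)
    A[cbind(ia, ib)] <- pmax(A[cbind(ia, ib)], e$weight)
    A[cbind(ib, ia)] <- pmax(A[cbind(ib, ia)], e$weight)
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- pmax(diag(A), loop)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mexp <- M %*% M
    Minf <- Mexp ^ inflation
    Minf[Minf < 0] <- 0
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    Minf[Minf < prune_below] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < convergence_tol) break
  }
  support <- (M > 0) | t(M > 0)
  diag(support) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(nodes, comp)
  clusters <- lapply(clusters, function(x) sort(x))
  clusters <- clusters[order(vapply(clusters, `[`, "", 1))]
  names(clusters) <- NULL
  structure(list(clusters = clusters,
                 labels = sprintf("cluster_%d", seq_along(clusters))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d clusters over %d members\n",
              length(x$clusters), sum(lengths(x$clusters))))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  %s (%d): %s%s\n", x$labels[i], length(x$clusters[[i]]),
                paste(head(x$clusters[[i]], 5), collapse = ", "),
                if (length(x$clusters[[i]]) > 5) ", ..." else ""))
  }
  invisible(x)
}

#' Attach taxonomic labels to clusters via anchor sequences
#'
#' The cluster containing an anchor protein takes the anchor's label
#' (`CP_A` ... `CP_H`, `AP205-like`, `RdRP_A`, `RdRP_B`, `MP_1` ... `MP_3`);
#' clusters without anchors are labelled `novel_<role>_<k>`.
#'
#' @param clusters A `cluster_set`.
#' @param anchors Named character vector: `anchor_protein_id -> label`.
#' @param role Role used for generated novel labels (default `"protein"`).
#' @return The `cluster_set` with `labels` replaced.
#' @export
label_clusters <- function(clusters, anchors = character(), role = "protein") {
  stopifnot(inherits(clusters, "cluster_set"))
  labs <- rep(NA_character_, length(clusters$clusters))
  for (a in names(anchors)) {
    hit <- which(vapply(clusters$clusters, function(cl) a %in% cl, TRUE))
    if (length(hit) != 1) {
      stop("anchor '", a, "' found in ", length(hit), " clusters")
    }
    if (!is.na(labs[hit]) && labs[hit] != anchors[[a]]) {
      stop("conflicting anchor labels in one cluster: ",
           labs[hit], " vs ", anchors[[a]])
    }
    labs[hit] <- anchors[[a]]
  }
  k <- 0L
  for (i in seq_along(labs)) {
    if (is.na(labs[i])) {
      k <- k + 1L
      labs[i] <- sprintf("novel_%s_%d", role, k)
    }
  }
  clusters$labels <- labs
  clusters
}
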