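#' Write profile HMMs in HMMER3 ASCII format
#'
#' Serialises profiles in the `HMMER3/f` text layout: per-node match and
#' insert emission lines and a seven-column transition line, all stored as
#' negative natural logs of probabilities, with `*` for probability zero.
#' The acceptance bit-score threshold is written as a `GA` line.
#'
#' @param hmms A `profile_hmm` or list of them.
#' @param path Output path.
#' @export
write_hmmer3 <- function(hmms, path) {
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  fmt <- function(p) ifelse(p > 0, sprintf("%.5f", -log(p)), "*")
  con <- file(path, "w")
  on.exit(close(con))
  for (hmm in hmms) {
    .validate_hmm(hmm)
    writeLines(c(
      "HMMER3/f [levitax]",
      paste0("NAME  ", hmm$name),
      paste0("LENG  ", hmm$M),
      "ALPH  amino",
      sprintf("GA    %.2f %.2f;", hmm$score_threshold_bits,
              hmm$score_threshold_bits),
      paste0("HMM          ", paste(sprintf("%7s", AA_ALPHABET),
                                    collapse = " ")),
      paste0("            ", paste(sprintf("%7s",
             c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
             collapse = " "))), con)
    writeLines(paste0("          ",
                      paste(sprintf("%7s", fmt(hmm$background)),
                            collapse = " ")), con)
    writeLines(paste0("          ",
                      paste(sprintf("%7s", fmt(hmm$transitions[1, ])),
                            collapse = " ")), con)
    for (k in seq_len(hmm$M)) {
      writeLines(sprintf("%7d   %s %7d - - - -", k,
                         paste(sprintf("%7s", fmt(hmm$match_emissions[k, ])),
                               collapse = " "), k), con)
      writeLines(paste0("          ",
                        paste(sprintf("%7s", fmt(hmm$insert_emissions[k, ])),
                              collapse = " ")), con)
      writeLines(paste0("          ",
                        paste(sprintf("%7s", fmt(hmm$transitions[k + 1, ])),
                              collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

.parse_hmm_values <- function(tokens, n, what, node) {
  if (length(tokens) < n) {
    stop(sprintf("truncated %s line at node %d", what, node))
  }
  vals <- tokens[seq_len(n)]
  out <- ifelse(vals == "*", 0, exp(-suppressWarnings(as.numeric(vals))))
  if (any(is.na(out))) {
    stop(sprintf("unparseable %s value at node %d", what, node))
  }
  out
}

#' Read profile HMMs from a HMMER3 ASCII file
#'
#' Parses the `HMMER3` text format (as produced by [write_hmmer3()] or by
#' HMMER's `hmmbuild`): probabilities are recovered as `exp(-x)`, `*` as
#' probability zero. Only amino-acid profiles are supported. A `GA` line,
#' when present, sets the profile's acceptance threshold (default 25 bits).
#'
#' @param path Path to a HMMER3 ASCII file (one or more profiles).
#' @return A list of `profile_hmm` objects.
#' @export
read_hmmer3 <- function(path) {
  lines <- readLines(path)
  hmms <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    while (i <= n_lines && !grepl("^HMMER3", lines[i])) i <- i + 1L
    if (i > n_lines) break
    name <- NA_character_; leng <- NA_integer_; alph <- NA_character_
    ga <- 25
    while (i <= n_lines && !grepl("^HMM\\s", lines[i])) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) >= 2) {
        if (tok[1] == "NAME") name <- tok[2]
        if (tok[1] == "LENG") leng <- as.integer(tok[2])
        if (tok[1] == "ALPH") alph <- tolower(tok[2])
        if (tok[1] == "GA") ga <- as.numeric(sub(";", "", tok[2]))
      }
      i <- i + 1L
    }
    if (i > n_lines) stop("missing HMM node table for profile ", name)
    if (is.na(alph) || alph != "amino") {
      stop("unsupported alphabet '", alph, "' in profile ", name,
           "' (only amino is supported)")
    }
    i <- i + 2L  # skip the HMM symbol line and the transition header
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    background <- AA_BACKGROUND
    if (length(tok) > 0 && tok[1] == "COMPO") {
      background <- setNames(.parse_hmm_values(tok[-1], 20, "COMPO", 0),
                             AA_ALPHABET)
      background <- background / sum(background)
      i <- i + 1L
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    }
    ins0 <- .parse_hmm_values(tok, 20, "node-0 insert", 0)
    i <- i + 1L
    tr <- matrix(0, nrow = leng + 1, ncol = 7,
                 dimnames = list(NULL, HMM_TRANS))
    tr[1, ] <- .parse_hmm_values(strsplit(trimws(lines[i]), "\\s+")[[1]],
                                 7, "node-0 transition", 0)
    i <- i + 1L
    em <- matrix(0, nrow = leng, ncol = 20,
                 dimnames = list(NULL, AA_ALPHABET))
    ins <- em
    for (k in seq_len(leng)) {
      if (i + 2L > n_lines) stop("truncated node table at node ", k)
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (suppressWarnings(as.integer(tok[1])) != k) {
        stop("truncated or misnumbered node table at node ", k)
      }
      em[k, ] <- .parse_hmm_values(tok[-1], 20, "match emission", k)
      ins[k, ] <- .parse_hmm_values(
        strsplit(trimws(lines[i + 1L]), "\\s+")[[1]], 20, "insert emission", k)
      tr[k + 1, ] <- .parse_hmm_values(
        strsplit(trimws(lines[i + 2L]), "\\s+")[[1]], 7, "transition", k)
      i <- i + 3L
    }
    while (i <= n_lines && trimws(lines[i]) != "//") i <- i + 1L
    i <- i + 1L
    # renormalise against the 5-decimal serialisation rounding
    em <- em / rowSums(em)
    ins <- ins / rowSums(ins)
    hmms[[length(hmms) + 1]] <- structure(
      list(name = name, M = leng, match_emissions = em,
           insert_emissions = ins, transitions = tr,
           background = background, score_threshold_bits = ga),
      class = "profile_hmm")
  }
  if (length(hmms) == 0) stop("no HMMER3 profiles found in ", path)
  hmms
}
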