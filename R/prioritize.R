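#' Rank candidate interactions by combined evidence
#'
#' Removes edges already validated in an interaction database
#' (`validated_in_db`), then orders the remainder by the descending sum of
#' three within-list ranks: the precomputed weighted-scoring-by-precision
#' (WSP) score, the logistic-regression score (LRS), and the number of
#' sequence-based prediction algorithms supporting the pair (0-5).  Higher
#' score = higher rank = earlier in the list; ties are broken by the network
#' closeness of the target gene (when supplied), then by miR/gene id.
#' Edges lacking an annotation row receive neutral (minimum) scores and a
#' log line.
#'
#' @param edges data.frame with `mir`, `gene` columns (e.g. from
#'   [select_candidates()]).
#' @param annotations data.frame with columns `mir`, `gene`, `wsp_score`,
#'   `lrs_score`, `n_prediction_algorithms`, `validated_in_db` (logical).
#' @param gene_closeness optional named numeric vector (gene -> closeness)
#'   used as tie-breaker.
#' @return The surviving edges ordered best-first, with columns `rank_sum`
#'   and the annotation columns attached.
#' @export
rank_candidates <- function(edges, annotations, gene_closeness = NULL) {
  if (nrow(edges) == 0) return(edges)
  need <- c("mir", "gene", "wsp_score", "lrs_score",
            "n_prediction_algorithms", "validated_in_db")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0)
    stopf("annotation table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(annotations$n_prediction_algorithms > 5))
    stopf("n_prediction_algorithms must be <= 5")
  key <- function(d) paste(d$mir, d$gene, sep = "\r")
  i <- match(key(edges), key(annotations))
  if (any(is.na(i)))
    stage_log("prioritize", "%d edge(s) without annotation: neutral scores assigned",
              sum(is.na(i)))
  ann <- data.frame(
    wsp_score = ifelse(is.na(i), -Inf, annotations$wsp_score[i]),
    lrs_score = ifelse(is.na(i), -Inf, annotations$lrs_score[i]),
    n_prediction_algorithms = ifelse(is.na(i), 0,
                                     annotations$n_prediction_algorithms[i]),
    validated_in_db = ifelse(is.na(i), FALSE, annotations$validated_in_db[i]))
  out <- cbind(edges[, c("mir", "gene")], ann)
  out <- out[!out$validated_in_db, , drop = FALSE]
  if (nrow(out) == 0) { rownames(out) <- NULL; return(out) }
  # rank() is ascending, so a larger score earns a larger rank
  rank_sum <- rank(out$wsp_score, ties.method = "average") +
    rank(out$lrs_score, ties.method = "average") +
    rank(out$n_prediction_algorithms, ties.method = "average")
  out$rank_sum <- rank_sum
  clo <- if (is.null(gene_closeness)) rep(0, nrow(out)) else {
    v <- gene_closeness[out$gene]
    v[is.na(v)] <- 0
    v
  }
  out <- out[order(-out$rank_sum, -clo, out$mir, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

RC_MAP <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

#' Seed-complement site motif of a microRNA
#'
#' The canonical target site in a 3'UTR is the reverse complement of the
#' miRNA seed, nucleotides 2-8 of the mature sequence (5'->3').  Returns
#' that 7-mer written as DNA.  For mature miR-30b
#' (`UGUAAACAUCCUACACUCAGCU`) the site is `TGTTTAC`.
#'
#' @param mir_sequence mature miRNA sequence, RNA or DNA alphabet, length
#'   >= 8.
#' @return A 7-character DNA motif.
#' @export
seed_complement <- function(mir_sequence) {
  s <- toupper(mir_sequence)
  if (nchar(s) < 8) stopf("mature miR sequence must be >= 8 nt")
  chars <- strsplit(s, "")[[1]]
  if (!all(chars %in% names(RC_MAP)))
    stopf("invalid nucleotide(s) in miR sequence")
  seed <- chars[2:8]
  paste(rev(RC_MAP[seed]), collapse = "")
}

#' 3'UTR sequence with a coordinate origin
#'
#' @param gene gene id.
#' @param sequence DNA string over ACGT, length >= 7.
#' @param origin 1-based coordinate of the first base within the annotated
#'   3'UTR (default 1); lets a sub-fragment keep the full-UTR frame.
#' @return An object of class `utr_sequence`.
#' @export
utr_sequence <- function(gene, sequence, origin = 1L) {
  s <- toupper(sequence)
  if (!grepl("^[ACGT]+$", s)) stopf("UTR sequence must be over {A,C,G,T}")
  if (nchar(s) < 7) stopf("UTR sequence must be >= 7 nt")
  structure(list(gene = gene, sequence = s, origin = as.integer(origin)),
            class = "utr_sequence")
}

#' Read 3'UTR sequences from FASTA
#'
#' Header lines are `>gene_id` optionally followed by `origin=<int>` to
#' place the fragment within the full UTR coordinate frame.
#'
#' @param path FASTA file path.
#' @return A named list of [utr_sequence()] objects.
#' @export
read_utr_fasta <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stopf("no FASTA records in '%s'", path)
  ends <- c(heads[-1] - 1L, length(lines))
  out <- lapply(seq_along(heads), function(i) {
    hdr <- sub("^>", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    gene <- toks[1]
    origin <- 1L
    ot <- grep("^origin=", toks, value = TRUE)
    if (length(ot) == 1) origin <- as.integer(sub("^origin=", "", ot))
    seq <- paste(lines[(heads[i] + 1L):ends[i]], collapse = "")
    utr_sequence(gene, seq, origin)
  })
  stats::setNames(out, vapply(out, function(u) u$gene, character(1)))
}

#' Find exact seed-site occurrences in a 3'UTR
#'
#' Returns every exact occurrence of the 7-mer motif, with 1-based inclusive
#' coordinates expressed in the UTR's own frame (i.e. offset by the
#' sequence's `origin`).
#'
#' @param utr a [utr_sequence()].
#' @param motif a 7-character DNA motif (e.g. from [seed_complement()]).
#' @return A data.frame with columns `start`, `end` (possibly 0 rows).
#' @export
find_sites <- function(utr, motif) {
  if (nchar(motif) != 7) stopf("motif must be a 7-mer")
  motif <- toupper(motif)
  hits <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(motif, substring(utr$sequence, from), fixed = TRUE)
    if (i == -1) break
    pos <- from + as.integer(i) - 1L
    hits <- c(hits, pos)
    from <- pos + 1L   # overlapping occurrences allowed
  }
  start <- hits + utr$origin - 1L
  data.frame(start = start, end = start + 6L)
}

#' Apply single-base substitutions to a 3'UTR
#'
#' Substitutions use the `<ref><position><alt>` notation (e.g. `"G2226T"`),
#' positions in the UTR's coordinate frame.  The reference base must match
#' the current sequence at that position -- a mismatch is a hard error, the
#' guard against coordinate-frame bugs.
#'
#' @param utr a [utr_sequence()].
#' @param subs character vector of substitutions; empty for identity.
#' @return A new [utr_sequence()].
#' @export
apply_substitutions <- function(utr, subs) {
  if (length(subs) == 0) return(utr)
  chars <- strsplit(utr$sequence, "")[[1]]
  for (s in subs) {
    mt <- regmatches(s, regexec("^([ACGT])([0-9]+)([ACGT])$", toupper(s)))[[1]]
    if (length(mt) != 4) stopf("malformed substitution '%s'", s)
    ref <- mt[2]; pos <- as.integer(mt[3]); alt <- mt[4]
    i <- pos - utr$origin + 1L
    if (i < 1 || i > length(chars))
      stopf("substitution position %d outside the sequence (frame %d-%d)",
            pos, utr$origin, utr$origin + length(chars) - 1L)
    if (chars[i] != ref)
      stopf("reference mismatch at position %d: sequence has %s, substitution says %s",
            pos, chars[i], ref)
    chars[i] <- alt
  }
  utr_sequence(utr$gene, paste(chars, collapse = ""), utr$origin)
}
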