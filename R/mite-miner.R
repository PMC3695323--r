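#' Parameters for the structural TIR/TSD scanner
#'
#' @param terminal_motif conserved terminal motif (IUPAC allowed). The left
#'   TIR must start with it; the right element terminus is its reverse
#'   complement.
#' @param min_tir,max_tir accepted TIR length range in bp.
#' @param max_mismatch_per_tir mismatch budget while extending the
#'   inverted repeat inward from the termini.
#' @param min_len,max_len accepted element length range in bp.
#' @param require_tsd demand the TSD immediately outside both termini.
#' @param tsd target-site duplication sequence (TA for Stowaway, TTA for
#'   Tourist-like elements).
#' @return a list of scanner parameters.
#' @export
mite_scan_params <- function(terminal_motif = "CTCCCT", min_tir = 13L,
                             max_tir = 30L, max_mismatch_per_tir = 2L,
                             min_len = 80L, max_len = 600L,
                             require_tsd = TRUE, tsd = "TA") {
  iupac_to_regex(terminal_motif)  # validates
  list(terminal_motif = toupper(terminal_motif), min_tir = as.integer(min_tir),
       max_tir = as.integer(max_tir),
       max_mismatch_per_tir = as.integer(max_mismatch_per_tir),
       min_len = as.integer(min_len), max_len = as.integer(max_len),
       require_tsd = isTRUE(require_tsd), tsd = toupper(tsd))
}

# Extend the inverted repeat inward from both termini of the element
# (element-local chars vector) under an edit budget. A banded edit-distance
# DP aligns the left prefix against the reverse complement of the right
# suffix, so substitutions AND single-base bulges each cost one unit of the
# mismatch budget. Returns c(tir_len, edits) where tir_len is the number of
# left-terminus bases covered.
extend_tir <- function(ch, len, max_tir, budget, band = 2L) {
  lim <- min(max_tir, len %/% 2L)
  l <- ch[seq_len(lim)]
  r <- complement_base(ch[len - seq_len(lim) + 1L])
  bad <- is.na(l) | l == "N"
  INF <- budget + 10L
  prev <- c(0L, pmin(seq_len(lim), INF))  # row i = 0
  tir <- 0L
  tir_mm <- 0L
  for (i in seq_len(lim)) {
    cur <- rep(INF, lim + 1L)
    jlo <- max(0L, i - band); jhi <- min(lim, i + band)
    for (j in jlo:jhi) {
      best <- if (j == 0L) i else INF
      if (j > 0L) {
        sub <- prev[j] + (if (bad[i] || is.na(r[j]) || r[j] == "N" ||
                              l[i] != r[j]) 1L else 0L)
        best <- min(best, sub, cur[j] + 1L)      # sub/match, gap in left
      }
      best <- min(best, prev[j + 1L] + 1L)        # gap in right
      cur[j + 1L] <- best
    }
    prev <- cur
    cost <- min(cur[(jlo + 1L):(jhi + 1L)])
    if (cost <= budget) {
      tir <- i
      tir_mm <- cost
    } else if (cost > budget + band) break
  }
  c(tir, tir_mm)
}

scan_record <- function(seq_id, s, p) {
  s <- toupper(s)
  n <- nchar(s)
  ml <- nchar(p$terminal_motif)
  tl <- nchar(p$tsd)
  lefts <- regex_starts0(iupac_to_regex(p$terminal_motif), s)
  rights <- regex_starts0(iupac_to_regex(revcomp(p$terminal_motif)), s)
  out <- list()
  if (length(lefts) > 0 && length(rights) > 0) {
    chs <- split1(s)
    for (i in lefts) {
      ends <- rights + ml  # candidate element ends (half-open)
      ends <- ends[ends - i >= max(p$min_len, 2L * p$min_tir) &
                   ends - i <= p$max_len]
      for (e in ends) {
        len <- e - i
        ext <- extend_tir(chs[(i + 1L):e], len, p$max_tir,
                          p$max_mismatch_per_tir)
        if (ext[1L] < p$min_tir) next
        tsd_ok <- i >= tl && e + tl <= n &&
          substr0(s, i - tl, i) == p$tsd && substr0(s, e, e + tl) == p$tsd
        if (p$require_tsd && !tsd_ok) next
        out[[length(out) + 1L]] <- data.frame(
          sequence_id = seq_id, start = i, end = e, length = len,
          strand = "+", tir_length = ext[1L], tir_mismatches = ext[2L],
          tsd = if (tsd_ok) p$tsd else NA_character_,
          motif_matched = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# keep the better of two overlapping candidates unless one is strictly
# inside the other (true nesting, both kept)
resolve_overlaps <- function(df) {
  if (nrow(df) < 2L) return(df)
  ord <- order(-df$tir_length, df$tir_mismatches, -df$length, df$start)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (df$end[i] <= df$start[j] || df$start[i] >= df$end[j]) next
      nested <- (df$start[i] >= df$start[j] && df$end[i] <= df$end[j]) ||
        (df$start[j] >= df$start[i] && df$end[j] <= df$end[i])
      same <- df$start[i] == df$start[j] && df$end[i] == df$end[j]
      if (!nested || same) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$end), , drop = FALSE]
}

#' Structural scan for Stowaway-like MITE candidates
#'
#' Finds occurrences of the terminal motif paired with downstream
#' occurrences of its reverse complement, extends the terminal inverted
#' repeat inward under an edit budget (substitutions and single-base
#' bulges both count against `max_mismatch_per_tir`), and (by default)
#' demands the TA
#' target-site duplication immediately outside both termini. Overlapping
#' candidates are resolved in favour of longer TIRs, fewer TIR mismatches,
#' longer elements, then leftmost start; strictly nested candidates are
#' both kept (true nested insertions exist).
#'
#' @param seqs named character vector of DNA sequences (or a single
#'   string).
#' @param params scanner parameters from [mite_scan_params()].
#' @return a `mite_candidates` data.frame with 0-based half-open spans,
#'   TIR geometry, TSD status, AT content, hairpin score and the element
#'   sequence.
#' @export
find_tir_candidates <- function(seqs, params = mite_scan_params()) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%02d", seq_along(seqs))
  res <- list()
  for (id in names(seqs)) {
    df <- scan_record(id, seqs[[id]], params)
    if (!is.null(df)) res[[id]] <- resolve_overlaps(df)
  }
  if (length(res) == 0) {
    df <- data.frame(sequence_id = character(0), start = integer(0),
                     end = integer(0), length = integer(0),
                     strand = character(0), tir_length = integer(0),
                     tir_mismatches = integer(0), tsd = character(0),
                     motif_matched = logical(0), at_content = numeric(0),
                     hairpin_score = numeric(0), source = character(0),
                     seq = character(0), stringsAsFactors = FALSE)
    class(df) <- c("mite_candidates", "data.frame")
    return(df)
  }
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df$seq <- vapply(seq_len(nrow(df)), function(i)
    substr0(toupper(seqs[[df$sequence_id[i]]]), df$start[i], df$end[i]), "")
  df$at_content <- at_content(df$seq)
  df$hairpin_score <- vapply(df$seq, hairpin_score, 0, USE.NAMES = FALSE)
  df$source <- "structural"
  df <- df[, c("sequence_id", "start", "end", "length", "strand",
               "tir_length", "tir_mismatches", "tsd", "motif_matched",
               "at_content", "hairpin_score", "source", "seq")]
  class(df) <- c("mite_candidates", "data.frame")
  df
}

#' Maximum base-pairing hairpin score
#'
#' A dependency-free, monotone proxy for secondary-structure-forming
#' potential: the maximum number of nested Watson-Crick base pairs
#' (optionally allowing G-T wobble) with a minimum loop of 3 unpaired
#' bases, divided by `floor(length/2)`. A near-perfect fold-back such as a
#' long inverted repeat scores close to 1.
#'
#' @param seq a DNA string of length >= 10.
#' @param wobble also allow G-T pairs (default `FALSE`).
#' @param min_loop minimum hairpin loop length (default 3).
#' @return a score in `[0, 1]`.
#' @export
hairpin_score <- function(seq, wobble = FALSE, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 10L) stop("sequence too short for hairpin scoring (< 10 bp)")
  nussinov_cpp(toupper(seq), wobble, as.integer(min_loop)) / (n %/% 2L)
}

#' Parameters for the homology search
#'
#' @param word_size exact k-mer seed length.
#' @param min_identity minimum alignment identity to report a hit.
#' @param min_aligned_fraction minimum fraction of the query covered.
#' @param match,mismatch,gap_open,gap_extend local-alignment scoring.
#' @return a parameter list.
#' @export
homology_params <- function(word_size = 11L, min_identity = 0.6,
                            min_aligned_fraction = 0.5, match = 1,
                            mismatch = -1, gap_open = 4, gap_extend = 1) {
  list(word_size = as.integer(word_size), min_identity = min_identity,
       min_aligned_fraction = min_aligned_fraction, match = match,
       mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend)
}

alignment_stats <- function(aa, ab) {
  ca <- split1(aa); cb <- split1(ab)
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb & ca != "N")
  list(npair = sum(both), matches = matches,
       identity = if (sum(both) > 0) matches / sum(both) else 0)
}

#' Homology search for element copies
#'
#' k-mer seeded local-alignment search of a query element (e.g. a family
#' consensus) against a sequence database, in the spirit of a BLAST mining
#' pass. Seeds are clustered by diagonal and each cluster's window is
#' aligned with affine-gap Smith-Waterman; hits passing the identity and
#' query-coverage thresholds are reported with their flank lengths.
#'
#' @param query query sequence (character scalar).
#' @param database named character vector of subject sequences.
#' @param params parameters from [homology_params()].
#' @return data.frame of hits: `sequence_id`, `start`, `end` (0-based
#'   half-open subject coordinates), `identity`, `aligned_length`,
#'   `left_flank_length`, `right_flank_length`, `validated` (NA until
#'   [validate_hit()] is applied).
#' @export
homology_search <- function(query, database, params = homology_params()) {
  query <- toupper(unname(query[1L]))
  qlen <- nchar(query)
  if (qlen < params$word_size)
    stop("query shorter than word_size (", params$word_size, ")")
  if (is.null(names(database)))
    names(database) <- sprintf("seq_%02d", seq_along(database))
  w <- params$word_size
  qwords <- substring(query, 1:(qlen - w + 1L), w:qlen)
  hits <- list()
  for (id in names(database)) {
    subj <- toupper(database[[id]])
    slen <- nchar(subj)
    if (slen < w) next
    swords <- substring(subj, 1:(slen - w + 1L), w:slen)
    m <- match(swords, qwords)
    spos <- which(!is.na(m))
    if (length(spos) == 0) next
    qpos <- m[spos]
    diag <- spos - qpos
    ord <- order(diag, spos)
    spos <- spos[ord]; diag <- diag[ord]
    # cluster seeds: same region if diagonals within qlen/4 and subject
    # positions within qlen of each other
    cl <- cumsum(c(TRUE, diff(diag) > max(20L, qlen %/% 4L) |
                     diff(spos) > qlen))
    for (g in unique(cl)) {
      sp <- spos[cl == g]
      win_s <- max(0L, min(sp) - qlen - 10L)
      win_e <- min(slen, max(sp) + w + qlen + 10L)
      aln <- sw_local_cpp(query, substr0(subj, win_s, win_e),
                          params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
      st <- alignment_stats(aln$aligned_a, aln$aligned_b)
      q_cov <- (aln$end_a - aln$start_a + 1L) / qlen
      if (st$identity < params$min_identity ||
          q_cov < params$min_aligned_fraction) next
      hs <- win_s + aln$start_b - 1L      # 0-based
      he <- win_s + aln$end_b             # half-open
      hits[[length(hits) + 1L]] <- data.frame(
        sequence_id = id, start = hs, end = he, identity = st$identity,
        aligned_length = nchar(aln$aligned_a),
        left_flank_length = hs, right_flank_length = slen - he,
        validated = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      aligned_length = integer(0),
                      left_flank_length = integer(0),
                      right_flank_length = integer(0), validated = logical(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  # drop duplicate/overlapping hits on the same record, best first
  df <- df[order(df$sequence_id, -df$identity * df$aligned_length), ,
           drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || df$sequence_id[i] != df$sequence_id[j]) next
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
      if (ov > 0.5 * (df$end[i] - df$start[i])) { keep[i] <- FALSE; break }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$sequence_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Validate a homology hit with the BAC-end screening filters
#'
#' A hit is validated when it carries the characteristic TSD, a detectable
#' TIR pair at its boundaries (the structural scanner is re-run on the hit
#' interval with 5 bp slack), and enough flanking sequence on both sides.
#'
#' @param hit one row of the [homology_search()] result.
#' @param database the sequence database the hit refers to.
#' @param min_flank minimum flank length in bp (default 100).
#' @param scan_params structural scanner parameters used for the TIR/TSD
#'   check.
#' @param slack coordinate slack in bp when matching the structural
#'   candidate to the hit interval (default 5).
#' @return the hit row with `validated` set.
#' @export
validate_hit <- function(hit, database, min_flank = 100L,
                         scan_params = mite_scan_params(), slack = 5L) {
  subj <- toupper(database[[hit$sequence_id]])
  if (is.null(subj) || is.na(subj)) stop("unknown sequence_id: ", hit$sequence_id)
  if (hit$start < 0 || hit$end > nchar(subj))
    stop("hit coordinates outside record")
  flank_ok <- hit$left_flank_length >= min_flank &&
    hit$right_flank_length >= min_flank
  win_s <- max(0L, hit$start - slack - nchar(scan_params$tsd))
  win_e <- min(nchar(subj), hit$end + slack + nchar(scan_params$tsd))
  cand <- find_tir_candidates(setNames(substr0(subj, win_s, win_e),
                                       hit$sequence_id), scan_params)
  struct_ok <- FALSE
  if (nrow(cand) > 0) {
    gs <- cand$start + win_s
    ge <- cand$end + win_s
    struct_ok <- any(abs(gs - hit$start) <= slack &
                     abs(ge - hit$end) <= slack & !is.na(cand$tsd))
  }
  hit$validated <- flank_ok && struct_ok
  hit
}
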