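#' Reconstruct the pre-insertion state of a locus
#'
#' Removes the element and one copy of its TA target-site duplication,
#' leaving the single ancestral TA — the inverse of a Stowaway insertion.
#' Which TA copy was ancestral is unknowable; the left copy is kept by
#' convention (string-identical either way for a TA TSD).
#'
#' @param seq the sequence carrying the element.
#' @param element_start,element_end 0-based half-open element span (TIRs
#'   included, TSDs excluded).
#' @return the sequence with `[element_start - 2, element_end)` excised.
#' @export
reconstruct_preinsertion <- function(seq, element_start, element_end) {
  s <- toupper(unname(seq[1L]))
  if (element_start < 2 || element_end + 2 > nchar(s))
    stop("element span leaves no room for the TSD")
  if (substr0(s, element_start - 2L, element_start) != "TA" ||
      substr0(s, element_end, element_end + 2L) != "TA")
    stop("TSD absent at element boundaries: cannot infer ancestral state")
  paste0(substr0(s, 0L, element_start - 2L),
         substr0(s, element_end, nchar(s)))
}

#' Detect insertions nested inside a mined element
#'
#' Re-runs the structural scanner within the outer element's span, once
#' per candidate TSD (TA for Stowaway, TTA for Tourist-like elements by
#' default). Inner hits overlapping the outer TIRs are discarded. Each
#' nested insertion is reported with the outer sequence reconstructed to
#' its pre-nesting state (inner element plus one TSD copy excised).
#'
#' @param candidate one row of a [find_tir_candidates()] result (the
#'   outer element).
#' @param seq the full sequence the candidate refers to.
#' @param params structural scanner parameters for the inner scan; the
#'   length floor is relaxed to `min_len` if the outer is small.
#' @param tsd_list TSDs to try (default `c("TA", "TTA")`).
#' @return list of nested insertions, each a list with `inner` (scanner
#'   row, coordinates relative to the outer span), `inner_genomic_start`,
#'   `inner_genomic_end`, `tsd` and `reconstructed_outer`.
#' @export
detect_nested <- function(candidate, seq, params = mite_scan_params(),
                          tsd_list = c("TA", "TTA")) {
  s <- toupper(unname(seq[1L]))
  os <- candidate$start; oe <- candidate$end
  outer_seq <- substr0(s, os, oe)
  otl <- candidate$tir_length
  out <- list()
  for (tsd in tsd_list) {
    p <- params
    p$tsd <- tsd
    inner <- find_tir_candidates(setNames(outer_seq, "outer"), p)
    if (nrow(inner) == 0) next
    tl <- nchar(tsd)
    # inner element plus its TSDs must sit strictly between the outer TIRs
    ok <- inner$start - tl >= otl & inner$end + tl <= nchar(outer_seq) - otl &
      !is.na(inner$tsd)
    # the outer element itself can be re-detected; drop it
    ok <- ok & !(inner$start == 0L & inner$end == nchar(outer_seq))
    inner <- inner[ok, , drop = FALSE]
    for (i in seq_len(nrow(inner))) {
      rec <- paste0(substr0(outer_seq, 0L, inner$start[i] - tl),
                    substr0(outer_seq, inner$end[i], nchar(outer_seq)))
      out[[length(out) + 1L]] <- list(
        inner = inner[i, , drop = FALSE],
        inner_genomic_start = os + inner$start[i],
        inner_genomic_end = os + inner$end[i],
        tsd = tsd, reconstructed_outer = rec)
    }
  }
  out
}

#' Classify one haplotype of an insertion locus
#'
#' Assigns a locus variant class by anchoring the observed haplotype to
#' the reference flanks, re-running the structural scanner, and comparing
#' the observed length to the reconstructed empty site. Classes:
#' `occupied` (full element, both TIR termini), `empty` (exact empty
#' site), `footprint` (empty site with a 1..`footprint_max` bp junction
#' residual), `internal_deletion` (element remnant with >= 20 bp missing),
#' `clustered` (two or more structural candidates at the locus) and
#' `complex` (none of the above).
#'
#' @param reference_occupied the occupied reference haplotype.
#' @param element_span 0-based half-open element span within the
#'   reference.
#' @param observed the haplotype to classify.
#' @param footprint_max largest junction residual called a footprint
#'   (default 10 bp).
#' @param flank_anchor anchor length checked on each side (default 30 bp,
#'   >= 90% identity required). Anchors are taken at the outer ends of the
#'   reference flanks, where neither footprints nor clustered insertions
#'   can disturb them.
#' @param scan_params structural scanner parameters.
#' @param min_element_fraction fraction of the element length a candidate
#'   must reach to call the locus occupied (default 0.9).
#' @return list of class `locus_variant`: `class`, `observed_length`,
#'   `detail`.
#' @export
classify_locus_variant <- function(reference_occupied, element_span, observed,
                                   footprint_max = 10L, flank_anchor = 30L,
                                   scan_params = mite_scan_params(),
                                   min_element_fraction = 0.9) {
  ref <- toupper(unname(reference_occupied[1L]))
  obs <- toupper(unname(observed[1L]))
  es <- element_span[1L]; ee <- element_span[2L]
  elen <- ee - es
  if (es - 2L < flank_anchor || nchar(ref) - ee - 2L < flank_anchor)
    stop("reference flanks too short for anchoring")
  left_anchor <- substr0(ref, 0L, flank_anchor)
  right_anchor <- substr0(ref, nchar(ref) - flank_anchor, nchar(ref))
  max_mm <- floor(0.1 * flank_anchor)
  anchored <- function(anchor) {
    length(Biostrings::matchPattern(anchor, Biostrings::DNAString(obs),
                                    max.mismatch = max_mm)) > 0
  }
  if (!anchored(left_anchor) || !anchored(right_anchor))
    stop("flank anchors fail to align: wrong locus?")
  empty_len <- nchar(ref) - elen - 2L
  d <- nchar(obs) - empty_len
  cand <- find_tir_candidates(setNames(obs, "obs"), scan_params)
  n_cand <- nrow(cand)
  cls <- "complex"; detail <- ""
  if (n_cand >= 2L) {
    cls <- "clustered"
    gaps <- diff(sort(cand$start))
    detail <- sprintf("%d candidates, min gap %d bp", n_cand, min(gaps))
  } else if (n_cand == 1L) {
    clen <- cand$length[1L]
    if (clen >= min_element_fraction * elen) {
      if (abs(d - (elen + 2L)) <= footprint_max) {
        cls <- "occupied"
        detail <- sprintf("element %d bp at %d", clen, cand$start[1L])
      }
    } else if (elen - clen >= 20L) {
      cls <- "internal_deletion"
      detail <- sprintf("remnant %d bp (%d bp missing)", clen, elen - clen)
    }
  } else {
    if (d == 0L) {
      cls <- "empty"
    } else if (abs(d) >= 1L && abs(d) <= footprint_max) {
      cls <- "footprint"
      detail <- sprintf("junction residual %+d bp", d)
    } else if (d >= 20L) {
      cls <- "internal_deletion"
      detail <- sprintf("element remnant without detectable TIR pair (%+d bp)", d)
    }
  }
  structure(list(class = cls, observed_length = nchar(obs), detail = detail),
            class = "locus_variant")
}

#' Classify every haplotype of a locus
#'
#' @param reference_occupied,element_span as in
#'   [classify_locus_variant()].
#' @param haplotypes named character vector of accession haplotypes.
#' @param ... passed to [classify_locus_variant()].
#' @return data.frame with `accession_id`, `class`, `observed_length`,
#'   `detail`.
#' @export
classify_locus_population <- function(reference_occupied, element_span,
                                      haplotypes, ...) {
  if (is.null(names(haplotypes)))
    names(haplotypes) <- sprintf("acc_%03d", seq_along(haplotypes))
  rows <- lapply(names(haplotypes), function(id) {
    v <- classify_locus_variant(reference_occupied, element_span,
                                haplotypes[[id]], ...)
    data.frame(accession_id = id, class = v$class,
               observed_length = v$observed_length, detail = v$detail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' A PCR primer
#'
#' @param name primer name.
#' @param sequence primer sequence, 5' to 3', length >= 15.
#' @param max_mismatch tolerated mismatches outside the 3'-terminal 3
#'   bases (which must match exactly).
#' @return object of class `primer_spec`.
#' @export
primer_spec <- function(name, sequence, max_mismatch = 2L) {
  sequence <- toupper(gsub("[ ]", "", sequence))
  stopifnot(nchar(sequence) >= 15L)
  validate_dna(sequence, name)
  structure(list(name = name, sequence = sequence,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_spec")
}

# binding sites of a primer: list of plus-strand starts (0-based; the 3'
# end points right) and minus-strand ends (half-open; the 3' end points
# left). The 3'-terminal `exact3` bases must match exactly.
primer_sites <- function(template, primer, exact3 = 3L) {
  s <- Biostrings::DNAString(template)
  p <- primer$sequence
  plen <- nchar(p)
  plus <- Biostrings::matchPattern(p, s, max.mismatch = primer$max_mismatch)
  ps <- BiocGenerics::start(plus) - 1L
  if (length(ps) > 0) {
    tail_ok <- vapply(ps, function(x)
      substr0(template, x + plen - exact3, x + plen) ==
        substr(p, plen - exact3 + 1L, plen), TRUE)
    ps <- ps[tail_ok]
  }
  rc <- revcomp(p)
  minus <- Biostrings::matchPattern(rc, s, max.mismatch = primer$max_mismatch)
  ms <- BiocGenerics::start(minus) - 1L
  if (length(ms) > 0) {
    head_rc <- substr(rc, 1L, exact3)  # rc of the primer's 3' tail
    tail_ok <- vapply(ms, function(x)
      substr0(template, x, x + exact3) == head_rc, TRUE)
    ms <- ms[tail_ok]
  }
  list(plus_start = ps, minus_end = ms + plen)
}

#' In-silico PCR amplicon prediction
#'
#' Finds all binding sites of the primers on both strands of the template
#' and reports every convergent pair within `max_product` bp. With a
#' single primer (`rev = NULL`) the same primer acts on both strands,
#' reproducing TIR-anchored amplification of full-length Stowaway
#' elements.
#'
#' @param template template sequence (character scalar).
#' @param fwd,rev [primer_spec()] objects (`rev` optional).
#' @param max_product maximum product length in bp (default 5000).
#' @param exact3 3'-terminal bases that must match exactly (default 3).
#' @return data.frame of amplicons: `start`, `end` (0-based half-open),
#'   `length`, `fwd_primer`, `rev_primer`, `seq`. Empty when there is no
#'   product.
#' @export
insilico_pcr <- function(template, fwd, rev = NULL, max_product = 5000L,
                         exact3 = 3L) {
  s <- toupper(unname(template[1L]))
  stopifnot(inherits(fwd, "primer_spec"))
  primers <- list(fwd)
  if (!is.null(rev)) {
    stopifnot(inherits(rev, "primer_spec"))
    primers <- c(primers, list(rev))
  }
  sites <- lapply(primers, function(p) primer_sites(s, p, exact3))
  out <- list()
  for (a in seq_along(primers)) for (b in seq_along(primers)) {
    if (length(primers) == 2L && a == b) next  # paired mode: convergent pair
    for (ps in sites[[a]]$plus_start) for (me in sites[[b]]$minus_end) {
      len <- me - ps
      if (len < nchar(primers[[a]]$sequence) || len > max_product) next
      out[[length(out) + 1L]] <- data.frame(
        start = ps, end = me, length = len,
        fwd_primer = primers[[a]]$name, rev_primer = primers[[b]]$name,
        seq = substr0(s, ps, me), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_primer = character(0),
                      rev_primer = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarize insertion polymorphism across loci
#'
#' @param variants data.frame with `locus_id`, `accession_id`, `class`
#'   (classes as produced by [classify_locus_variant()]).
#' @return per-locus data.frame: accession count, count per class,
#'   `insertion_frequency` (fraction of haplotypes carrying the element:
#'   occupied, internal_deletion or clustered) and `polymorphic` (>= 2
#'   classes observed).
#' @export
polymorphism_report <- function(variants) {
  stopifnot(all(c("locus_id", "accession_id", "class") %in% names(variants)))
  if (nrow(variants) == 0) stop("need at least one locus")
  classes <- c("occupied", "empty", "footprint", "internal_deletion",
               "clustered", "complex")
  carrying <- c("occupied", "internal_deletion", "clustered")
  rows <- lapply(split(variants, variants$locus_id), function(v) {
    counts <- vapply(classes, function(cl) sum(v$class == cl), 0L)
    out <- data.frame(locus_id = v$locus_id[1L], n = nrow(v),
                      stringsAsFactors = FALSE)
    for (cl in classes) out[[paste0("n_", cl)]] <- counts[[cl]]
    out$insertion_frequency <- mean(v$class %in% carrying)
    out$polymorphic <- length(unique(v$class)) >= 2L
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
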