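#' Specification of a synthetic Stowaway-like MITE family
#'
#' Describes the consensus from which copies of one family are simulated.
#' Defaults mirror the canonical carrot DcSto1 element: 274 bp long, 16 bp
#' terminal inverted repeats (TIRs) opening with the conserved `CTCCCT`
#' motif, and an AT fraction drawn from 0.60-0.72 when not given.
#'
#' @param family_id family label.
#' @param consensus_length element length in bp (TIRs included), `< 600`.
#' @param tir_length TIR length in bp (13-30 typical).
#' @param terminal_motif conserved terminal motif (IUPAC allowed); the left
#'   TIR starts with it and the right terminus is its reverse complement.
#' @param at_fraction target AT fraction of the consensus, or `NULL` to draw
#'   uniformly from `[0.60, 0.72]` at generation time.
#' @param divergence per-site substitution rate applied to each copy, in
#'   `[0, 0.3]`.
#' @param indel_rate per-site single-base indel rate applied to each copy.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(family_id = "DcSto1", consensus_length = 274L,
                        tir_length = 16L, terminal_motif = "CTCCCT",
                        at_fraction = NULL, divergence = 0.05,
                        indel_rate = 0.002) {
  terminal_motif <- toupper(terminal_motif)
  iupac_to_regex(terminal_motif)  # validates alphabet
  stopifnot(consensus_length < 600, consensus_length > 0,
            tir_length >= nchar(terminal_motif),
            2L * tir_length < consensus_length,
            divergence >= 0, divergence <= 0.3, indel_rate >= 0)
  if (!is.null(at_fraction))
    stopifnot(at_fraction >= 0, at_fraction <= 1)
  structure(list(family_id = family_id,
                 consensus_length = as.integer(consensus_length),
                 tir_length = as.integer(tir_length),
                 terminal_motif = terminal_motif,
                 at_fraction = at_fraction,
                 divergence = divergence, indel_rate = indel_rate),
            class = "family_spec")
}

#' Generate an i.i.d. background sequence
#'
#' Bases are drawn independently with `P(A) = P(T) = at_fraction/2` and
#' `P(C) = P(G) = (1 - at_fraction)/2`, emulating an AT-rich host genome.
#'
#' @param length sequence length in bp (> 0).
#' @param at_fraction AT fraction in (0, 1]; 1 gives an A/T-only sequence.
#' @param seed integer seed for reproducibility (optional).
#' @param id record id.
#' @return a named character scalar (name = `id`).
#' @export
generate_background <- function(length, at_fraction = 0.65, seed = NULL,
                                id = "background") {
  stopifnot(length > 0, at_fraction > 0, at_fraction <= 1)
  with_seed(seed, {
    p <- c(at_fraction / 2, at_fraction / 2,
           (1 - at_fraction) / 2, (1 - at_fraction) / 2)
    bases <- sample(c("A", "T", "C", "G"), length, replace = TRUE, prob = p)
    setNames(paste(bases, collapse = ""), id)
  })
}

# Build a family consensus with exact AT composition.  The left TIR starts
# with the terminal motif; the right TIR is the reverse complement of the
# left, so every left-TIR base contributes twice to composition (A/T
# complements to A/T).
build_family_consensus <- function(spec) {
  L <- spec$consensus_length
  tl <- spec$tir_length
  ml <- nchar(spec$terminal_motif)
  # instantiate any degenerate motif positions
  motif <- vapply(split1(spec$terminal_motif),
                  function(c) sample(IUPAC_CODES[[c]], 1L), "")
  at <- spec$at_fraction
  target <- round(at * L)
  fixed_at <- 2L * sum(motif %in% c("A", "T"))
  n_tirfree <- tl - ml            # weight 2 each
  n_internal <- L - 2L * tl       # weight 1 each
  a <- round(at * n_tirfree)      # AT bases among free TIR positions
  b <- target - fixed_at - 2L * a
  while (b < 0 && a > 0) { a <- a - 1L; b <- b + 2L }
  while (b > n_internal && a < n_tirfree) { a <- a + 1L; b <- b - 2L }
  b <- max(0L, min(n_internal, b))
  fill <- function(n, n_at) {
    cls <- sample(c(rep(TRUE, n_at), rep(FALSE, n - n_at)))
    ifelse(cls, sample(c("A", "T"), n, replace = TRUE),
           sample(c("C", "G"), n, replace = TRUE))
  }
  tir_free <- if (n_tirfree > 0) fill(n_tirfree, a) else character(0)
  internal <- if (n_internal > 0) fill(n_internal, b) else character(0)
  left_tir <- paste(c(motif, tir_free), collapse = "")
  paste0(left_tir, paste(internal, collapse = ""), revcomp(left_tir))
}

# Mutate one copy away from the consensus: uniform substitutions at rate
# `divergence`, single-base indels at rate `indel_rate`; the terminal motif
# positions at both ends are immutable.
mutate_copy <- function(consensus, divergence, indel_rate, protect_len) {
  ch <- split1(consensus)
  L <- length(ch)
  protected <- c(seq_len(protect_len), seq(L - protect_len + 1L, L))
  mutable <- setdiff(seq_len(L), protected)
  if (divergence > 0) {
    hit <- mutable[runif(length(mutable)) < divergence]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  if (indel_rate > 0) {
    hit <- mutable[runif(length(mutable)) < indel_rate]
    if (length(hit) > 0) {
      out <- as.list(ch)
      for (i in hit) {
        if (runif(1) < 0.5) out[[i]] <- character(0)  # deletion
        else out[[i]] <- c(ch[i], sample(c("A", "C", "G", "T"), 1L))
      }
      ch <- unlist(out)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate copies of one MITE family
#'
#' Builds a consensus obeying the family specification and mutates it
#' independently into `n_copies` element sequences. The terminal motif at
#' both ends is protected from mutation (intact termini).
#'
#' @param spec a [family_spec()].
#' @param n_copies number of copies (>= 1).
#' @param seed integer seed (optional).
#' @return a list with `spec` (with realized `at_fraction`), `consensus`
#'   (character scalar) and `copies` (data.frame with `copy_id`,
#'   `family_id`, `seq`, `at_content`).
#' @export
generate_family <- function(spec, n_copies, seed = NULL) {
  stopifnot(inherits(spec, "family_spec"), n_copies >= 1)
  with_seed(seed, {
    if (is.null(spec$at_fraction)) spec$at_fraction <- runif(1, 0.60, 0.72)
    consensus <- build_family_consensus(spec)
    ml <- nchar(spec$terminal_motif)
    seqs <- vapply(seq_len(n_copies), function(i)
      mutate_copy(consensus, spec$divergence, spec$indel_rate, ml), "")
    copies <- data.frame(
      copy_id = sprintf("%s_c%02d", spec$family_id, seq_len(n_copies)),
      family_id = spec$family_id, seq = seqs,
      at_content = at_content(seqs), stringsAsFactors = FALSE)
    list(spec = spec, consensus = consensus, copies = copies)
  })
}

as_element_df <- function(elements) {
  if (is.data.frame(elements)) {
    stopifnot(all(c("copy_id", "family_id", "seq") %in% names(elements)))
    return(elements)
  }
  stopifnot(is.character(elements))
  ids <- names(elements)
  if (is.null(ids)) ids <- sprintf("element_%02d", seq_along(elements))
  data.frame(copy_id = ids, family_id = "unknown", seq = unname(elements),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(sequence_id = character(0), start = integer(0), end = integer(0),
             family_id = character(0), copy_id = character(0),
             nesting_parent = character(0), class = character(0),
             stringsAsFactors = FALSE)
}

#' Plant elements into a background at TA target sites
#'
#' Each insertion replaces one `TA` occurrence by `TA + element + TA`,
#' duplicating the target dinucleotide exactly as a Stowaway insertion
#' does. Truth coordinates are 0-based half-open on the final sequence and
#' span the element only (TIRs included, flanking TSDs excluded).
#'
#' @param genome background sequence (named character scalar or plain
#'   string).
#' @param elements element sequences: data.frame with `copy_id`,
#'   `family_id`, `seq`, or a (named) character vector.
#' @param n number of insertions; defaults to the number of elements
#'   supplied. If `n` differs, elements are sampled with replacement.
#' @param seed integer seed (optional).
#' @return list with `genome` (mutated named character scalar) and `truth`
#'   (planted-insertion ledger data.frame).
#' @export
plant_insertions <- function(genome, elements, n = NULL, seed = NULL) {
  seq_id <- if (!is.null(names(genome))) names(genome)[1L] else "genome"
  bg <- unname(genome[1L])
  el <- as_element_df(elements)
  if (is.null(n)) n <- nrow(el)
  stopifnot(n >= 0)
  if (n == 0)
    return(list(genome = setNames(bg, seq_id), truth = empty_truth()))
  with_seed(seed, {
    idx <- if (n == nrow(el)) seq_len(n) else
      sample(nrow(el), n, replace = TRUE)
    picked <- el[idx, , drop = FALSE]
    if (anyDuplicated(picked$copy_id))
      picked$copy_id <- make.unique(picked$copy_id, sep = ".")
    sites <- regex_starts0("TA", bg)
    sites <- sites[sites >= 2 & sites <= nchar(bg) - 4]
    if (length(sites) < n)
      stop("insufficient TA sites: need ", n, ", found ", length(sites))
    chosen <- sort(sample(sites, n))
    picked <- picked[sample(n), , drop = FALSE]  # random site assignment
    lens <- nchar(picked$seq)
    # assemble left-to-right
    pieces <- character(2L * n + 1L)
    prev <- 0L
    starts <- integer(n)
    offset <- 0L
    for (i in seq_len(n)) {
      p <- chosen[i]
      pieces[2L * i - 1L] <- substr0(bg, prev, p + 2L)
      pieces[2L * i] <- paste0(picked$seq[i], "TA")
      starts[i] <- p + 2L + offset
      offset <- offset + lens[i] + 2L
      prev <- p + 2L
    }
    pieces[2L * n + 1L] <- substr0(bg, prev, nchar(bg))
    out <- paste(pieces, collapse = "")
    truth <- data.frame(sequence_id = seq_id, start = starts,
                        end = starts + lens, family_id = picked$family_id,
                        copy_id = picked$copy_id,
                        nesting_parent = NA_character_, class = "intact",
                        stringsAsFactors = FALSE)
    list(genome = setNames(out, seq_id), truth = truth)
  })
}

#' Nest an element inside a previously planted copy
#'
#' Inserts `inner_element` at a TA site strictly inside the target copy
#' (away from its TIRs), with its own TA target site duplication, and
#' records the nesting in the truth ledger.
#'
#' @param genome named character scalar holding the planted sequence.
#' @param truth the truth ledger from [plant_insertions()].
#' @param inner_element inner element sequence (character scalar).
#' @param target_copy_id `copy_id` of the (intact) outer copy.
#' @param seed integer seed (optional).
#' @param inner_family family label for the inner element.
#' @param inner_copy_id copy id for the inner element.
#' @param margin bp at each end of the outer copy kept free of the
#'   insertion so the outer TIRs stay intact (default 20).
#' @return list with updated `genome` and `truth`.
#' @export
plant_nested <- function(genome, truth, inner_element, target_copy_id,
                         seed = NULL, inner_family = "inner",
                         inner_copy_id = paste0(target_copy_id, ".nested"),
                         margin = 20L) {
  seq_id <- if (!is.null(names(genome))) names(genome)[1L] else "genome"
  g <- unname(genome[1L])
  row <- which(truth$copy_id == target_copy_id)
  if (length(row) != 1L) stop("unknown target copy: ", target_copy_id)
  if (truth$class[row] != "intact")
    stop("target copy is not intact (class ", truth$class[row], ")")
  s <- truth$start[row]; e <- truth$end[row]
  inside <- substr0(g, s, e)
  sites <- regex_starts0("TA", inside)
  sites <- sites[sites >= margin & sites <= nchar(inside) - margin - 2L]
  if (length(sites) == 0) stop("no internal TA site in target copy")
  with_seed(seed, {
    p <- if (length(sites) == 1L) sites else sample(sites, 1L)
    cut <- s + p + 2L  # genome position after the chosen TA
    ilen <- nchar(inner_element)
    g2 <- paste0(substr0(g, 0L, cut), inner_element, "TA",
                 substr0(g, cut, nchar(g)))
    shift <- ilen + 2L
    spans <- truth$start < cut & truth$end >= cut  # the outer (and any parent)
    truth$end[spans] <- truth$end[spans] + shift
    move <- truth$start >= cut                     # records fully downstream
    truth$start[move] <- truth$start[move] + shift
    truth$end[move] <- truth$end[move] + shift
    inner_row <- data.frame(sequence_id = seq_id, start = cut,
                            end = cut + ilen, family_id = inner_family,
                            copy_id = inner_copy_id,
                            nesting_parent = target_copy_id,
                            class = "intact", stringsAsFactors = FALSE)
    truth <- rbind(truth, inner_row)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = setNames(g2, seq_id), truth = truth)
  })
}

#' Simulate haplotypes of one insertion locus across accessions
#'
#' Emulates the locus variant classes seen at polymorphic Stowaway
#' insertion sites: `occupied` (element with TA TSDs), `empty` (ancestral
#' site), `footprint` (empty site with a 1-10 bp residual indel at the
#' junction, as left by imprecise excision), `internal_deletion` (occupied
#' allele with a contiguous deletion of 20-80% of the element, e.g. from
#' abortive gap repair) and `clustered` (occupied plus a second element
#' 20-100 bp upstream).
#'
#' @param locus_flanks character vector of length 2: left and right flank
#'   sequences (left flank >= 150 bp for the clustered class).
#' @param element element sequence placed at the locus.
#' @param class_frequencies named numeric vector over a subset of
#'   `occupied, empty, footprint, internal_deletion, clustered`; must sum
#'   to 1 (tolerance 1e-9).
#' @param n_accessions number of haplotypes to simulate.
#' @param seed integer seed (optional).
#' @param second_element element used for the clustered class (defaults to
#'   `element`).
#' @return list with `haplotypes` (named character vector), `truth`
#'   (data.frame `accession_id`, `class`, `detail`), `reference_occupied`
#'   and `element_span` (0-based half-open span of the element within the
#'   occupied reference).
#' @export
simulate_locus_population <- function(locus_flanks, element,
                                      class_frequencies =
                                        c(occupied = 0.4, empty = 0.3,
                                          footprint = 0.1,
                                          internal_deletion = 0.1,
                                          clustered = 0.1),
                                      n_accessions, seed = NULL,
                                      second_element = element) {
  stopifnot(length(locus_flanks) == 2L, n_accessions >= 1)
  classes <- c("occupied", "empty", "footprint", "internal_deletion",
               "clustered")
  if (!all(names(class_frequencies) %in% classes))
    stop("unknown class in frequencies: ",
         paste(setdiff(names(class_frequencies), classes), collapse = ", "))
  if (abs(sum(class_frequencies) - 1) > 1e-9)
    stop("class frequencies must sum to 1")
  left <- unname(locus_flanks[1L]); right <- unname(locus_flanks[2L])
  L <- nchar(element)
  ref_occ <- paste0(left, "TA", element, "TA", right)
  span <- c(nchar(left) + 2L, nchar(left) + 2L + L)
  with_seed(seed, {
    cls <- sample(names(class_frequencies), n_accessions, replace = TRUE,
                  prob = class_frequencies)
    haps <- character(n_accessions)
    detail <- character(n_accessions)
    for (i in seq_len(n_accessions)) {
      haps[i] <- switch(cls[i],
        occupied = ref_occ,
        empty = paste0(left, "TA", right),
        footprint = {
          k <- sample(1:10, 1L)
          if (runif(1) < 0.5) {
            detail[i] <- sprintf("insertion_%dbp", k)
            ins <- paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
            paste0(left, "TA", ins, right)
          } else {
            detail[i] <- sprintf("deletion_%dbp", k)
            paste0(left, "TA", substr(right, k + 1L, nchar(right)))
          }
        },
        internal_deletion = {
          dlen <- round(runif(1, 0.2, 0.8) * L)
          dstart <- sample.int(L - dlen + 1L, 1L) - 1L  # 0-based
          detail[i] <- sprintf("del_%d_%d", dstart, dstart + dlen)
          trunc <- paste0(substr0(element, 0L, dstart),
                          substr0(element, dstart + dlen, L))
          paste0(left, "TA", trunc, "TA", right)
        },
        clustered = {
          d <- sample(20:100, 1L)
          if (nchar(left) < d + 2L + 42L)
            stop("left flank too short for the clustered class")
          cut <- nchar(left) - d
          detail[i] <- sprintf("second_element_at_-%dbp", d)
          # the 2 bp at the chosen point are written as a TA target site
          paste0(substr(left, 1L, cut - 2L), "TA", second_element, "TA",
                 substr(left, cut + 1L, nchar(left)),
                 "TA", element, "TA", right)
        })
    }
    ids <- sprintf("acc_%03d", seq_len(n_accessions))
    list(haplotypes = setNames(haps, ids),
         truth = data.frame(accession_id = ids, class = cls,
                            detail = detail, stringsAsFactors = FALSE),
         reference_occupied = ref_occ, element_span = span)
  })
}

#' Fragment a genome into BAC-like clones with truth counts
#'
#' Draws uniform random substrings emulating a BAC library and counts how
#' many intact planted elements each clone fully contains (the quantity a
#' PCR screen with a TIR-anchored primer would detect).
#'
#' @param genome named character scalar.
#' @param truth truth ledger from [plant_insertions()].
#' @param clone_size clone length in bp (`<=` genome length).
#' @param n_clones number of clones (0 allowed).
#' @param seed integer seed (optional).
#' @param sequences if `TRUE`, include clone sequences in the result.
#' @return data.frame with `clone_id`, `start`, `end`, `n_elements`,
#'   `positive` (and `seq` if requested).
#' @export
fragment_into_clones <- function(genome, truth, clone_size, n_clones,
                                 seed = NULL, sequences = FALSE) {
  g <- unname(genome[1L])
  G <- nchar(g)
  if (clone_size > G) stop("clone_size exceeds genome length")
  if (n_clones == 0)
    return(data.frame(clone_id = character(0), start = integer(0),
                      end = integer(0), n_elements = integer(0),
                      positive = logical(0), stringsAsFactors = FALSE))
  with_seed(seed, {
    starts <- sample.int(G - clone_size + 1L, n_clones, replace = TRUE) - 1L
    intact <- truth[truth$class == "intact", , drop = FALSE]
    counts <- vapply(starts, function(s)
      sum(intact$start >= s & intact$end <= s + clone_size), 0L)
    out <- data.frame(clone_id = sprintf("clone_%04d", seq_len(n_clones)),
                      start = starts, end = starts + clone_size,
                      n_elements = counts, positive = counts > 0L,
                      stringsAsFactors = FALSE)
    if (sequences)
      out$seq <- vapply(starts, function(s) substr0(g, s, s + clone_size), "")
    out
  })
}
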