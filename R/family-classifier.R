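#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment with affine gap penalties and penalized end
#' gaps. Identity, coverage and the Kimura transition/transversion
#' proportions are tallied over columns where both rows are non-gap
#' (pairwise deletion, as in PHYLIP's dnadist).
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return an object of class `pairwise_alignment`: gapped strings
#'   `aligned_a`/`aligned_b`, `score`, `identity`, `coverage` (aligned
#'   non-gap columns over the shorter raw length), transition proportion
#'   `P` and transversion proportion `Q`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = 4,
                         gap_extend = 1) {
  a <- toupper(unname(a[1L])); b <- toupper(unname(b[1L]))
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  aln <- nw_affine_cpp(a, b, match, mismatch, gap_open, gap_extend)
  ca <- split1(aln$aligned_a); cb <- split1(aln$aligned_b)
  both <- ca != "-" & cb != "-"
  usable <- both & ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  matches <- sum(usable & ca == cb)
  purine <- c("A", "G")
  mism <- usable & ca != cb
  transitions <- sum(mism & ((ca %in% purine) == (cb %in% purine)))
  transversions <- sum(mism) - transitions
  npair <- sum(usable)
  structure(list(aligned_a = aln$aligned_a, aligned_b = aln$aligned_b,
                 score = aln$score,
                 identity = if (npair > 0) matches / npair else 0,
                 coverage = sum(both) / min(nchar(a), nchar(b)),
                 P = if (npair > 0) transitions / npair else 0,
                 Q = if (npair > 0) transversions / npair else 0,
                 n_sites = npair),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "pairwise alignment: %d columns, identity %.3f, coverage %.3f, P %.4f, Q %.4f\n",
    nchar(x$aligned_a), x$identity, x$coverage, x$P, x$Q))
  invisible(x)
}

elements_as_vector <- function(elements) {
  if (is.data.frame(elements)) {
    stopifnot(all(c("copy_id", "seq") %in% names(elements)))
    setNames(elements$seq, elements$copy_id)
  } else {
    if (is.null(names(elements)))
      names(elements) <- sprintf("element_%02d", seq_along(elements))
    elements
  }
}

#' Group elements into families by the 80-80-80 criterion
#'
#' Two elements are related when their global-alignment identity is at
#' least `min_identity` over at least `min_coverage` of the shorter
#' sequence; elements shorter than `min_length` are dropped. Families are
#' the connected components of this relation (single linkage), numbered
#' by decreasing size, ties by smallest member id.
#'
#' @param elements named character vector of element sequences, or a
#'   data.frame with `copy_id` and `seq`.
#' @param min_identity,min_coverage,min_length the 80-80-80 thresholds.
#' @return an object of class `mite_families`: list with `membership`
#'   (data.frame `element_id`, `family_id`), `families` (per-family list
#'   with `family_id`, `member_ids`, `consensus`, `mean_identity`) and
#'   `dropped` (ids below `min_length`).
#' @export
cluster_families <- function(elements, min_identity = 0.80,
                             min_coverage = 0.80, min_length = 80L) {
  seqs <- elements_as_vector(elements)
  if (length(seqs) == 0) stop("empty element set")
  dropped <- names(seqs)[nchar(seqs) < min_length]
  seqs <- seqs[nchar(seqs) >= min_length]
  if (length(seqs) == 0) stop("no element passes the length filter")
  ids <- names(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ident <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      aln <- global_align(seqs[[i]], seqs[[j]])
      ident[i, j] <- ident[j, i] <- aln$identity
      if (aln$identity >= min_identity && aln$coverage >= min_coverage) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(ids, comp)
  # deterministic numbering: descending size, then smallest member id
  key <- vapply(groups, function(g) min(g), "")
  groups <- groups[order(-lengths(groups), key)]
  membership <- data.frame(
    element_id = unlist(groups, use.names = FALSE),
    family_id = rep(sprintf("F%d", seq_along(groups)), lengths(groups)),
    stringsAsFactors = FALSE)
  membership <- membership[order(match(membership$element_id, ids)), ,
                           drop = FALSE]
  rownames(membership) <- NULL
  families <- lapply(seq_along(groups), function(k) {
    g <- sort(groups[[k]])
    mi <- if (length(g) > 1) mean(ident[g, g][upper.tri(ident[g, g])]) else 1
    list(family_id = sprintf("F%d", k), member_ids = g,
         consensus = build_consensus(seqs[g]), mean_identity = mi)
  })
  structure(list(membership = membership, families = families,
                 dropped = dropped, identity_matrix = ident),
            class = "mite_families")
}

#' @export
print.mite_families <- function(x, ...) {
  cat(sprintf("%d families over %d elements (%d dropped by length)\n",
              length(x$families), nrow(x$membership), length(x$dropped)))
  for (f in x$families)
    cat(sprintf("  %s: %d members, mean identity %.3f, consensus %d bp\n",
                f$family_id, length(f$member_ids), f$mean_identity,
                nchar(f$consensus)))
  invisible(x)
}

#' Build a family consensus by star alignment
#'
#' Members are aligned pairwise to the longest member and projected onto
#' its columns (insertions relative to the reference are discarded). Each
#' column takes the majority base; ties are written as the IUPAC
#' degenerate code covering the tied bases (e.g. T/C -> Y, A/G -> R);
#' majority-gap columns are removed.
#'
#' @param seqs named character vector of member sequences.
#' @return the consensus string (may contain IUPAC degenerate codes).
#' @export
build_consensus <- function(seqs) {
  seqs <- elements_as_vector(seqs)
  if (length(seqs) == 0) stop("empty family")
  if (length(seqs) == 1L) return(unname(seqs[[1L]]))
  ref_i <- which.max(nchar(seqs))
  ref <- toupper(seqs[[ref_i]])
  nref <- nchar(ref)
  prof <- matrix("-", nrow = length(seqs), ncol = nref)
  prof[ref_i, ] <- split1(ref)
  for (k in setdiff(seq_along(seqs), ref_i)) {
    aln <- global_align(ref, seqs[[k]])
    ca <- split1(aln$aligned_a); cb <- split1(aln$aligned_b)
    prof[k, ] <- cb[ca != "-"]  # member bases at reference columns
  }
  cols <- character(nref)
  keep <- logical(nref)
  for (j in seq_len(nref)) {
    v <- prof[, j]
    tab <- table(v)
    if (("-" %in% names(tab)) && tab[["-"]] * 2L > length(v)) next
    tab <- tab[names(tab) %in% c("A", "C", "G", "T")]
    if (length(tab) == 0) next
    best <- names(tab)[tab == max(tab)]
    cols[j] <- if (length(best) == 1L) best else iupac_code_for(best)
    keep[j] <- TRUE
  }
  paste(cols[keep], collapse = "")
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with transition proportion
#' `P` and transversion proportion `Q`. Outside the model's domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the substitution process is
#' saturated and a `k2p_saturation` error is signalled rather than NaN.
#'
#' @param x either a `pairwise_alignment` (P and Q taken from it) or the
#'   transition proportion P.
#' @param Q transversion proportion (when `x` is numeric).
#' @return the distance (substitutions per site, >= 0).
#' @export
k2p_distance <- function(x, Q = NULL) {
  if (inherits(x, "pairwise_alignment")) {
    P <- x$P; Q <- x$Q
  } else {
    P <- x
    if (is.null(Q)) stop("Q must be supplied when x is numeric")
  }
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("k2p_saturation", "error", "condition"),
                   list(message = sprintf(
                     "K2P distance saturated (P = %.4f, Q = %.4f)", P, Q),
                     call = sys.call())))
  max(0, -0.5 * log(w1 * sqrt(w2)))
}

#' Pairwise K2P distance matrix
#'
#' @param seqs named character vector of sequences.
#' @param ... passed to [global_align()].
#' @return symmetric matrix of K2P distances with zero diagonal.
#' @export
k2p_matrix <- function(seqs, ...) {
  seqs <- elements_as_vector(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- k2p_distance(global_align(seqs[[i]], seqs[[j]], ...))
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` is joined (ties broken by the
#' lexicographically smallest sorted label pair). Negative branch lengths
#' are clamped to zero with the deficit moved to the sibling branch, so
#' path lengths are preserved. On additive matrices the input distances
#' are reproduced exactly. With two taxa the single edge of length `d` is
#' represented as two branches of `d/2` (an `ape` tree cannot hold a lone
#' edge), preserving the tip-to-tip path length.
#'
#' @param dm symmetric non-negative matrix with labels and zero diagonal.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- colnames(dm)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 labels")
  if (any(dm < 0)) stop("negative distances")
  if (max(abs(dm - t(dm))) > 1e-12) stop("asymmetric distance matrix")
  if (any(abs(diag(dm)) > 1e-12)) stop("non-zero diagonal")
  fmt <- function(x) sprintf("%.15g", x)
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(dm[1, 2] / 2),
                   labels[2], fmt(dm[1, 2] / 2))
    return(ape::read.tree(text = nwk))
  }
  # active nodes: newick fragment + tie-break label (smallest leaf inside)
  frag <- labels
  tie <- labels
  d <- dm
  while (length(frag) > 3L) {
    r <- length(frag)
    R <- rowSums(d)
    qm <- (r - 2) * d - outer(R, R, `+`)
    diag(qm) <- Inf
    best <- which(qm == min(qm), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (nrow(best) > 1L) {
      keys <- apply(best, 1L, function(ij)
        paste(sort(c(tie[ij[1]], tie[ij[2]])), collapse = "\r"))
      best <- best[order(keys)[1L], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    bi <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newtie <- min(tie[i], tie[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    tie <- c(tie[keep], newtie)
    d <- d2
  }
  # final trifurcation
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- c(ba, bb, bc)
  for (k in which(b < 0)) {  # clamp, move deficit to the shortest sibling
    sib <- setdiff(1:3, k)[which.min(b[setdiff(1:3, k)])]
    b[sib] <- b[sib] + b[k]
    b[k] <- 0
  }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(b[1]), frag[2],
                 fmt(b[2]), frag[3], fmt(b[3]))
  ape::read.tree(text = nwk)
}

#' Terminal-inverted-repeat consensus across families
#'
#' Left TIRs are aligned flush at the element terminus (shorter TIRs are
#' padded on the right), each column is summarized as the IUPAC code
#' covering the observed bases, and the longest terminal run of
#' non-degenerate consensus columns is reported — the analogue of the
#' conserved CTCCCT-type TIR portion shared by Stowaway families.
#'
#' @param tirs named character vector of left-TIR sequences (one per
#'   family).
#' @return list with `table` (character matrix, families x columns),
#'   `consensus` (IUPAC string) and `conserved_terminal_run` (integer).
#' @export
tir_consensus <- function(tirs) {
  if (length(tirs) == 0 || any(is.na(tirs)) || any(nchar(tirs) == 0))
    stop("every family must expose a left-TIR sequence")
  if (is.null(names(tirs))) names(tirs) <- sprintf("F%d", seq_along(tirs))
  tirs <- toupper(tirs)
  wmax <- max(nchar(tirs))
  tab <- t(vapply(tirs, function(s) {
    ch <- split1(s)
    c(ch, rep(".", wmax - length(ch)))
  }, character(wmax)))
  consensus <- vapply(seq_len(wmax), function(j) {
    bases <- setdiff(tab[, j], ".")
    bases <- unique(unlist(IUPAC_CODES[bases]))
    iupac_code_for(bases)
  }, "")
  nondeg <- consensus %in% c("A", "C", "G", "T")
  run <- if (nondeg[1L]) which.min(c(nondeg, FALSE)) - 1L else 0L
  list(table = tab, consensus = paste(consensus, collapse = ""),
       conserved_terminal_run = as.integer(run))
}
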