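# Shared in-code fixtures: small planted genomes with ground truth.

make_planted_genome <- function(seed, n_families = 2L, copies = 5L,
                                bg_len = 60000L, divergence = 0.05,
                                indel_rate = 0.002, at = 0.65) {
  elements <- do.call(rbind, lapply(seq_len(n_families), function(f) {
    spec <- family_spec(family_id = sprintf("Fam%d", f),
                        divergence = divergence, indel_rate = indel_rate)
    generate_family(spec, copies, seed = seed + f)$copies
  }))
  bg <- generate_background(bg_len, at, seed = seed + 50L)
  planted <- plant_insertions(bg, elements, seed = seed + 99L)
  c(planted, list(background = bg, elements = elements))
}

# candidate-vs-truth matching with a small coordinate slack (indels in the
# simulated copies shift boundaries by a base or two)
truth_recovered <- function(truth, cand, tol = 5L) {
  vapply(seq_len(nrow(truth)), function(i) {
    any(cand$sequence_id == truth$sequence_id[i] &
          abs(cand$start - truth$start[i]) <= tol &
          abs(cand$end - truth$end[i]) <= tol)
  }, TRUE)
}

candidate_is_true <- function(cand, truth, tol = 5L) {
  vapply(seq_len(nrow(cand)), function(i) {
    any(truth$sequence_id == cand$sequence_id[i] &
          abs(truth$start - cand$start[i]) <= tol &
          abs(truth$end - cand$end[i]) <= tol)
  }, TRUE)
}

# independent pairwise-identity oracle built on Biostrings
oracle_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  nm <- Biostrings::nmatch(aln)
  nm / (nm + Biostrings::nmismatch(aln))
}

oracle_score <- function(a, b) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
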