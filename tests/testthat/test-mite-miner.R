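test_that("at_content counts A/T and excludes N", {
  expect_equal(at_content("ATAT"), 1.0)
  expect_equal(at_content("GCGC"), 0.0)
  expect_equal(at_content("ATGCN"), 0.5)
  expect_error(at_content(""), "empty")
})

# brute-force enumeration of nested pairings (independent oracle)
brute_max_pairs <- function(s, wobble = FALSE, min_loop = 3) {
  ch <- strsplit(toupper(s), "")[[1]]
  pairs_ok <- function(x, y) {
    wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "C" & y == "G") | (x == "G" & y == "C")
    if (wobble) wc <- wc | (x == "G" & y == "T") | (x == "T" & y == "G")
    wc
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (pairs_ok(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1, k - 1) +
                      if (k < j) rec(k + 1, j) else 0L)
    }
    best
  }
  rec(1, length(ch))
}

test_that("hairpin score equals brute-force nested pairing", {
  s <- "CCCCCTTTGGGGG"  # 5 C-G pairs possible around a TTT loop
  expect_equal(brute_max_pairs(s), 5L)
  expect_equal(hairpin_score(s), 5 / 6)
  expect_equal(hairpin_score("AAAAAAAAAA"), 0)
  # symmetry under reverse complement, plus oracle agreement on random 14-mers
  set.seed(77)
  for (i in 1:5) {
    x <- random_dna(14)
    expect_equal(hairpin_score(x), hairpin_score(revcomp(x)))
    expect_equal(hairpin_score(x) * 7, brute_max_pairs(x))
  }
  expect_error(hairpin_score("ACGTACG"), "short")
})

test_that("structural scan recovers planted elements exactly at zero divergence", {
  fix <- make_planted_genome(601, n_families = 2, copies = 5,
                             divergence = 0, indel_rate = 0)
  cand <- find_tir_candidates(fix$genome)
  expect_equal(nrow(cand), nrow(fix$truth))
  expect_setequal(paste(cand$start, cand$end),
                  paste(fix$truth$start, fix$truth$end))
  expect_true(all(cand$tsd == "TA"))
  expect_true(all(cand$tir_length >= 13))
})

test_that("a motif-free sequence yields no candidates", {
  s <- setNames(strrep("AT", 500), "flat")
  expect_equal(nrow(find_tir_candidates(s)), 0)
})

test_that("the TSD filter rejects elements whose flanking TAs are mutated", {
  bg <- generate_background(5000, 0.65, seed = 61)
  fam <- generate_family(family_spec(divergence = 0, indel_rate = 0), 1,
                         seed = 62)
  pl <- plant_insertions(bg, fam$copies, seed = 63)
  g <- pl$genome[[1]]
  s <- pl$truth$start[1]; e <- pl$truth$end[1]
  # mutate both TSDs to GG
  substr(g, s - 1, s) <- "GG"
  substr(g, e + 1, e + 2) <- "GG"
  expect_equal(nrow(find_tir_candidates(setNames(g, "mut"))), 0)
  # without the TSD requirement the element is still structurally visible
  relaxed <- find_tir_candidates(setNames(g, "mut"),
                                 mite_scan_params(require_tsd = FALSE))
  expect_equal(relaxed$start, s)
  expect_equal(relaxed$end, e)
  expect_true(is.na(relaxed$tsd[1]))
})

test_that("emitted candidates satisfy their own invariants from sequence alone", {
  fix <- make_planted_genome(701, n_families = 2, copies = 8)
  cand <- find_tir_candidates(fix$genome)
  g <- fix$genome[[1]]
  for (i in seq_len(nrow(cand))) {
    expect_lt(cand$length[i], 600)
    expect_equal(cand$end[i] - cand$start[i], cand$length[i])
    expect_equal(substr(g, cand$start[i] + 1, cand$end[i]), cand$seq[i])
    expect_equal(substr(g, cand$start[i] - 1, cand$start[i]), "TA")
    expect_equal(substr(g, cand$end[i] + 1, cand$end[i] + 2), "TA")
    # TIR reverse-complementarity within the edit budget (a bulge inside
    # the TIR costs one extra unit when both strings are cut to the same
    # length, hence budget + 1 on the equal-length edit distance)
    tl <- cand$tir_length[i]
    left <- substr(cand$seq[i], 1, tl)
    right <- substr(cand$seq[i], cand$length[i] - tl + 1, cand$length[i])
    expect_lte(as.integer(utils::adist(left, revcomp(right))), 3)
    expect_lte(cand$tir_mismatches[i], 2)
  }
})

test_that("mining is independent of record order", {
  fa <- make_planted_genome(801, n_families = 1, copies = 4, bg_len = 30000)
  fb <- make_planted_genome(802, n_families = 1, copies = 4, bg_len = 30000)
  two <- c(setNames(fa$genome[[1]], "recA"), setNames(fb$genome[[1]], "recB"))
  fwd <- find_tir_candidates(two)
  rev_ <- find_tir_candidates(two[c(2, 1)])
  key <- function(df) {
    df <- df[order(df$sequence_id, df$start), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(fwd), key(rev_))
})

test_that("homology search finds the query verbatim and nothing in background", {
  query <- generate_family(family_spec(divergence = 0, indel_rate = 0), 1,
                           seed = 91)$consensus
  db <- c(self = query)
  hit <- homology_search(query, db)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$start, 0)
  expect_equal(hit$end, nchar(query))

  # pure background: neither the seeded search nor an exhaustive local
  # alignment oracle produces a reportable hit
  bg <- generate_background(20000, 0.65, seed = 92, id = "bg")
  expect_equal(nrow(homology_search(query, bg)), 0)
  oracle <- Biostrings::pairwiseAlignment(
    query, bg[[1]], type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  q_cov <- Biostrings::nchar(Biostrings::pattern(oracle)) / nchar(query)
  expect_lt(q_cov, 0.5)  # the oracle's best local hit also fails the filter

  expect_error(homology_search("ACGTACGT", bg), "word_size")
})

test_that("homology identity agrees with the exhaustive local oracle", {
  spec <- family_spec(divergence = 0.1, indel_rate = 0)
  fam <- generate_family(spec, 1, seed = 95)
  bg <- generate_background(20000, 0.65, seed = 96)
  pl <- plant_insertions(bg, data.frame(copy_id = "c1", family_id = "F",
                                        seq = fam$copies$seq[1]), seed = 97)
  hits <- homology_search(fam$consensus, pl$genome)
  expect_equal(nrow(hits), 1)
  oracle <- Biostrings::pairwiseAlignment(
    fam$consensus, pl$genome[[1]], type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  onm <- Biostrings::nmatch(oracle)
  oid <- onm / (onm + Biostrings::nmismatch(oracle))
  expect_lt(abs(hits$identity - oid), 0.03)
  # hit interval matches the planted copy
  expect_lt(abs(hits$start - pl$truth$start), 6)
  expect_lt(abs(hits$end - pl$truth$end), 6)
})

test_that("hit validation applies the TSD/TIR/flank filters", {
  fam <- generate_family(family_spec(divergence = 0, indel_rate = 0), 1,
                         seed = 101)
  el <- fam$copies$seq[1]
  flank <- function(n, s) generate_background(n, 0.65, seed = s)[[1]]
  # 150 bp flanks: validated
  good <- setNames(paste0(flank(150, 1), "TA", el, "TA", flank(150, 2)), "g")
  h <- homology_search(fam$consensus, good)
  expect_equal(nrow(h), 1)
  expect_true(validate_hit(h[1, ], good)$validated)
  # flush against the record end: flank too short
  flush <- setNames(paste0("TA", el, "TA", flank(150, 3)), "f")
  h2 <- homology_search(fam$consensus, flush)
  expect_false(validate_hit(h2[1, ], flush)$validated)
  # TSD mutated: structural check fails
  mut <- setNames(paste0(flank(150, 4), "GG", el, "GG", flank(150, 5)), "m")
  h3 <- homology_search(fam$consensus, mut)
  expect_false(validate_hit(h3[1, ], mut)$validated)
})
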