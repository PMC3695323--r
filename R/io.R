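#' Read a FASTA file
#'
#' Multi-record, wrapped or unwrapped; sequences are upper-cased and the
#' alphabet validated (A/C/G/T/N, IUPAC codes optionally). Record ids are
#' the first whitespace-delimited header tokens.
#'
#' @param path file path.
#' @param allow_iupac accept IUPAC degenerate codes (default `FALSE`).
#' @return named character vector of sequences; full headers in the
#'   `descriptions` attribute.
#' @export
read_fasta <- function(path, allow_iupac = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  for (i in seq_along(seqs)) validate_dna(seqs[i], ids[i], allow_iupac)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

candidates_to_granges <- function(candidates) {
  gr <- GenomicRanges::GRanges(
    seqnames = candidates$sequence_id,
    ranges = IRanges::IRanges(start = candidates$start + 1L,
                              end = candidates$end),
    strand = candidates$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "stowawaykit", type = "MITE",
    ID = sprintf("MITE_%04d", seq_len(nrow(candidates))),
    tir_len = candidates$tir_length,
    tsd = ifelse(is.na(candidates$tsd), "absent", candidates$tsd),
    at_content = round(candidates$at_content, 4),
    hairpin_score = round(candidates$hairpin_score, 4))
  gr
}

#' Write MITE candidates as GFF3
#'
#' GFF3 is 1-based inclusive; internal spans are 0-based half-open and
#' converted at this boundary. Features are sorted by (seqid, start).
#'
#' @param candidates a [find_tir_candidates()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(candidates, path) {
  candidates <- candidates[order(candidates$sequence_id, candidates$start), ,
                           drop = FALSE]
  if (nrow(candidates) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- candidates_to_granges(candidates)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write MITE candidates as BED
#'
#' BED shares the package's 0-based half-open convention; no coordinate
#' shift is applied.
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(candidates, path) {
  candidates <- candidates[order(candidates$sequence_id, candidates$start), ,
                           drop = FALSE]
  if (nrow(candidates) == 0) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", candidates$sequence_id,
                   candidates$start, candidates$end,
                   sprintf("MITE_%04d", seq_len(nrow(candidates))),
                   pmin(1000L, round(1000 * candidates$at_content)),
                   candidates$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file of MITE features back into candidate spans
#'
#' @param path GFF3 path.
#' @return data.frame with `sequence_id`, `start`, `end` (0-based
#'   half-open), `strand` and any recovered attributes.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(sequence_id = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (col in c("tir_len", "tsd", "at_content", "hairpin_score"))
    if (col %in% names(mc)) df[[col]] <- mc[[col]]
  df
}

#' Write / read the planted-insertion truth ledger as TSV
#'
#' @param truth truth data.frame.
#' @param path file path.
#' @return `path` (write) or the truth data.frame (read).
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "stowawaykit-out",
    simulate = list(genome_length = 200000L, at_fraction = 0.65,
                    n_families = 3L, copies_per_family = 15L,
                    divergence = 0.05, indel_rate = 0.002),
    mine = list(terminal_motif = "CTCCCT", min_tir = 13L, max_tir = 30L,
                max_mismatch_per_tir = 2L, min_len = 80L, max_len = 600L,
                require_tsd = TRUE),
    classify = list(min_identity = 0.80, min_coverage = 0.80,
                    min_length = 80L),
    copy_number = list(clone_size = 121000L, n_clones = 141L,
                       method = "both", ci_level = 0.95),
    genotype = list(n_accessions = 50L, flank_length = 300L))
}

check_unknown_keys <- function(x, ref, path = "") {
  bad <- setdiff(names(x), names(ref))
  if (length(bad) > 0)
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(path, bad, collapse = ", "))
  for (k in names(x))
    if (is.list(ref[[k]]) && !is.null(x[[k]])) {
      if (!is.list(x[[k]])) stop("config key ", path, k, " must be a block")
      check_unknown_keys(x[[k]], ref[[k]], paste0(path, k, "."))
    }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file mirroring the per-stage parameter
#' blocks; unknown keys are rejected and missing keys take the package
#' defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged over the file values (CLI flags).
#' @return the merged configuration list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- pipeline_defaults()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check_unknown_keys(cfg, defaults)
  check_unknown_keys(overrides, defaults)
  merged <- modifyList(defaults, cfg)
  modifyList(merged, overrides)
}

log_stage <- function(con, stage, params) {
  flat <- unlist(params)
  writeLines(sprintf("[%s] %s", stage,
                     paste(names(flat), flat, sep = "=", collapse = " ")),
             con)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> mine -> classify -> copy-number -> genotype,
#' writing FASTA/GFF3/BED/TSV/newick artifacts plus a parameter log to the
#' output directory. Identical configurations produce byte-identical
#' artifacts.
#'
#' @param config configuration from [pipeline_config()].
#' @param genome optional named character vector to analyse instead of a
#'   simulated genome (the simulate stage is skipped and truth-based
#'   reports are omitted).
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), genome = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  seed <- config$seed
  truth <- NULL
  if (is.null(genome)) {
    sim <- config$simulate
    log_stage(con, "simulate", c(sim, seed = seed))
    elements <- list()
    for (f in seq_len(sim$n_families)) {
      spec <- family_spec(family_id = sprintf("SimFam%d", f),
                          divergence = sim$divergence,
                          indel_rate = sim$indel_rate)
      fam <- generate_family(spec, sim$copies_per_family,
                             seed = derive_seed(seed, f))
      elements[[f]] <- fam$copies
    }
    elements <- do.call(rbind, elements)
    bg <- generate_background(sim$genome_length, sim$at_fraction,
                              seed = derive_seed(seed, 100L), id = "sim_genome")
    planted <- plant_insertions(bg, elements, seed = derive_seed(seed, 101L))
    genome <- planted$genome
    truth <- planted$truth
    write_fasta(genome, file.path(config$out_dir, "genome.fasta"))
    write_truth_tsv(truth, file.path(config$out_dir, "truth.tsv"))
  }
  mine_p <- config$mine
  log_stage(con, "mine", mine_p)
  params <- mite_scan_params(terminal_motif = mine_p$terminal_motif,
                             min_tir = mine_p$min_tir,
                             max_tir = mine_p$max_tir,
                             max_mismatch_per_tir = mine_p$max_mismatch_per_tir,
                             min_len = mine_p$min_len,
                             max_len = mine_p$max_len,
                             require_tsd = mine_p$require_tsd)
  cand <- find_tir_candidates(genome, params)
  write_gff3(cand, file.path(config$out_dir, "candidates.gff3"))
  write_bed(cand, file.path(config$out_dir, "candidates.bed"))
  if (nrow(cand) > 0) {
    el <- setNames(cand$seq, sprintf("MITE_%04d", seq_len(nrow(cand))))
    write_fasta(el, file.path(config$out_dir, "elements.fasta"))
  }
  fams <- NULL
  tree <- NULL
  if (nrow(cand) >= 2) {
    cl <- config$classify
    log_stage(con, "classify", cl)
    el <- setNames(cand$seq, sprintf("MITE_%04d", seq_len(nrow(cand))))
    fams <- cluster_families(el, cl$min_identity, cl$min_coverage,
                             cl$min_length)
    utils::write.table(fams$membership,
                       file.path(config$out_dir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cons <- setNames(vapply(fams$families, `[[`, "", "consensus"),
                     vapply(fams$families, `[[`, "", "family_id"))
    write_fasta(cons, file.path(config$out_dir, "consensus.fasta"))
    tirs <- setNames(
      vapply(fams$families, function(f) {
        m <- cand[match(f$member_ids[1L], sprintf("MITE_%04d",
                                                  seq_len(nrow(cand)))), ]
        substr(m$seq, 1L, m$tir_length)
      }, ""),
      vapply(fams$families, `[[`, "", "family_id"))
    tc <- tir_consensus(tirs)
    utils::write.table(
      data.frame(family_id = rownames(tc$table),
                 tir = apply(tc$table, 1L, paste, collapse = ""),
                 stringsAsFactors = FALSE),
      file.path(config$out_dir, "tir_table.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    if (length(fams$families) >= 2) {
      reps <- setNames(cons, names(cons))
      tree <- neighbor_joining(k2p_matrix(reps))
      ape::write.tree(tree, file.path(config$out_dir, "families.nwk"))
    }
  }
  if (!is.null(truth)) {
    cn <- config$copy_number
    log_stage(con, "copy_number", c(cn, seed = seed))
    clones <- fragment_into_clones(genome, truth, cn$clone_size, cn$n_clones,
                                   seed = derive_seed(seed, 200L))
    screen <- bac_screen(cn$n_clones, sum(clones$positive),
                         cn$clone_size / 1e6,
                         nchar(genome[[1L]]) / 1e6)
    ests <- list()
    if (cn$method %in% c("naive", "both"))
      ests$naive <- estimate_naive(screen)
    if (cn$method %in% c("poisson", "both") &&
        screen$n_positive < screen$n_clones)
      ests$poisson <- estimate_poisson(screen)
    cn_df <- do.call(rbind, lapply(ests, function(e)
      data.frame(method = e$method, density_per_mbp = e$density_per_mbp,
                 spacing_kb = e$spacing_kb, copies = e$copies,
                 stringsAsFactors = FALSE)))
    utils::write.table(cn_df, file.path(config$out_dir, "copy_number.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- config$genotype
    log_stage(con, "genotype", c(gt, seed = seed))
    first <- truth[truth$class == "intact", ][1L, ]
    element <- substr0(genome[[1L]], first$start, first$end)
    flanks <- c(generate_background(gt$flank_length, 0.65,
                                    seed = derive_seed(seed, 300L), "left"),
                generate_background(gt$flank_length, 0.65,
                                    seed = derive_seed(seed, 301L), "right"))
    pop <- simulate_locus_population(flanks, element,
                                     n_accessions = gt$n_accessions,
                                     seed = derive_seed(seed, 302L))
    calls <- classify_locus_population(pop$reference_occupied,
                                       pop$element_span, pop$haplotypes)
    calls$locus_id <- "locus_1"
    utils::write.table(calls, file.path(config$out_dir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep_df <- polymorphism_report(calls)
    utils::write.table(rep_df,
                       file.path(config$out_dir, "polymorphism_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(genome = genome, truth = truth, candidates = cand,
                 families = fams, tree = tree))
}
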