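#' @useDynLib stowawaykit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils head modifyList
NULL

# IUPAC nucleotide codes and their base expansions
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# sorted base set ("AG") -> degenerate code ("R")
IUPAC_FROM_BASES <- local({
  keys <- vapply(IUPAC_CODES, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_CODES), keys)
})

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse complement of a DNA string
#'
#' Handles IUPAC degenerate codes (e.g. the reverse complement of the
#' Stowaway terminal motif `CTCCCT` is `AGGGAG`).
#'
#' @param x a single DNA string.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(split1(toupper(x)))
  comp <- IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) stop("non-IUPAC character in sequence")
  paste(comp, collapse = "")
}

complement_base <- function(b) unname(IUPAC_COMPLEMENT[b])

# degenerate IUPAC motif -> strict regular expression; N in the subject
# matches nothing because character classes never include N
iupac_to_regex <- function(motif) {
  ch <- split1(toupper(motif))
  bad <- setdiff(ch, names(IUPAC_CODES))
  if (length(bad) > 0)
    stop("motif contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  paste(vapply(ch, function(c) {
    ex <- IUPAC_CODES[[c]]
    if (length(ex) == 1L) ex else paste0("[", paste(ex, collapse = ""), "]")
  }, ""), collapse = "")
}

iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_FROM_BASES[key]
  if (is.na(code)) stop("cannot encode base set: ", key)
  unname(code)
}

# all 0-based start positions of a regex in a string
regex_starts0 <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# 0-based half-open substring
substr0 <- function(x, start, end) substr(x, start + 1L, end)

validate_dna <- function(x, id = "sequence", allow_iupac = FALSE) {
  ok <- if (allow_iupac) "[^ACGTRYSWKMBDHVN]" else "[^ACGTN]"
  hit <- regexpr(ok, x)
  if (hit != -1L)
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(x, hit, hit), id, as.integer(hit)))
  invisible(TRUE)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# derive a per-operation stream seed from a top-level seed, kept < 2^31
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + 12345 * k) %% 2147483647)
}

#' AT content of DNA sequences
#'
#' Fraction of A/T bases; `N` bases are excluded from both numerator and
#' denominator. Stowaway-like MITEs are characteristically AT rich
#' (roughly 0.60-0.72 in carrot).
#'
#' @param x character vector of DNA strings.
#' @return numeric vector of AT fractions in `[0, 1]`.
#' @export
at_content <- function(x) {
  stopifnot(is.character(x))
  if (any(nchar(x) == 0L)) stop("empty sequence")
  x <- toupper(x)
  n_at <- nchar(gsub("[^AT]", "", x))
  n_n <- nchar(gsub("[^N]", "", x))
  denom <- nchar(x) - n_n
  if (any(denom == 0L)) stop("sequence contains only N bases")
  n_at / denom
}
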