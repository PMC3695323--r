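#' A BAC-library PCR screen summary
#'
#' @param n_clones clones screened.
#' @param n_positive clones with an amplicon of the expected size.
#' @param mean_clone_size_mbp mean clone insert size in Mbp.
#' @param genome_size_mbp (diploid) genome size in Mbp.
#' @return object of class `bac_screen`.
#' @export
bac_screen <- function(n_clones, n_positive, mean_clone_size_mbp,
                       genome_size_mbp) {
  stopifnot(n_clones >= 1, n_positive >= 0, n_positive <= n_clones,
            mean_clone_size_mbp > 0, genome_size_mbp > 0)
  structure(list(n_clones = as.integer(n_clones),
                 n_positive = as.integer(n_positive),
                 mean_clone_size_mbp = mean_clone_size_mbp,
                 genome_size_mbp = genome_size_mbp),
            class = "bac_screen")
}

new_copy_number_estimate <- function(method, density, screen,
                                     lambda = NA_real_) {
  structure(list(method = method, density_per_mbp = density,
                 spacing_kb = if (density > 0) 1000 / density else Inf,
                 copies = screen$genome_size_mbp * density,
                 lambda = lambda, ci_low = NA_real_, ci_high = NA_real_,
                 screen = screen),
            class = "copy_number_estimate")
}

#' Naive copy-number estimate from a BAC screen
#'
#' Assumes one element per positive clone: density =
#' `n_positive / (n_clones * mean_clone_size)`, spacing = `1000 / density`
#' kb per element, copies = `genome_size * density`. With the carrot
#' DcSto1 screen (141 clones, 87 positive, 0.121 Mbp clones, 980 Mbp 2n
#' genome) this gives one element per ~196 kb and ~5,000 copies.
#'
#' @param screen a [bac_screen()].
#' @return object of class `copy_number_estimate`.
#' @export
estimate_naive <- function(screen) {
  stopifnot(inherits(screen, "bac_screen"))
  density <- screen$n_positive /
    (screen$n_clones * screen$mean_clone_size_mbp)
  new_copy_number_estimate("naive", density, screen)
}

#' Poisson-corrected copy-number estimate
#'
#' Under random insertion the number of elements per clone is Poisson with
#' mean `lambda`; a clone is negative with probability `exp(-lambda)`, so
#' `lambda = -ln(1 - n_positive/n_clones)` corrects for clones carrying
#' several elements, which the naive estimator counts once.
#'
#' @param screen a [bac_screen()].
#' @return object of class `copy_number_estimate` with `lambda` filled in.
#' @export
estimate_poisson <- function(screen) {
  stopifnot(inherits(screen, "bac_screen"))
  p <- screen$n_positive / screen$n_clones
  if (p >= 1)
    stop(structure(class = c("screen_saturation", "error", "condition"),
                   list(message = "all clones positive: Poisson estimate saturated",
                        call = sys.call())))
  lambda <- -log(1 - p)
  new_copy_number_estimate("poisson", lambda / screen$mean_clone_size_mbp,
                           screen, lambda = lambda)
}

#' Exact confidence interval for the copy number
#'
#' Clopper-Pearson interval on the positive-clone proportion, with the
#' endpoints propagated through the chosen estimator (both estimators are
#' monotone in the proportion, so endpoint propagation is exact).
#'
#' @param screen a [bac_screen()].
#' @param method `"naive"` or `"poisson"`.
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(low, high)` in copies (`high` may be `Inf`
#'   for a saturated Poisson upper endpoint).
#' @export
copies_confidence_interval <- function(screen, method = c("naive", "poisson"),
                                       level = 0.95) {
  stopifnot(inherits(screen, "bac_screen"))
  method <- match.arg(method)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  ci_p <- stats::binom.test(screen$n_positive, screen$n_clones,
                            conf.level = level)$conf.int
  to_copies <- function(p) {
    dens <- if (method == "naive") p / screen$mean_clone_size_mbp
    else if (p >= 1) Inf else -log(1 - p) / screen$mean_clone_size_mbp
    screen$genome_size_mbp * dens
  }
  c(low = to_copies(ci_p[1L]), high = to_copies(ci_p[2L]))
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("copy-number estimate (%s method)\n", x$method))
  cat(sprintf("  density : %.3f elements/Mbp\n", x$density_per_mbp))
  if (is.finite(x$spacing_kb))
    cat(sprintf("  spacing : one element per %d kb\n", round(x$spacing_kb)))
  else cat("  spacing : no elements detected\n")
  cat(sprintf("  copies  : %s per genome\n", signif(x$copies, 3)))
  if (!is.na(x$lambda))
    cat(sprintf("  lambda  : %.4f elements per clone\n", x$lambda))
  invisible(x)
}
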