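#' Genotyping-error model parameters
#'
#' Bundles the per-allele genotyping error rate `eps` with the per-window
#' false-elimination probability bounds for the two filters. `eps` is the
#' probability that a single allele in a genotype call is read incorrectly;
#' each of the two alleles of a diploid call errs independently. `p_th_major`
#' and `p_th_minor` bound, per window, the probability that genotyping errors
#' alone push a truly IBD individual above the tolerated opposite-homozygote
#' count for the Major and Minor Filter respectively; lowering them makes the
#' filter more tolerant (larger `k`), raising sensitivity at the cost of a
#' larger candidate set.
#'
#' @param eps per-allele genotyping error rate, in `[0, 0.5)`.
#' @param p_th_major,p_th_minor per-window false-elimination bounds in `(0, 1]`.
#' @return an object of class `error_params`.
#' @export
error_params <- function(eps = 0.005, p_th_major = 0.01, p_th_minor = 0.01) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps >= 0, eps < 0.5,
            p_th_major > 0, p_th_major <= 1,
            p_th_minor > 0, p_th_minor <= 1)
  structure(list(eps = eps, p_th_major = p_th_major, p_th_minor = p_th_minor),
            class = "error_params")
}

#' Probability of an observed genotype given the true genotype
#'
#' Independent per-allele flip model: each of the two alleles of a diploid
#' call is read correctly with probability `1 - eps` and flipped to the other
#' allele with probability `eps`. Genotypes are minor-allele counts in
#' `{0, 1, 2}`.
#'
#' @param t true minor-allele count (0, 1 or 2).
#' @param o observed minor-allele count (0, 1 or 2).
#' @param eps per-allele error rate.
#' @return `P(observed = o | true = t)`; vectorised over `eps`.
#' @export
obs_given_true <- function(t, o, eps) {
  stopifnot(length(t) == 1L, length(o) == 1L,
            t %in% 0:2, o %in% 0:2, all(eps >= 0), all(eps < 0.5))
  if (t == 1L) {
    # one minor + one major allele; observed count moves when exactly one flips
    if (o == 1L) (1 - eps)^2 + eps^2 else eps * (1 - eps)
  } else {
    # homozygous truth: count of flipped alleles is Binomial(2, eps)
    d <- abs(o - t)
    if (d == 0L) (1 - eps)^2 else if (d == 1L) 2 * eps * (1 - eps) else eps^2
  }
}

#' Hardy-Weinberg genotype prior
#'
#' @param f minor allele frequency in `[0, 0.5]`.
#' @return numeric vector `c(P(t=0), P(t=1), P(t=2))` =
#'   `((1-f)^2, 2f(1-f), f^2)`.
#' @export
hwe_prior <- function(f) {
  stopifnot(length(f) == 1L, f >= 0, f <= 0.5)
  c((1 - f)^2, 2 * f * (1 - f), f^2)
}

#' Probability of a false opposite-homozygous call at a selected marker
#'
#' Computes `p_e`, the probability that, at a marker selected by a filter, a
#' truly IBD indexed individual shows an opposite-homozygous genotype purely
#' through genotyping error. The generative model for an IBD-sharing pair at a
#' marker with minor allele frequency `f`: one shared allele is drawn with
#' minor probability `f`; each individual's remaining allele is an independent
#' population draw at frequency `f` (so marginal genotypes are
#' Hardy-Weinberg); all four observed alleles then flip independently with
#' probability `eps`. For the Major Filter a marker is selected when the
#' query's observed genotype is 2 (homozygous minor) and the opposite event is
#' an observed indexed genotype of 0; the Minor Filter is the mirror image.
#' Because the pair shares a true allele, every such observed opposite
#' homozygote is a false rejection, so
#' `p_e = P(o_indexed = opposite | o_query = selected)` under the model.
#'
#' @param kind `"major"` or `"minor"`.
#' @param f minor allele frequency; may be a vector.
#' @param eps per-allele genotyping error rate.
#' @return `p_e`, same length as `f`.
#' @export
false_opphom_prob <- function(kind = c("major", "minor"), f, eps) {
  kind <- match.arg(kind)
  stopifnot(all(f >= 0 & f <= 0.5), length(eps) == 1L, eps >= 0, eps < 0.5)
  o_q <- if (kind == "major") 2L else 0L
  o_x <- if (kind == "major") 0L else 2L
  # P(observed | shared allele h), integrating the individual's population
  # allele (minor w.p. f); h = 1 means the shared allele is minor
  mix <- function(h, o) {
    f * obs_given_true(h + 1L, o, eps) + (1 - f) * obs_given_true(h + 0L, o, eps)
  }
  num <- f * mix(1L, o_q) * mix(1L, o_x) + (1 - f) * mix(0L, o_q) * mix(0L, o_x)
  den <- f^2       * obs_given_true(2L, o_q, eps) +
    2 * f * (1 - f) * obs_given_true(1L, o_q, eps) +
    (1 - f)^2       * obs_given_true(0L, o_q, eps)
  ifelse(den > 0, num / den, 0)
}

#' Solve for the per-window error tolerance k
#'
#' Treating the number of error-induced opposite-homozygous markers among the
#' `c` selected markers of a window as `Binomial(c, p_e)`, returns the
#' smallest integer `k >= 0` such that the probability of observing more than
#' `k` of them is at most `p_th`. Individuals with more than `k` observed
#' opposite homozygotes in the window are eliminated.
#'
#' @param c number of selected markers in the window (vectorised).
#' @param p_e per-marker false opposite-homozygote probability (vectorised).
#' @param p_th per-window false-elimination bound in `(0, 1]`.
#' @return integer vector of tolerances, `0 <= k <= c`.
#' @export
solve_tolerance <- function(c, p_e, p_th) {
  stopifnot(all(c >= 0), all(p_e >= 0), all(p_e <= 1), p_th > 0, p_th <= 1)
  n <- max(length(c), length(p_e))
  c <- rep_len(as.integer(c), n)
  p_e <- rep_len(p_e, n)
  # smallest k with CDF(k) >= 1 - p_th, i.e. P(X > k) <= p_th
  k <- as.integer(qbinom(1 - p_th, c, p_e))
  k[c == 0L | p_e == 0] <- 0L
  k
}

#' Per-window error tolerance from the selected markers' allele frequencies
#'
#' Fixes a single conservative minor allele frequency for the whole window --
#' the minimum selected-marker MAF for the Major Filter and the maximum for
#' the Minor Filter, the direction in each case that maximises `p_e` and hence
#' the tolerance -- then computes `p_e` and the binomial tolerance `k`.
#'
#' @param kind `"major"` or `"minor"`.
#' @param selected_mafs MAFs of the markers selected in the window (possibly
#'   empty).
#' @param params an [error_params()] object.
#' @return list with elements `c`, `f_fixed`, `p_e`, `k`.
#' @export
window_tolerance <- function(kind = c("major", "minor"), selected_mafs, params) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "error_params"))
  cc <- length(selected_mafs)
  if (cc == 0L) {
    return(list(c = 0L, f_fixed = NA_real_, p_e = 0, k = 0L))
  }
  f_fixed <- if (kind == "major") min(selected_mafs) else max(selected_mafs)
  p_e <- false_opphom_prob(kind, f_fixed, params$eps)
  p_th <- if (kind == "major") params$p_th_major else params$p_th_minor
  list(c = cc, f_fixed = f_fixed, p_e = p_e,
       k = solve_tolerance(cc, p_e, p_th))
}
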