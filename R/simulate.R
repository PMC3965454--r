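#' Synthetic cohort configuration
#'
#' Describes the simulated SNP panel and query-generation protocol used for
#' testing and calibration in place of real genotyping-array cohorts:
#' markers placed uniformly along a genetic map, per-marker minor allele
#' frequencies drawn from a uniform spectrum, haplotypes drawn under
#' Hardy-Weinberg with an optional first-order linkage-disequilibrium knob,
#' query individuals assembled as mosaics of short composite-haplotype
#' blocks, one injected IBD segment per query, and per-allele genotyping
#' errors in the query.
#'
#' @param n number of indexed individuals.
#' @param m number of biallelic markers.
#' @param length_cm chromosome genetic length in cM.
#' @param chrom chromosome label.
#' @param maf_min,maf_max bounds of the uniform MAF spectrum.
#' @param rho first-order LD parameter in `[0, 1)`: probability that a
#'   haplotype's latent frequency quantile carries over to the next marker
#'   (0 = linkage equilibrium).
#' @param seg_cm composite-haplotype block length in cM (default 0.2).
#' @param ibd_cm injected IBD segment length in cM (default 4).
#' @param eps_sim per-allele genotyping error rate applied to query
#'   haplotypes.
#' @param n_queries number of query individuals per experiment.
#' @param seed master random seed (mandatory for reproducibility).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 500, m = 5000, length_cm = 180, chrom = "1",
                       maf_min = 0.05, maf_max = 0.5, rho = 0,
                       seg_cm = 0.2, ibd_cm = 4, eps_sim = 0.005,
                       n_queries = 500, seed = 1L) {
  stopifnot(n >= 1, m >= 2, length_cm > 0,
            maf_min >= 0, maf_max <= 0.5, maf_min <= maf_max,
            rho >= 0, rho < 1, seg_cm > 0, ibd_cm > 0, ibd_cm <= length_cm,
            eps_sim >= 0, eps_sim < 0.5, n_queries >= 1,
            is.numeric(seed), length(seed) == 1L, !is.na(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genotype panel with known haplotypes
#'
#' Marker positions are drawn uniformly on `[0, length_cm]` and sorted;
#' per-marker MAFs come from the configured uniform spectrum. Each of the
#' `2n` haplotypes is generated marker by marker through a latent-quantile
#' chain: with probability `rho` a haplotype reuses its previous marker's
#' latent uniform draw, otherwise it draws afresh, and the allele is minor
#' whenever the latent value falls below the marker's MAF. Marginal allele
#' frequencies therefore match the drawn MAF exactly while `rho` controls
#' adjacent-marker correlation. Genotypes are haplotype-pair sums, and the
#' coding is re-oriented so `maf <= 0.5` holds for the realized frequencies.
#'
#' @param config a [sim_config()].
#' @return list with `haplotypes` (`2n x m` 0/1 matrix, rows `2i-1` and `2i`
#'   belonging to individual `i`), `panel` ([genotype_panel()]), `map`
#'   ([marker_map()] with realized MAFs) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m
  n <- config$n
  cm <- sort(runif(m, 0, config$length_cm))
  bp <- as.integer(cummax(as.integer(round(cm * 1e6))) + seq_len(m))
  f <- runif(m, config$maf_min, config$maf_max)
  nh <- 2L * n
  hap <- matrix(0L, nh, m)
  u <- runif(nh)
  hap[, 1] <- as.integer(u < f[1])
  if (m > 1L) {
    for (j in 2:m) {
      fresh <- runif(nh)
      keep <- runif(nh) < config$rho
      u <- ifelse(keep, u, fresh)
      hap[, j] <- as.integer(u < f[j])
    }
  }
  # orient so the counted allele is the realized minor allele
  freq <- colMeans(hap)
  flip <- freq > 0.5
  if (any(flip)) hap[, flip] <- 1L - hap[, flip]
  geno <- hap[seq(1, nh, by = 2), , drop = FALSE] +
    hap[seq(2, nh, by = 2), , drop = FALSE]
  ids <- sprintf("I%04d", seq_len(n))
  panel <- genotype_panel(ids, geno)
  map <- marker_map(sprintf("M%05d", seq_len(m)), config$chrom, bp, cm,
                    major_allele = "A", minor_allele = "B")
  st <- compute_allele_stats(panel, map)
  list(haplotypes = hap, panel = st$panel, map = st$map, config = config)
}

#' Build composite (mosaic) query haplotypes
#'
#' Partitions the genetic map into consecutive blocks of `seg_cm` cM and
#' fills each block of each composite haplotype by copying the alleles of one
#' uniformly chosen base haplotype. The mosaics of the two composite
#' haplotypes are drawn independently. This breaks any latent long-range
#' sharing between the query and the panel while preserving local allele and
#' LD structure.
#'
#' @param haplotypes base haplotype matrix (`2n x m`).
#' @param map the panel's [marker_map()].
#' @param seg_cm block length in cM.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return list with `haplotypes` (`2 x m`), `blocks` (block id per marker)
#'   and `provenance` (`2 x n_blocks` matrix of source haplotype rows).
#' @export
make_composite_haplotypes <- function(haplotypes, map, seg_cm = 0.2,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(haplotypes) >= 1L, ncol(haplotypes) == nrow(map))
  m <- nrow(map)
  blocks <- integer(m)
  off <- 0L
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    v <- map$cm[sel]
    b <- pmin(floor((v - min(v)) / seg_cm), # last marker lands in final block
              max(floor((max(v) - min(v) - 1e-12) / seg_cm), 0))
    blocks[sel] <- as.integer(b) + 1L + off
    off <- off + max(as.integer(b)) + 1L
  }
  nb <- max(blocks)
  prov <- matrix(sample.int(nrow(haplotypes), 2L * nb, replace = TRUE), 2L, nb)
  comp <- rbind(haplotypes[cbind(prov[1, blocks], seq_len(m))],
                haplotypes[cbind(prov[2, blocks], seq_len(m))])
  storage.mode(comp) <- "integer"
  list(haplotypes = comp, blocks = blocks, provenance = prov)
}

#' Inject one IBD segment into a query individual
#'
#' Copies one haplotype of a uniformly chosen indexed individual over the
#' query's first haplotype on all markers within a uniformly placed `L`-cM
#' interval, making the pair IBD there by construction.
#'
#' @param query_haps `2 x m` query haplotype matrix.
#' @param haplotypes panel haplotype matrix (`2n x m`).
#' @param map the panel's [marker_map()].
#' @param L segment length in cM.
#' @param ids panel individual ids (for the truth record).
#' @param seed optional seed.
#' @return list with modified `query_haps` and `truth` (a one-row data.frame
#'   with `indexed_id`, `hap`, `chrom`, `start_cm`, `end_cm`).
#' @export
inject_ibd <- function(query_haps, haplotypes, map, L, ids = NULL,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spans <- vapply(unique(map$chrom), function(ch) {
    v <- map$cm[map$chrom == ch]
    max(v) - min(v)
  }, numeric(1))
  ok <- names(spans)[spans >= L]
  if (length(ok) == 0L) {
    stop("IBD length ", L, " cM exceeds every chromosome's mapped span")
  }
  ch <- if (length(ok) == 1L) ok else
    sample(ok, 1L, prob = spans[ok] - L + 1e-9)
  v <- map$cm[map$chrom == ch]
  start <- runif(1, min(v), max(v) - L)
  n <- nrow(haplotypes) / 2L
  ind <- sample.int(n, 1L)
  hap_idx <- sample.int(2L, 1L)
  src <- 2L * (ind - 1L) + hap_idx
  idx <- which(map$chrom == ch & map$cm >= start & map$cm < start + L)
  query_haps[1L, idx] <- haplotypes[src, idx]
  truth <- data.frame(
    indexed_id = if (is.null(ids)) as.character(ind) else ids[ind],
    ind = ind, hap = hap_idx, chrom = ch,
    start_cm = start, end_cm = start + L, stringsAsFactors = FALSE)
  list(query_haps = query_haps, truth = truth)
}

#' Apply per-allele genotyping errors to haplotypes
#'
#' Every allele flips independently with probability `eps_sim`; flipping acts
#' at the allele level, so a heterozygous genotype can become either
#' homozygote.
#'
#' @param haplotypes 0/1 haplotype matrix.
#' @param eps_sim per-allele error rate in `[0, 0.5)`.
#' @param seed optional seed.
#' @return haplotype matrix with errors applied.
#' @export
inject_errors <- function(haplotypes, eps_sim, seed = NULL) {
  stopifnot(eps_sim >= 0, eps_sim < 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (eps_sim == 0) return(haplotypes)
  flip <- matrix(runif(length(haplotypes)) < eps_sim, nrow(haplotypes))
  out <- haplotypes
  out[flip] <- 1L - out[flip]
  out
}

#' Simulate query individuals with injected IBD segments
#'
#' Implements the full query protocol: per query, two composite haplotypes
#' are assembled from `seg_cm` blocks of the panel's haplotypes, one `L`-cM
#' IBD segment is injected from a random indexed haplotype, genotyping errors
#' are applied to the query's haplotypes, and the unphased genotypes are
#' returned. Deterministic given `seed` (child seeds are derived from the
#' master seed by a fixed counter scheme, one per query).
#'
#' @param sim a [simulate_panel()] result.
#' @param n_queries number of queries (defaults to the config value).
#' @param L injected IBD length in cM (defaults to the config value).
#' @param eps_sim per-allele error rate (defaults to the config value).
#' @param seed master seed (defaults to `config$seed + 1`).
#' @return list with `queries` (`n_queries x m` genotype matrix, rows named
#'   by query id) and `truths` (data.frame of injected-segment records).
#' @export
simulate_queries <- function(sim, n_queries = NULL, L = NULL, eps_sim = NULL,
                             seed = NULL) {
  config <- sim$config
  if (is.null(n_queries)) n_queries <- config$n_queries
  if (is.null(L)) L <- config$ibd_cm
  if (is.null(eps_sim)) eps_sim <- config$eps_sim
  if (is.null(seed)) seed <- config$seed + 1L
  m <- ncol(sim$haplotypes)
  queries <- matrix(NA_integer_, n_queries, m)
  truths <- vector("list", n_queries)
  ids <- sprintf("Q%05d", seq_len(n_queries))
  for (q in seq_len(n_queries)) {
    set.seed((seed + 131L * q) %% .Machine$integer.max)
    comp <- make_composite_haplotypes(sim$haplotypes, sim$map, config$seg_cm)
    inj <- inject_ibd(comp$haplotypes, sim$haplotypes, sim$map, L,
                      ids = sim$panel$ids)
    noisy <- inject_errors(inj$query_haps, eps_sim)
    queries[q, ] <- noisy[1L, ] + noisy[2L, ]
    truths[[q]] <- cbind(query_id = ids[q], inj$truth,
                         stringsAsFactors = FALSE)
  }
  rownames(queries) <- ids
  list(queries = queries, truths = do.call(rbind, truths))
}

#' Simulate d-th cousin queries
#'
#' A pair of d-th cousins is separated by `2(d + 1)` meioses, so the expected
#' length of a co-inherited segment is `100 / (2(d + 1))` cM. Each query gets
#' one injected segment of that length, and the recommended window size
#' follows the rule `w = L - s`, rounded up to the closest half cM.
#'
#' @param degree cousin degree `d >= 1`.
#' @param sim a [simulate_panel()] result.
#' @param n_queries,eps_sim,seed as in [simulate_queries()].
#' @param step_cm step size `s` used to derive the window size (default 0.5).
#' @return list with `queries`, `truths`, the segment length `L` and a
#'   [query_params()] object with the derived window settings.
#' @export
simulate_cousin_queries <- function(degree, sim, n_queries = NULL,
                                    eps_sim = NULL, seed = NULL,
                                    step_cm = 0.5) {
  stopifnot(degree >= 1)
  L <- 100 / (2 * (degree + 1))
  w <- ceiling((L - step_cm) * 2) / 2
  res <- simulate_queries(sim, n_queries = n_queries, L = L,
                          eps_sim = eps_sim, seed = seed)
  params <- query_params(window_cm = w, step_cm = step_cm, target_cm = L,
                         error = error_params())
  c(res, list(L = L, params = params))
}
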