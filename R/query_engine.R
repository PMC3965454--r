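#' Query parameters for the sliding-window scan
#'
#' @param window_cm window size `w` in cM (default 3.5). The window is a
#'   lower bound on the detectable IBD length.
#' @param step_cm step size `s` in cM between consecutive windows
#'   (default 0.5).
#' @param target_cm target IBD segment length `L` in cM (default 4). Each
#'   surviving window is extended by `L - w` cM on both sides, the region in
#'   which an IBD segment fully containing the window may end.
#' @param use_pruning drop Jaccard-redundant markers at query time
#'   (default `TRUE`); switching it off maximises pruning power at the cost
#'   of examining more markers.
#' @param error an [error_params()] object.
#' @param filters which filters to apply; both by default. A window's
#'   survivors must pass every enabled filter.
#' @return an object of class `query_params`.
#' @export
query_params <- function(window_cm = 3.5, step_cm = 0.5, target_cm = 4.0,
                         use_pruning = TRUE, error = error_params(),
                         filters = c("major", "minor")) {
  stopifnot(step_cm > 0, step_cm <= window_cm, window_cm < target_cm,
            inherits(error, "error_params"),
            length(filters) >= 1L, all(filters %in% c("major", "minor")))
  structure(list(window_cm = window_cm, step_cm = step_cm,
                 target_cm = target_cm, use_pruning = isTRUE(use_pruning),
                 error = error, filters = unique(filters)),
            class = "query_params")
}

#' Plan sliding windows along the genome
#'
#' Windows of size `w` start at each chromosome's first marker and advance by
#' `s` while they fit before the last marker; a final window anchored at
#' `last - w` is appended when the regular grid does not already end there,
#' so the chromosome tail is always covered. A chromosome whose cM span is
#' below `w` gets a single window covering the whole span. Intervals are
#' half-open `[start, end)` except the last window of each chromosome, which
#' is closed on the right so the final marker is reachable.
#'
#' @param map a [marker_map()] (or a `filter_index`, which carries the same
#'   coordinates).
#' @param w,s window and step size in cM.
#' @return data.frame with columns `chrom`, `start`, `end`, `closed_right`.
#' @export
plan_windows <- function(map, w, s) {
  stopifnot(w > 0, s > 0)
  chrom <- map$chrom
  cm <- map$cm
  out <- list()
  for (ch in unique(chrom)) {
    v <- cm[chrom == ch]
    lo <- min(v)
    hi <- max(v)
    span <- hi - lo
    if (span <= w) {
      starts <- lo
      ends <- hi
    } else {
      nstep <- floor((span - w) / s + 1e-9)
      starts <- lo + s * (0:nstep)
      tail_start <- hi - w
      if (tail_start > starts[length(starts)] + 1e-9) {
        starts <- c(starts, tail_start)
      }
      ends <- starts + w
    }
    k <- length(starts)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            closed_right = c(rep(FALSE, k - 1L), TRUE),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# positions (1-based, inclusive) of the sorted values `v` falling inside a
# window; closed=TRUE includes the right endpoint
window_range <- function(v, start, end, closed) {
  lo <- findInterval(start, v, left.open = TRUE) + 1L
  hi <- if (closed) findInterval(end, v) else findInterval(end, v, left.open = TRUE)
  c(lo, hi)
}

#' Select the query's filter markers within a window
#'
#' Major Filter: markers where the query's observed genotype is 2 (homozygous
#' minor), excluding low-MAF markers; the filter then rejects indexed
#' individuals homozygous major there. Minor Filter: markers where the query
#' is homozygous major (genotype 0). Under pruning, only the first in-window
#' marker of each Jaccard label contributes.
#'
#' @param query integer vector of the query's minor-allele counts, on the
#'   index's marker set and allele coding.
#' @param window one row of [plan_windows()] output (or a list with `chrom`,
#'   `start`, `end`, `closed_right`).
#' @param index a `filter_index`.
#' @param kind `"major"` or `"minor"`.
#' @param use_pruning apply first-per-label pruning.
#' @return integer vector of marker indices, in map order.
#' @export
select_markers <- function(query, window, index, kind = c("major", "minor"),
                           use_pruning = TRUE) {
  kind <- match.arg(kind)
  stopifnot(length(query) == index$m)
  g <- if (kind == "major") 2L else 0L
  in_chrom <- index$chrom == window$chrom
  rng <- window_range(index$cm[in_chrom], window$start, window$end,
                      isTRUE(window$closed_right))
  sel <- logical(index$m)
  pos <- which(in_chrom)
  if (rng[1] <= rng[2]) sel[pos[rng[1]:rng[2]]] <- TRUE
  sel <- sel & !is.na(query) & query == g
  if (kind == "major") sel <- sel & !index$low_maf_excluded
  sel <- which(sel)
  if (use_pruning && length(sel) > 1L) {
    lab <- if (kind == "major") index$label_major[sel] else index$label_minor[sel]
    sel <- sel[c(TRUE, lab[-1] != lab[-length(lab)])]
  }
  sel
}

#' Scan one window against the index (reference implementation)
#'
#' Counts, for every indexed individual, the selected markers at which it is
#' an observed opposite homozygote, and keeps the individuals whose count is
#' within tolerance for every enabled filter. This is the straightforward
#' per-window computation; [run_query()] produces identical results through a
#' batched kernel.
#'
#' @param window one row of [plan_windows()] output.
#' @param selections list with marker-index vectors `major` and `minor` (as
#'   from [select_markers()]).
#' @param index a `filter_index`.
#' @param tolerances list with elements `major` and `minor` as returned by
#'   [window_tolerance()].
#' @param filters filters to enforce.
#' @return list with the window, per-filter counts, tolerances and the
#'   surviving individual indices.
#' @export
scan_window <- function(window, selections, index, tolerances,
                        filters = c("major", "minor")) {
  counts_major <- as.integer(
    rowSums(index$hom_major[, selections$major, drop = FALSE]))
  counts_minor <- as.integer(
    rowSums(index$hom_minor[, selections$minor, drop = FALSE]))
  keep <- rep(TRUE, index$n)
  if ("major" %in% filters) keep <- keep & counts_major <= tolerances$major$k
  if ("minor" %in% filters) keep <- keep & counts_minor <= tolerances$minor$k
  list(window = window, counts_major = counts_major,
       counts_minor = counts_minor, tolerances = tolerances,
       survivors = which(keep))
}

#' Update opposite-homozygote counters when the window slides
#'
#' Rather than recounting from scratch, the counts of the previous window are
#' adjusted by subtracting the contribution of markers that leave the window
#' and adding that of markers that enter it. The result is identical to a
#' fresh [scan_window()] count. Per-window tolerances are always recomputed
#' (the selected-marker count and conservative MAF change with the window).
#'
#' @param counters integer per-individual counts from the previous window.
#' @param index a `filter_index`.
#' @param kind `"major"` or `"minor"` (which homozygote sets to use).
#' @param leaving,entering marker indices leaving/entering the selection.
#' @return updated integer counters.
#' @export
slide_update <- function(counters, index, kind = c("major", "minor"),
                         leaving = integer(0), entering = integer(0)) {
  kind <- match.arg(kind)
  H <- if (kind == "major") index$hom_major else index$hom_minor
  out <- counters -
    as.integer(rowSums(H[, leaving, drop = FALSE])) +
    as.integer(rowSums(H[, entering, drop = FALSE]))
  if (any(out < 0L)) stop("negative counter after slide update: counters do ",
                          "not correspond to the previous window's selection")
  out
}

#' Extend a surviving window to the full candidate interval
#'
#' An IBD segment of length `L >= w` that fully contains the window `[a, b)`
#' can end anywhere within `L - w` cM of either window edge, so the reported
#' candidate interval is `(a - (L - w), b + (L - w))`, clamped to the
#' chromosome's mapped cM range.
#'
#' @param window one row of [plan_windows()] output.
#' @param target_cm target IBD length `L`.
#' @param w window size (defaults to the window's own width).
#' @param chrom_range optional `c(lo, hi)` cM bounds for clamping.
#' @return numeric `c(start, end)` in cM.
#' @export
extend_window <- function(window, target_cm, w = window$end - window$start,
                          chrom_range = NULL) {
  e <- target_cm - w
  if (e < 0) stop("target_cm must be at least the window size")
  out <- c(window$start - e, window$end + e)
  if (!is.null(chrom_range)) {
    out[1] <- max(out[1], chrom_range[1])
    out[2] <- min(out[2], chrom_range[2])
  }
  out
}

# chromosome cM bounds of the indexed map, as a named list
chrom_ranges <- function(index) {
  lv <- unique(index$chrom)
  setNames(lapply(lv, function(ch) range(index$cm[index$chrom == ch])), lv)
}

# total mapped genetic length (cM) summed over chromosomes
total_genetic_length <- function(index) {
  sum(vapply(chrom_ranges(index), function(r) r[2] - r[1], numeric(1)))
}

#' Per-window opposite-homozygote counts for a query
#'
#' Runs the full sliding-window count for both filters in one pass and
#' returns everything that depends on the query but not on the error
#' thresholds: per-window per-individual counts, the contributing marker
#' count `c`, the conservative fixed MAF and the per-marker false
#' opposite-homozygote probability `p_e`. Threshold sweeps reuse this object
#' via [candidate_segments()] without rescanning the genome.
#'
#' @param query integer vector of minor-allele counts on the index's markers.
#' @param index a `filter_index`.
#' @param params a [query_params()] object.
#' @return an object of class `query_counts`.
#' @export
scan_query_counts <- function(query, index, params = query_params()) {
  stopifnot(inherits(index, "filter_index"), inherits(params, "query_params"))
  if (length(query) != index$m) {
    stop("query has ", length(query), " markers but the index has ", index$m)
  }
  windows <- plan_windows(index, params$window_cm, params$step_cm)
  chrom_levels <- unique(index$chrom)
  chrom_id <- match(windows$chrom, chrom_levels)
  W <- nrow(windows)

  one_kind <- function(kind) {
    g <- if (kind == "major") 2L else 0L
    keep <- !is.na(query) & query == g
    if (kind == "major") keep <- keep & !index$low_maf_excluded
    sel <- which(keep)
    lab <- if (!params$use_pruning) seq_along(sel)
           else if (kind == "major") index$label_major[sel]
           else index$label_minor[sel]
    win_lo <- integer(W)
    win_hi <- integer(W)
    sel_chrom <- index$chrom[sel]
    sel_cm <- index$cm[sel]
    wchrom <- windows$chrom
    wstart <- windows$start
    wend <- windows$end
    wclosed <- windows$closed_right
    for (ch in chrom_levels) {
      wrows <- which(wchrom == ch)
      in_ch <- which(sel_chrom == ch)
      base <- if (length(in_ch)) in_ch[1] - 1L else 0L
      v <- sel_cm[in_ch]
      lo <- findInterval(wstart[wrows], v, left.open = TRUE) + 1L
      hi_open <- findInterval(wend[wrows], v, left.open = TRUE)
      hi_closed <- findInterval(wend[wrows], v)
      win_lo[wrows] <- base + lo
      win_hi[wrows] <- base + ifelse(wclosed[wrows], hi_closed, hi_open)
    }
    # Major Filter counts indexed hom-major individuals at query hom-minor
    # markers; the Minor Filter is the mirror image
    H <- if (kind == "major") index$hom_major else index$hom_minor
    res <- cpp_window_counts(H, sel - 1L, lab, win_lo - 1L,
                             win_hi - 1L, index$maf[sel],
                             use_min = (kind == "major"),
                             prune = params$use_pruning)
    p_e <- rep(0, W)
    nz <- res$c > 0L
    if (any(nz)) {
      p_e[nz] <- false_opphom_prob(kind, res$f_fixed[nz], params$error$eps)
    }
    list(sel = sel, counts = res$counts, c = res$c,
         f_fixed = res$f_fixed, p_e = p_e)
  }

  structure(list(
    windows = windows, chrom_id = chrom_id, chrom_levels = chrom_levels,
    major = one_kind("major"), minor = one_kind("minor"),
    n = index$n, params = params
  ), class = "query_counts")
}

# extended + clamped window bounds for a query_counts object
extended_bounds <- function(qc, index) {
  e <- qc$params$target_cm - qc$params$window_cm
  rng <- chrom_ranges(index)
  lo <- vapply(rng, `[`, numeric(1), 1)[qc$windows$chrom]
  hi <- vapply(rng, `[`, numeric(1), 2)[qc$windows$chrom]
  list(start = pmax(qc$windows$start - e, lo),
       end = pmin(qc$windows$end + e, hi))
}

#' Candidate segments from precomputed window counts
#'
#' Applies per-window binomial tolerances for the given thresholds to the
#' counts in a `query_counts` object, extends each surviving window by
#' `target_cm - window_cm` on both sides and merges overlapping or touching
#' intervals per indexed individual.
#'
#' @param qc a `query_counts` from [scan_query_counts()].
#' @param index the `filter_index` the counts were computed against.
#' @param p_th_major,p_th_minor per-window false-elimination bounds;
#'   default to the values in `qc$params$error`.
#' @param filters filters to enforce (default from `qc$params`).
#' @param focal `NULL` to collect merged intervals for every individual, or
#'   one individual index to collect only theirs (faster for scoring).
#' @return list with `cand_cm` (per-individual candidate cM),
#'   `segments` (data.frame `ind`, `chrom`, `start_cm`, `end_cm`) and
#'   `candidate_fraction`.
#' @export
candidate_segments <- function(qc, index, p_th_major = NULL, p_th_minor = NULL,
                               filters = NULL, focal = NULL) {
  stopifnot(inherits(qc, "query_counts"))
  if (is.null(p_th_major)) p_th_major <- qc$params$error$p_th_major
  if (is.null(p_th_minor)) p_th_minor <- qc$params$error$p_th_minor
  if (is.null(filters)) filters <- qc$params$filters
  k_major <- solve_tolerance(qc$major$c, qc$major$p_e, p_th_major)
  k_minor <- solve_tolerance(qc$minor$c, qc$minor$p_e, p_th_minor)
  ext <- extended_bounds(qc, index)
  focal_arg <- if (is.null(focal)) -2L else as.integer(focal) - 1L
  res <- cpp_candidate_segments(
    qc$major$counts, qc$minor$counts, k_major, k_minor,
    use_major = "major" %in% filters, use_minor = "minor" %in% filters,
    ext_start = ext$start, ext_end = ext$end,
    chrom_id = qc$chrom_id, focal = focal_arg)
  segments <- data.frame(ind = res$ind,
                         chrom = qc$chrom_levels[res$chrom_id],
                         start_cm = res$start_cm, end_cm = res$end_cm,
                         stringsAsFactors = FALSE)
  list(cand_cm = res$cand_cm, segments = segments,
       k_major = k_major, k_minor = k_minor,
       candidate_fraction = sum(res$cand_cm) /
         (qc$n * total_genetic_length(index)))
}

#' Run the opposite-homozygosity filter for one query individual
#'
#' Slides the window along the genome, applies the Major and Minor Filters
#' with per-window error tolerances, extends surviving windows and merges
#' them into candidate segments per indexed individual.
#'
#' @param query integer vector of the query's minor-allele counts on the
#'   index's marker set and allele coding (see [align_query()]).
#' @param index a `filter_index`.
#' @param params a [query_params()] object.
#' @param query_id identifier recorded in the report.
#' @return an object of class `candidate_report`: `query_id`, `segments`
#'   (data.frame with `indexed_id`, `chrom`, `start_cm`, `end_cm`,
#'   `start_bp`, `end_bp`), `candidate_fraction` and the parameters used.
#' @export
run_query <- function(query, index, params = query_params(),
                      query_id = "query") {
  qc <- scan_query_counts(query, index, params)
  res <- candidate_segments(qc, index)
  seg <- res$segments
  out <- data.frame(indexed_id = index$ids[seg$ind],
                    chrom = seg$chrom,
                    start_cm = seg$start_cm, end_cm = seg$end_cm,
                    start_bp = NA_integer_, end_bp = NA_integer_,
                    stringsAsFactors = FALSE)
  for (ch in unique(out$chrom)) {
    rows <- out$chrom == ch
    mk <- index$chrom == ch
    out$start_bp[rows] <- as.integer(round(
      approx(index$cm[mk], index$bp[mk], xout = out$start_cm[rows],
             rule = 2, ties = "ordered")$y))
    out$end_bp[rows] <- as.integer(round(
      approx(index$cm[mk], index$bp[mk], xout = out$end_cm[rows],
             rule = 2, ties = "ordered")$y))
  }
  structure(list(
    query_id = query_id,
    segments = out,
    candidate_fraction = res$candidate_fraction,
    params = list(window_cm = params$window_cm, step_cm = params$step_cm,
                  target_cm = params$target_cm,
                  use_pruning = params$use_pruning,
                  filters = params$filters,
                  eps = params$error$eps,
                  p_th_major = params$error$p_th_major,
                  p_th_minor = params$error$p_th_minor,
                  J_th = index$J_th, maf_cutoff = index$maf_cutoff)
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> query %s: %d segments over %d individuals, candidate fraction %.4g\n",
              x$query_id, nrow(x$segments),
              length(unique(x$segments$indexed_id)), x$candidate_fraction))
  invisible(x)
}

#' Map a query panel onto an index's marker set and allele coding
#'
#' The query must be genotyped on exactly the index's markers (same ids, same
#' order). Genotypes are re-oriented marker by marker: where the query map's
#' major/minor assignment is swapped relative to the index, counts are
#' flipped (`g -> 2 - g`); a query allele pair that does not match the
#' index's alleles is an error.
#'
#' @param panel query [genotype_panel()].
#' @param map the query's [marker_map()].
#' @param index the `filter_index` to align to.
#' @return integer genotype matrix (queries x markers) on the index coding.
#' @export
align_query <- function(panel, map, index) {
  if (nrow(map) != index$m) {
    stop("query marker set does not match the index: ", nrow(map),
         " query markers vs ", index$m, " indexed markers")
  }
  if (!identical(as.character(map$marker_id), as.character(index$marker_id))) {
    mism <- which(as.character(map$marker_id) != as.character(index$marker_id))[1]
    stop("query marker set does not match the index: first mismatch at ",
         "position ", mism, " (", map$marker_id[mism], " vs ",
         index$marker_id[mism], ")")
  }
  idx_alleles <- paste(pmin(index_major(index), index_minor(index)),
                       pmax(index_major(index), index_minor(index)))
  q_alleles <- paste(pmin(map$major_allele, map$minor_allele),
                     pmax(map$major_allele, map$minor_allele))
  known <- !is.na(map$major_allele) & !is.na(map$minor_allele) &
    map$minor_allele != "N"
  bad <- known & q_alleles != idx_alleles
  if (any(bad)) {
    j <- which(bad)[1]
    stop("query alleles at marker ", map$marker_id[j], " (", q_alleles[j],
         ") do not match the index (", idx_alleles[j], ")")
  }
  geno <- panel$geno
  swap <- known & map$minor_allele == index_major(index)
  if (any(swap)) geno[, swap] <- 2L - geno[, swap]
  geno
}

# allele symbols are optional in a filter_index built from simulated data
index_major <- function(index) {
  if (!is.null(index$major_allele)) index$major_allele else rep("A", index$m)
}
index_minor <- function(index) {
  if (!is.null(index$minor_allele)) index$minor_allele else rep("B", index$m)
}
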