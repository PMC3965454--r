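#' Default error-threshold grid for performance sweeps
#'
#' A 5 x 5 logarithmic grid over the per-window false-elimination bounds of
#' the two filters, spanning strict (1e-4) to loose (0.1) settings.
#'
#' @param values threshold values for each filter.
#' @return data.frame with columns `p_th_major`, `p_th_minor`.
#' @export
default_threshold_grid <- function(values = c(1e-4, 1e-3, 5e-3, 2e-2, 1e-1)) {
  expand.grid(p_th_major = values, p_th_minor = values,
              KEEP.OUT.ATTRS = FALSE)
}

#' Assemble a simulated filtering scenario
#'
#' Convenience wrapper tying the simulator to the filter: simulates a panel,
#' indexes it, and generates queries with injected IBD segments.
#'
#' @param config a [sim_config()].
#' @param params a [query_params()] object.
#' @param J_th,maf_cutoff index-construction parameters (see
#'   [build_index()]).
#' @return list with `sim`, `index`, `map`, `queries`, `truths`, `params`.
#' @export
make_scenario <- function(config, params = query_params(),
                          J_th = 0.9, maf_cutoff = 0.05) {
  sim <- simulate_panel(config)
  index <- build_index(sim$panel, sim$map, J_th = J_th,
                       maf_cutoff = maf_cutoff)
  qs <- simulate_queries(sim)
  list(sim = sim, index = index, map = sim$map,
       queries = qs$queries, truths = qs$truths, params = params)
}

# marker indices of a truth segment on the map (same convention as the
# injection: [start, end) on the truth chromosome)
truth_marker_idx <- function(map, truth_row) {
  which(map$chrom == truth_row$chrom &
          map$cm >= truth_row$start_cm & map$cm < truth_row$end_cm)
}

# coverage of marker cM positions by a set of [start, end] intervals
covered_by <- function(cm, chrom, intervals) {
  if (length(cm) == 0L) return(logical(0))
  out <- logical(length(cm))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  for (r in seq_len(nrow(intervals))) {
    out <- out | (chrom == intervals$chrom[r] &
                    cm >= intervals$start_cm[r] & cm <= intervals$end_cm[r])
  }
  out
}

# shared scoring core: per-query partner intervals + candidate fraction
score_core <- function(partner_intervals, cand_fractions, truths, map) {
  total <- 0L
  detected <- 0L
  fully <- 0L
  nq <- nrow(truths)
  for (q in seq_len(nq)) {
    idx <- truth_marker_idx(map, truths[q, ])
    cov <- covered_by(map$cm[idx], map$chrom[idx], partner_intervals[[q]])
    total <- total + length(idx)
    detected <- detected + sum(cov)
    fully <- fully + as.integer(length(idx) > 0L && all(cov))
  }
  cf <- mean(cand_fractions)
  structure(list(
    sensitivity = if (total > 0L) detected / total else NA_real_,
    full_coverage_sensitivity = fully / nq,
    candidate_fraction = cf,
    speedup = if (cf > 0) 1 / cf else Inf,
    speedup_undefined = cf == 0,
    n_queries = nq, detected_markers = detected, total_markers = total
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d queries: sensitivity %.4f ",
                     "(full coverage %.4f), candidate fraction %.4g, ",
                     "speedup %.1fx\n"),
              x$n_queries, x$sensitivity, x$full_coverage_sensitivity,
              x$candidate_fraction, x$speedup))
  invisible(x)
}

#' Score candidate reports against simulation truth
#'
#' Overall (marker-level) sensitivity is the fraction of markers inside
#' injected IBD segments that are covered by candidate segments reported for
#' the correct indexed partner, pooled over queries. Full-coverage
#' sensitivity is the fraction of injected segments all of whose markers are
#' covered. The candidate fraction is the mean over queries of the fraction
#' of the database (individuals x genetic length) retained; speedup is its
#' reciprocal (infinite, and flagged, when nothing is retained).
#'
#' @param reports list of `candidate_report` objects, one per query, in the
#'   order of `truths` rows.
#' @param truths truth data.frame from [simulate_queries()].
#' @param map the panel's [marker_map()].
#' @param ids panel individual ids (to validate truth references).
#' @return an object of class `eval_report`.
#' @export
score_candidates <- function(reports, truths, map, ids = NULL) {
  stopifnot(length(reports) == nrow(truths))
  if (!is.null(ids) && !all(truths$indexed_id %in% ids)) {
    bad <- setdiff(truths$indexed_id, ids)[1]
    stop("truth references unknown indexed individual: ", bad)
  }
  partner <- lapply(seq_along(reports), function(q) {
    seg <- reports[[q]]$segments
    seg[seg$indexed_id == truths$indexed_id[q], , drop = FALSE]
  })
  cf <- vapply(reports, function(r) r$candidate_fraction, numeric(1))
  score_core(partner, cf, truths, map)
}

#' Sweep the error-tolerance thresholds of both filters
#'
#' Reuses one genome scan per query ([scan_query_counts()]) and re-applies
#' the per-window binomial tolerances for every threshold pair, producing one
#' performance point (sensitivity, candidate fraction) per pair.
#'
#' @param scenario a [make_scenario()] result (or any list with `index`,
#'   `queries`, `truths`, `params`, `map`).
#' @param grid data.frame of `p_th_major`, `p_th_minor` pairs
#'   (default [default_threshold_grid()]).
#' @param filters filters to enforce (default from `scenario$params`).
#' @param progress print a dot per query.
#' @return data.frame with one row per threshold pair: thresholds, mean
#'   per-window tolerances, sensitivity, full-coverage sensitivity,
#'   candidate fraction and speedup.
#' @export
sweep_thresholds <- function(scenario, grid = default_threshold_grid(),
                             filters = NULL, progress = FALSE) {
  stopifnot(nrow(grid) >= 1L)
  index <- scenario$index
  params <- scenario$params
  if (is.null(filters)) filters <- params$filters
  truths <- scenario$truths
  nq <- nrow(truths)
  stopifnot(nrow(scenario$queries) == nq)
  G <- nrow(grid)
  detected <- integer(G)
  total <- 0L
  fully <- integer(G)
  cf_sum <- numeric(G)
  k_major_sum <- numeric(G)
  k_minor_sum <- numeric(G)
  for (q in seq_len(nq)) {
    qc <- scan_query_counts(scenario$queries[q, ], index, params)
    tr <- truths[q, ]
    idx <- truth_marker_idx(scenario$map, tr)
    total <- total + length(idx)
    for (g in seq_len(G)) {
      res <- candidate_segments(qc, index,
                                p_th_major = grid$p_th_major[g],
                                p_th_minor = grid$p_th_minor[g],
                                filters = filters, focal = tr$ind)
      cov <- covered_by(scenario$map$cm[idx], scenario$map$chrom[idx],
                        res$segments)
      detected[g] <- detected[g] + sum(cov)
      fully[g] <- fully[g] + as.integer(length(idx) > 0L && all(cov))
      cf_sum[g] <- cf_sum[g] + res$candidate_fraction
      k_major_sum[g] <- k_major_sum[g] + mean(res$k_major)
      k_minor_sum[g] <- k_minor_sum[g] + mean(res$k_minor)
    }
    if (progress && q %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  cf <- cf_sum / nq
  data.frame(
    p_th_major = grid$p_th_major, p_th_minor = grid$p_th_minor,
    mean_k_major = k_major_sum / nq, mean_k_minor = k_minor_sum / nq,
    sensitivity = if (total > 0L) detected / total else NA_real_,
    full_coverage_sensitivity = fully / nq,
    candidate_fraction = cf,
    speedup = ifelse(cf > 0, 1 / cf, Inf))
}

#' Pareto frontier of performance points
#'
#' Keeps the points not dominated by any other: a point is dominated when
#' another has sensitivity at least as high and candidate fraction at most
#' as low, with at least one strict inequality.
#'
#' @param points data.frame with `sensitivity` and `candidate_fraction`
#'   columns (e.g. from [sweep_thresholds()]).
#' @return the non-dominated subset, sorted by sensitivity.
#' @export
pareto_frontier <- function(points) {
  n <- nrow(points)
  if (n == 0L) return(points)
  s <- points$sensitivity
  f <- points$candidate_fraction
  keep <- vapply(seq_len(n), function(i) {
    !any(s >= s[i] & f <= f[i] & (s > s[i] | f < f[i]))
  }, logical(1))
  out <- points[keep, , drop = FALSE]
  out[order(out$sensitivity), , drop = FALSE]
}

#' Best speedup at a sensitivity level
#'
#' @param curve a sweep result (data.frame with `sensitivity` and `speedup`).
#' @param level required minimum sensitivity (default 0.99).
#' @return the maximum speedup among points with `sensitivity >= level`, or
#'   `NA` if no point reaches the level.
#' @export
speedup_at <- function(curve, level = 0.99) {
  ok <- curve$sensitivity >= level
  if (!any(ok)) return(NA_real_)
  max(curve$speedup[ok])
}
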