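# hand-built index with full control over sets, labels and MAFs
synth_index <- function(hom_major, hom_minor, cm, maf,
                        label_major = seq_along(cm),
                        label_minor = seq_along(cm),
                        low_maf_excluded = rep(FALSE, length(cm)),
                        chrom = rep("1", length(cm))) {
  n <- nrow(hom_major)
  structure(list(
    ids = sprintf("i%03d", seq_len(n)), n = n, m = length(cm),
    marker_id = sprintf("m%03d", seq_along(cm)), chrom = chrom,
    bp = as.integer(round(cm * 1e6)) + seq_along(cm), cm = cm, maf = maf,
    major_allele = rep("A", length(cm)), minor_allele = rep("B", length(cm)),
    hom_major = hom_major, hom_minor = hom_minor,
    label_major = as.integer(label_major), label_minor = as.integer(label_minor),
    low_maf_excluded = low_maf_excluded,
    J_th = 0.9, maf_cutoff = 0.05, version = 1L), class = "filter_index")
}

test_that("window planning covers the span and anchors the chromosome tail", {
  mk_map <- function(cm) marker_map(sprintf("m%d", seq_along(cm)), "1",
                                    seq_along(cm) * 100L, cm)
  w1 <- plan_windows(mk_map(c(0, 2, 5)), w = 3.5, s = 0.5)
  expect_equal(w1$start, c(0, 0.5, 1, 1.5))
  expect_equal(w1$end, w1$start + 3.5)
  expect_equal(w1$closed_right, c(FALSE, FALSE, FALSE, TRUE))
  # span below w: one whole-span window
  w2 <- plan_windows(mk_map(c(0, 1, 3)), w = 3.5, s = 0.5)
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0, 3))
  # grid does not land on the tail: anchored final window appended
  w3 <- plan_windows(mk_map(c(0, 2, 5.2)), w = 3.5, s = 0.5)
  expect_equal(w3$start, c(0, 0.5, 1, 1.5, 1.7))
  expect_equal(w3$end[5], 5.2)
})

test_that("marker selection follows query homozygosity, exclusions and labels", {
  cm <- c(1, 2, 3, 4, 5)
  H <- matrix(FALSE, 3, 5)
  idx <- synth_index(H, H, cm, maf = rep(0.3, 5))
  win <- list(chrom = "1", start = 0.5, end = 5.5, closed_right = TRUE)
  query <- c(2L, 1L, 2L, 0L, 2L)
  expect_identical(select_markers(query, win, idx, "major"), c(1L, 3L, 5L))
  expect_identical(select_markers(query, win, idx, "minor"), 4L)
  # shared label prunes the later marker
  idx2 <- synth_index(H, H, cm, maf = rep(0.3, 5),
                      label_major = c(1L, 2L, 1L, 3L, 4L))
  expect_identical(select_markers(query, win, idx2, "major"), c(1L, 5L))
  expect_identical(select_markers(query, win, idx2, "major",
                                  use_pruning = FALSE), c(1L, 3L, 5L))
  # low-MAF exclusion applies to the Major Filter only
  idx3 <- synth_index(H, H, cm, maf = c(0.01, rep(0.3, 4)),
                      low_maf_excluded = c(TRUE, rep(FALSE, 4)))
  expect_identical(select_markers(query, win, idx3, "major"), c(3L, 5L))
  # heterozygous query selects nothing
  expect_identical(select_markers(rep(1L, 5), win, idx, "major"), integer(0))
  # window bounds are half-open unless closed_right
  win2 <- list(chrom = "1", start = 1, end = 5, closed_right = FALSE)
  expect_identical(select_markers(query, win2, idx, "major"), c(1L, 3L))
})

test_that("window scan eliminates individuals beyond tolerance under both filters", {
  # A (ind 1) is hom-major at marker 1 only; B (ind 2) in no set
  hom_major <- cbind(c(TRUE, FALSE), c(FALSE, FALSE))
  hom_minor <- matrix(FALSE, 2, 2)
  idx <- synth_index(hom_major, hom_minor, cm = c(1, 2), maf = c(0.3, 0.3))
  win <- list(chrom = "1", start = 0, end = 3, closed_right = TRUE)
  sels <- list(major = c(1L, 2L), minor = integer(0))
  tol0 <- list(major = list(k = 0L), minor = list(k = 0L))
  res0 <- scan_window(win, sels, idx, tol0)
  expect_identical(res0$counts_major, c(1L, 0L))
  expect_identical(res0$survivors, 2L)
  tol1 <- list(major = list(k = 1L), minor = list(k = 0L))
  expect_identical(scan_window(win, sels, idx, tol1)$survivors, c(1L, 2L))
})

test_that("slide update reproduces from-scratch counts and flags corruption", {
  st <- hwe_panel(n = 50, mafs = runif(60, 0.1, 0.5), seed = 21)
  idx <- build_index(st$panel, st$map, maf_cutoff = 0)
  prev <- as.integer(rowSums(idx$hom_major[, 1:10]))
  expect_identical(slide_update(prev, idx, "major"), prev)
  upd <- slide_update(prev, idx, "major", leaving = 1:3, entering = 11:12)
  fresh <- as.integer(rowSums(idx$hom_major[, c(4:10, 11:12)]))
  expect_identical(upd, fresh)
  one <- slide_update(prev, idx, "major", leaving = 5L)
  expect_identical(prev - one, as.integer(idx$hom_major[, 5]))
  # counters that do not match the claimed selection go negative
  expect_error(slide_update(rep(0L, 50), idx, "major",
                            leaving = which.max(colSums(idx$hom_major))),
               "negative")
})

test_that("surviving windows extend by the target-length flank and clamp", {
  win <- list(chrom = "1", start = 10, end = 13.5, closed_right = FALSE)
  expect_equal(extend_window(win, target_cm = 4), c(9.5, 14))
  expect_equal(extend_window(win, target_cm = 3.5), c(10, 13.5))
  expect_equal(extend_window(win, target_cm = 4, chrom_range = c(9.8, 20)),
               c(9.8, 14))
  expect_error(extend_window(win, target_cm = 3))
})

test_that("candidate segments merge across surviving windows per individual", {
  sim <- simulate_panel(sim_config(n = 40, m = 600, length_cm = 25,
                                   n_queries = 1, seed = 31))
  idx <- build_index(sim$panel, sim$map)
  qs <- simulate_queries(sim, n_queries = 3, eps_sim = 0.005)
  params <- query_params()
  for (q in 1:3) {
    rep_q <- run_query(qs$queries[q, ], idx, params,
                       query_id = rownames(qs$queries)[q])
    seg <- rep_q$segments
    # per individual: sorted, disjoint (no touching intervals survive a
    # merge), and at least window + both flanks long
    min_len <- params$window_cm + 2 * (params$target_cm - params$window_cm)
    for (id in unique(seg$indexed_id)) {
      iv <- seg[seg$indexed_id == id, ]
      expect_true(all(diff(iv$start_cm) > 0))
      if (nrow(iv) > 1L) {
        expect_true(all(iv$start_cm[-1] > iv$end_cm[-nrow(iv)]))
      }
      full_span <- range(idx$cm)
      interior <- iv$start_cm > full_span[1] & iv$end_cm < full_span[2]
      expect_true(all(iv$end_cm[interior] - iv$start_cm[interior] >=
                        min_len - 1e-9))
    }
    expect_true(all(seg$end_cm > seg$start_cm))
  }
})

test_that("lowering the false-elimination bound only enlarges the candidate set", {
  sim <- simulate_panel(sim_config(n = 50, m = 700, length_cm = 30,
                                   n_queries = 1, seed = 41))
  idx <- build_index(sim$panel, sim$map)
  qs <- simulate_queries(sim, n_queries = 2, eps_sim = 0.01)
  params <- query_params(use_pruning = FALSE)
  for (q in 1:2) {
    qc <- scan_query_counts(qs$queries[q, ], idx, params)
    loose <- candidate_segments(qc, idx, p_th_major = 1e-4, p_th_minor = 1e-4)
    strict <- candidate_segments(qc, idx, p_th_major = 0.1, p_th_minor = 0.1)
    # tolerances grow as p_th shrinks
    expect_true(all(loose$k_major >= strict$k_major))
    expect_true(all(loose$k_minor >= strict$k_minor))
    expect_true(all(loose$cand_cm >= strict$cand_cm - 1e-12))
    # every strict candidate interval is contained in a loose interval
    s_seg <- strict$segments
    l_seg <- loose$segments
    for (r in seq_len(nrow(s_seg))) {
      hit <- l_seg$ind == s_seg$ind[r] &
        l_seg$start_cm <= s_seg$start_cm[r] + 1e-9 &
        l_seg$end_cm >= s_seg$end_cm[r] - 1e-9
      expect_true(any(hit))
    }
  }
})

test_that("queries are aligned onto the index coding and mismatches are caught", {
  st <- hwe_panel(n = 30, mafs = runif(20, 0.1, 0.5), seed = 51)
  idx <- build_index(st$panel, st$map)
  qmap <- st$map
  qgeno <- st$panel$geno[1:2, , drop = FALSE]
  # swap the allele labels (and counts) at marker 3 in the query's coding
  qmap$major_allele[3] <- st$map$minor_allele[3]
  qmap$minor_allele[3] <- st$map$major_allele[3]
  qgeno[, 3] <- 2L - qgeno[, 3]
  qpanel <- genotype_panel(c("q1", "q2"), qgeno)
  aligned <- align_query(qpanel, qmap, idx)
  expect_identical(unname(aligned), unname(st$panel$geno[1:2, , drop = FALSE]))
  # foreign allele pair
  qmap2 <- st$map
  qmap2$minor_allele[5] <- "Z"
  expect_error(align_query(qpanel, qmap2, idx), "alleles")
  # different marker set
  qmap3 <- st$map
  qmap3$marker_id[7] <- "other"
  expect_error(align_query(qpanel, qmap3, idx), "mismatch")
  expect_error(run_query(c(0L, 2L), idx), "markers")
})
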