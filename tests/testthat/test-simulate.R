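test_that("panel simulation is deterministic and matches its MAF spectrum", {
  cfg <- sim_config(n = 300, m = 400, length_cm = 20, n_queries = 1, seed = 77)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$panel$geno, b$panel$geno)
  expect_equal(a$map, b$map)
  # genotypes are haplotype-pair sums
  expect_identical(a$panel$geno[3, ], a$haplotypes[5, ] + a$haplotypes[6, ])
  # realized MAF within 3 binomial SE of a fair re-draw around itself:
  # the counted allele frequency over 2n draws must stay below 0.5 and the
  # spectrum must fill the configured range
  expect_true(all(a$map$maf <= 0.5))
  expect_gt(diff(range(a$map$maf)), 0.2)
  # map is sorted with positive span
  expect_false(is.unsorted(a$map$cm))
})

test_that("realized allele frequencies track the drawn MAFs within binomial error", {
  # n = 1000 individuals at fixed drawn frequencies
  cfg <- sim_config(n = 1000, m = 60, length_cm = 10, maf_min = 0.2,
                    maf_max = 0.2, n_queries = 1, seed = 78)
  sim <- simulate_panel(cfg)
  f <- 0.2
  se <- sqrt(f * (1 - f) / (2 * cfg$n))
  expect_true(all(abs(sim$map$maf - f) <= 3 * se + 1e-12))
})

test_that("linkage equilibrium draws show no adjacent-marker correlation", {
  cfg <- sim_config(n = 500, m = 200, length_cm = 20, rho = 0,
                    n_queries = 1, seed = 79)
  sim <- simulate_panel(cfg)
  cors <- vapply(seq_len(cfg$m - 1L), function(j) {
    suppressWarnings(cor(sim$haplotypes[, j], sim$haplotypes[, j + 1L]))
  }, numeric(1))
  cors <- cors[is.finite(cors)]
  # mean adjacent correlation ~ 0 within Monte-Carlo error
  expect_lt(abs(mean(cors)), 3 / sqrt(length(cors) * 2 * cfg$n))
  # and a strongly linked panel shows clear positive correlation
  cfg_ld <- sim_config(n = 500, m = 200, length_cm = 20, rho = 0.9,
                       n_queries = 1, seed = 79)
  sim_ld <- simulate_panel(cfg_ld)
  cors_ld <- vapply(seq_len(200 - 1L), function(j) {
    suppressWarnings(cor(sim_ld$haplotypes[, j], sim_ld$haplotypes[, j + 1L]))
  }, numeric(1))
  expect_gt(mean(cors_ld, na.rm = TRUE), 0.5)
})

test_that("composite haplotypes are block mosaics of the base haplotypes", {
  cfg <- sim_config(n = 20, m = 120, length_cm = 1.0, ibd_cm = 0.5,
                    n_queries = 1, seed = 80)
  sim <- simulate_panel(cfg)
  comp <- make_composite_haplotypes(sim$haplotypes, sim$map, seg_cm = 0.2,
                                    seed = 81)
  # a 1.0 cM chromosome in 0.2 cM blocks
  expect_identical(max(comp$blocks), 5L)
  expect_true(all(diff(comp$blocks) %in% c(0L, 1L)))
  # provenance replay: every allele equals its source haplotype's allele
  for (hp in 1:2) {
    src <- comp$provenance[hp, comp$blocks]
    expect_identical(comp$haplotypes[hp, ],
                     sim$haplotypes[cbind(src, seq_len(cfg$m))])
  }
  # a single base haplotype forces the composite to equal it
  one <- sim$haplotypes[1, , drop = FALSE]
  comp1 <- make_composite_haplotypes(one, sim$map, seg_cm = 0.2, seed = 82)
  expect_identical(comp1$haplotypes[1, ], one[1, ])
  expect_identical(comp1$haplotypes[2, ], one[1, ])
})

test_that("IBD injection copies the source haplotype exactly within the interval", {
  cfg <- sim_config(n = 30, m = 500, length_cm = 25, n_queries = 1, seed = 83)
  sim <- simulate_panel(cfg)
  comp <- make_composite_haplotypes(sim$haplotypes, sim$map, seed = 84)
  inj <- inject_ibd(comp$haplotypes, sim$haplotypes, sim$map, L = 4,
                    ids = sim$panel$ids, seed = 85)
  tr <- inj$truth
  idx <- which(sim$map$cm >= tr$start_cm & sim$map$cm < tr$end_cm)
  src <- 2L * (tr$ind - 1L) + tr$hap
  expect_gt(length(idx), 0L)
  expect_identical(inj$query_haps[1, idx], sim$haplotypes[src, idx])
  # without errors the pair has no opposite homozygote inside the segment
  qg <- inj$query_haps[1, ] + inj$query_haps[2, ]
  pg <- sim$panel$geno[tr$ind, ]
  opp <- (qg == 2L & pg == 0L) | (qg == 0L & pg == 2L)
  expect_false(any(opp[idx]))
  # truth interval has the requested length
  expect_equal(tr$end_cm - tr$start_cm, 4)
  expect_error(inject_ibd(comp$haplotypes, sim$haplotypes, sim$map, L = 100),
               "span")
})

test_that("genotyping errors flip alleles independently at the allele level", {
  haps <- matrix(0L, 2, 40000)
  out0 <- inject_errors(haps, 0)
  expect_identical(out0, haps)
  out <- inject_errors(haps, 0.01, seed = 86)
  flips <- sum(out != haps)
  n_alleles <- length(haps)
  expect_lt(abs(flips - n_alleles * 0.01), 3 * sqrt(n_alleles * 0.01 * 0.99))
  # heterozygous genotypes can move to either homozygote
  het <- rbind(rep(1L, 20000), rep(0L, 20000))
  noisy <- inject_errors(het, 0.3, seed = 87)
  g <- noisy[1, ] + noisy[2, ]
  expect_true(all(c(0L, 1L, 2L) %in% unique(g)))
})

test_that("query simulation is reproducible and records consistent truths", {
  cfg <- sim_config(n = 25, m = 300, length_cm = 20, n_queries = 4, seed = 88)
  sim <- simulate_panel(cfg)
  a <- simulate_queries(sim)
  b <- simulate_queries(sim)
  expect_identical(a$queries, b$queries)
  expect_identical(a$truths, b$truths)
  expect_identical(nrow(a$queries), 4L)
  expect_true(all(a$truths$indexed_id %in% sim$panel$ids))
  expect_true(all(a$truths$start_cm >= min(sim$map$cm) &
                    a$truths$end_cm <= max(sim$map$cm) + 1e-9))
})

test_that("cousin-degree queries derive segment length and window size correctly", {
  cfg <- sim_config(n = 20, m = 600, length_cm = 30, n_queries = 2, seed = 89)
  sim <- simulate_panel(cfg)
  c4 <- simulate_cousin_queries(4, sim)
  expect_equal(c4$L, 10)
  expect_equal(c4$params$window_cm, 9.5)
  c7 <- simulate_cousin_queries(7, sim)
  expect_equal(c7$L, 6.25)
  # w = L - s rounded up to the closest half cM
  expect_equal(c7$params$window_cm, 6.0)
  Ls <- vapply(4:7, function(d) 100 / (2 * (d + 1)), numeric(1))
  expect_true(all(diff(Ls) < 0))
  expect_equal(c4$truths$end_cm - c4$truths$start_cm, rep(10, 2))
})
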