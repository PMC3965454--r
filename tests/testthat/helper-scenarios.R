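# Shared simulated scenarios, built lazily and cached for the whole test run.
# The main protocol scenario (n=500 individuals, m=5000 markers on a 180 cM
# chromosome, MAF ~ U(0.05, 0.5), 500 queries each carrying one injected 4 cM
# IBD segment, per-allele query error rate 0.005) is reused by several
# performance tests, as is its 5x5 threshold sweep.

.scenario_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (!exists(name, envir = .scenario_cache)) {
    assign(name, build(), envir = .scenario_cache)
  }
  get(name, envir = .scenario_cache)
}

protocol_scenario <- function() {
  cache_get("protocol_scenario", function() {
    make_scenario(sim_config(n = 500, m = 5000, length_cm = 180,
                             n_queries = 500, eps_sim = 0.005, seed = 101),
                  query_params())
  })
}

protocol_sweep <- function() {
  cache_get("protocol_sweep", function() {
    sweep_thresholds(protocol_scenario())
  })
}

# the same scenario restricted to its first nq queries (cheaper trend sweeps)
scenario_head <- function(sc, nq) {
  sc$queries <- sc$queries[seq_len(nq), , drop = FALSE]
  sc$truths <- sc$truths[seq_len(nq), , drop = FALSE]
  sc
}

# restrict a scenario to a random sorted subset of markers (marker-density
# experiments); allele frequencies are unchanged by subsetting
subsample_markers <- function(sc, m_keep, seed) {
  set.seed(seed)
  keep <- sort(sample.int(ncol(sc$queries), m_keep))
  panel <- genotype_panel(sc$sim$panel$ids, sc$sim$panel$geno[, keep])
  map <- sc$map[keep, ]
  class(map) <- class(sc$map)
  index <- build_index(panel, map, J_th = sc$index$J_th,
                       maf_cutoff = sc$index$maf_cutoff)
  list(sim = sc$sim, index = index, map = map,
       queries = sc$queries[, keep, drop = FALSE],
       truths = sc$truths, params = sc$params)
}

# 3x3 threshold grid (a subset of the default 5x5 values) for trend sweeps
trend_grid <- function() {
  default_threshold_grid(c(1e-4, 5e-3, 1e-1))
}

# small panel built directly under Hardy-Weinberg at given MAFs (no LD)
hwe_panel <- function(n, mafs, length_cm = 30, seed = 1) {
  set.seed(seed)
  m <- length(mafs)
  geno <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), n, m)
  panel <- genotype_panel(sprintf("h%04d", seq_len(n)), geno)
  map <- marker_map(sprintf("m%05d", seq_len(m)), "1",
                    bp = seq_len(m) * 1000L, cm = sort(runif(m, 0, length_cm)),
                    major_allele = "A", minor_allele = "B")
  st <- compute_allele_stats(panel, map)
  st
}
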