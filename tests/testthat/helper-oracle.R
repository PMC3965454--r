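# Independent reference implementations used as oracles. These deliberately
# avoid the package's window/count/merge machinery: everything is computed by
# direct loops over the genotype matrix and simple interval arithmetic.

# Monte-Carlo estimate of the false opposite-homozygote probability under the
# IBD-pair generative model: one shared allele plus one population allele per
# individual (all minor w.p. f), then independent per-allele read errors.
mc_false_opphom <- function(kind, f, eps, N = 3e6) {
  h <- runif(N) < f
  aq <- runif(N) < f
  ax <- runif(N) < f
  flip <- function(a) ifelse(runif(N) < eps, !a, a)
  oq <- flip(h) + flip(aq)
  ox <- flip(h) + flip(ax)
  if (kind == "major") {
    sel <- oq == 2
    opp <- ox[sel] == 0
  } else {
    sel <- oq == 0
    opp <- ox[sel] == 2
  }
  p <- mean(opp)
  list(p = p, n = sum(sel), se = sqrt(max(p * (1 - p), 1e-12) / sum(sel)))
}

# smallest k with P(Binomial(c, pe) > k) <= pth, by direct CDF accumulation;
# the tiny relative fuzz keeps exact mathematical ties (tail prob == pth)
# from being flipped by floating-point dust
enum_tolerance <- function(c, pe, pth) {
  if (c == 0L || pe == 0) return(0L)
  cdf <- cumsum(dbinom(0:c, c, pe))
  k <- which(1 - cdf <= pth * (1 + 1e-9))[1] - 1L
  if (is.na(k)) c else k
}

# Naive filter: per window and per individual, count opposite homozygotes
# straight from the genotype matrix; merge extended surviving windows by
# sorting intervals. Pruning off. Returns segments (ind/chrom/start/end) and
# the candidate fraction.
naive_run_query <- function(query, geno, map, params, maf_cutoff = 0.05) {
  w <- params$window_cm
  s <- params$step_cm
  L <- params$target_cm
  eps <- params$error$eps
  n <- nrow(geno)
  per_ind <- lapply(seq_len(n), function(i) list())
  total_len <- 0
  for (ch in unique(map$chrom)) {
    in_ch <- which(map$chrom == ch)
    cmv <- map$cm[in_ch]
    lo <- min(cmv)
    hi <- max(cmv)
    total_len <- total_len + (hi - lo)
    if (hi - lo <= w) {
      starts <- lo
      ends <- hi
    } else {
      starts <- seq(lo, hi - w + 1e-12, by = s)
      if (hi - w > starts[length(starts)] + 1e-9) starts <- c(starts, hi - w)
      ends <- starts + w
    }
    nw <- length(starts)
    for (wi in seq_len(nw)) {
      a <- starts[wi]
      b <- ends[wi]
      inside <- cmv >= a & (if (wi == nw) cmv <= b else cmv < b)
      mk <- in_ch[inside]
      sel_major <- mk[!is.na(query[mk]) & query[mk] == 2L &
                        map$maf[mk] >= maf_cutoff]
      sel_minor <- mk[!is.na(query[mk]) & query[mk] == 0L]
      k_major <- if (length(sel_major) == 0L) 0L else {
        enum_tolerance(length(sel_major),
                       false_opphom_prob("major", min(map$maf[sel_major]), eps),
                       params$error$p_th_major)
      }
      k_minor <- if (length(sel_minor) == 0L) 0L else {
        enum_tolerance(length(sel_minor),
                       false_opphom_prob("minor", max(map$maf[sel_minor]), eps),
                       params$error$p_th_minor)
      }
      ext <- c(max(a - (L - w), lo), min(b + (L - w), hi))
      for (i in seq_len(n)) {
        cm_count <- sum(geno[i, sel_major] == 0L, na.rm = TRUE)
        cn_count <- sum(geno[i, sel_minor] == 2L, na.rm = TRUE)
        if (cm_count <= k_major && cn_count <= k_minor) {
          per_ind[[i]] <- c(per_ind[[i]], list(c(ext[1], ext[2])))
        }
      }
    }
    # merge per individual within this chromosome before moving on
    for (i in seq_len(n)) {
      iv <- per_ind[[i]]
      tagged <- vapply(iv, function(x) length(x) == 2L, logical(1))
      if (!any(tagged)) next
      open <- do.call(rbind, iv[tagged])
      keepers <- iv[!tagged]
      open <- open[order(open[, 1]), , drop = FALSE]
      merged <- list()
      cur <- open[1, ]
      for (r in seq_len(nrow(open))[-1]) {
        if (open[r, 1] <= cur[2]) {
          cur[2] <- max(cur[2], open[r, 2])
        } else {
          merged <- c(merged, list(cur))
          cur <- open[r, ]
        }
      }
      merged <- c(merged, list(cur))
      per_ind[[i]] <- c(keepers,
                        lapply(merged, function(x) c(x, chrom = ch)))
    }
  }
  rows <- list()
  cand <- 0
  for (i in seq_len(n)) {
    for (iv in per_ind[[i]]) {
      rows <- c(rows, list(data.frame(ind = i, chrom = as.character(iv[3]),
                                      start_cm = as.numeric(iv[1]),
                                      end_cm = as.numeric(iv[2]),
                                      stringsAsFactors = FALSE)))
      cand <- cand + as.numeric(iv[2]) - as.numeric(iv[1])
    }
  }
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ind = integer(), chrom = character(),
               start_cm = numeric(), end_cm = numeric())
  rownames(segments) <- NULL
  list(segments = segments, candidate_fraction = cand / (n * total_len))
}
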