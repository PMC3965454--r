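#' Jaccard index of two individual sets
#'
#' `|A intersect B| / |A union B|`, with the convention that two empty sets
#' have Jaccard index 1 (they are trivially identical).
#'
#' @param A,B vectors of individual indices (treated as sets).
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  i <- length(intersect(A, B))
  u <- length(A) + length(B) - i
  if (u == 0L) 1 else i / u
}

#' Assign Jaccard run labels to per-marker individual sets
#'
#' Markers whose homozygous-individual sets are nearly identical carry almost
#' no independent pruning power (a consequence of local linkage
#' disequilibrium), so they are grouped under a shared label and only one
#' member of each label needs to be examined at query time. Labels are
#' assigned by a single greedy pass along the chromosome: a marker joins the
#' current run iff the Jaccard index between the run's first marker's set and
#' its own set exceeds `J_th` (sets identical to the representative always
#' join, even at `J_th = 1`); otherwise a new label begins.
#'
#' @param sets list of per-marker individual sets, in chromosome cM order.
#' @param J_th Jaccard threshold in `[0, 1]`.
#' @return integer label vector (starting at 1), same length as `sets`.
#' @export
assign_labels <- function(sets, J_th) {
  m <- length(sets)
  if (m == 0L) return(integer(0))
  labels <- integer(m)
  lab <- 1L
  rep_set <- sets[[1]]
  labels[1] <- lab
  if (m > 1L) {
    for (j in 2:m) {
      jc <- jaccard(rep_set, sets[[j]])
      # identical sets always share a label, even at J_th = 1
      if (jc > J_th || jc == 1) {
        labels[j] <- lab
      } else {
        lab <- lab + 1L
        rep_set <- sets[[j]]
        labels[j] <- lab
      }
    }
  }
  labels
}

#' Build the opposite-homozygosity filter index
#'
#' One pass over the genotype matrix records, for every marker, the set of
#' indexed individuals homozygous in the major allele (observed genotype 0;
#' used by the Major Filter) and the set homozygous in the minor allele
#' (observed genotype 2; Minor Filter). Jaccard run labels are assigned per
#' chromosome and per filter, and markers with `maf < maf_cutoff` are flagged
#' for exclusion from the Major Filter, where rare alleles make the filter
#' overly sensitive to genotyping error. Missing calls place an individual in
#' neither set.
#'
#' @param panel a [genotype_panel()] coded as minor-allele counts.
#' @param map the matching [marker_map()] with `maf` populated (see
#'   [compute_allele_stats()]).
#' @param J_th Jaccard threshold for label assignment (default 0.9).
#' @param maf_cutoff markers with `maf` below this are excluded from the
#'   Major Filter (default 0.05).
#' @return an object of class `filter_index`.
#' @export
build_index <- function(panel, map, J_th = 0.9, maf_cutoff = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"),
            J_th >= 0, J_th <= 1, maf_cutoff >= 0, maf_cutoff <= 0.5)
  n <- nrow(panel$geno)
  m <- ncol(panel$geno)
  if (n == 0L || m == 0L) stop("cannot index an empty panel")
  if (m != nrow(map)) stop("panel and map disagree on marker count")
  if (any(is.na(map$maf))) {
    stop("map has no allele frequencies; run compute_allele_stats() first")
  }
  if (anyDuplicated(rle(map$chrom)$values)) {
    stop("markers must be grouped by chromosome")
  }
  geno <- panel$geno
  hom_major <- !is.na(geno) & geno == 0L
  hom_minor <- !is.na(geno) & geno == 2L
  label_major <- integer(m)
  label_minor <- integer(m)
  off <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    sets_maj <- lapply(idx, function(j) which(hom_major[, j]))
    sets_min <- lapply(idx, function(j) which(hom_minor[, j]))
    label_major[idx] <- assign_labels(sets_maj, J_th) + off
    label_minor[idx] <- assign_labels(sets_min, J_th) + off
    off <- max(label_major[idx], label_minor[idx])
  }
  structure(list(
    ids = panel$ids,
    n = n, m = m,
    marker_id = map$marker_id,
    chrom = map$chrom,
    bp = map$bp,
    cm = map$cm,
    maf = map$maf,
    major_allele = map$major_allele,
    minor_allele = map$minor_allele,
    hom_major = hom_major,
    hom_minor = hom_minor,
    label_major = label_major,
    label_minor = label_minor,
    low_maf_excluded = map$maf < maf_cutoff,
    J_th = J_th,
    maf_cutoff = maf_cutoff,
    version = 1L
  ), class = "filter_index")
}

#' @export
print.filter_index <- function(x, ...) {
  cat(sprintf(paste0("<filter_index> n=%d individuals, m=%d markers, ",
                     "%d/%d labels (major/minor), J_th=%g, maf_cutoff=%g\n"),
              x$n, x$m, length(unique(x$label_major)),
              length(unique(x$label_minor)), x$J_th, x$maf_cutoff))
  invisible(x)
}

INDEX_MAGIC <- charToRaw("IBDSCREENIDX\n")

#' Save a filter index to disk
#'
#' Binary container: a 13-byte magic string, a little-endian int32 header
#' length, a JSON header (all metadata: n, m, format version, thresholds,
#' individual ids, marker table, labels, low-MAF mask), then the two
#' homozygote set matrices as packed column-major bitsets over `n`, each
#' padded to a whole number of bytes.
#'
#' @param index a `filter_index`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "filter_index"))
  header <- jsonlite::toJSON(list(
    version = index$version, n = index$n, m = index$m,
    J_th = index$J_th, maf_cutoff = index$maf_cutoff,
    ids = index$ids, marker_id = index$marker_id,
    chrom = index$chrom, bp = index$bp, cm = index$cm, maf = index$maf,
    major_allele = index$major_allele, minor_allele = index$minor_allele,
    label_major = index$label_major, label_minor = index$label_minor,
    low_maf_excluded = index$low_maf_excluded
  ), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(INDEX_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  pack <- function(M) {
    v <- as.logical(M)
    pad <- (8L - length(v) %% 8L) %% 8L
    packBits(c(v, rep(FALSE, pad)), type = "raw")
  }
  writeBin(pack(index$hom_major), con)
  writeBin(pack(index$hom_minor), con)
  invisible(path)
}

#' Load a filter index saved by [save_index()]
#'
#' @param path input file.
#' @return a `filter_index`.
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(INDEX_MAGIC))
  if (!identical(magic, INDEX_MAGIC)) stop("not an ibdscreen index file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L) {
    stop("truncated index file: ", path)
  }
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) != hlen) stop("truncated index file: ", path)
  h <- jsonlite::fromJSON(rawToChar(hraw))
  if (!identical(as.integer(h$version), 1L)) {
    stop("unsupported index format version: ", h$version)
  }
  n <- as.integer(h$n)
  m <- as.integer(h$m)
  nbytes <- ceiling(n * m / 8)
  unpack <- function() {
    raw <- readBin(con, "raw", nbytes)
    if (length(raw) != nbytes) stop("truncated index file: ", path)
    matrix(as.logical(rawToBits(raw))[seq_len(n * m)], n, m)
  }
  hom_major <- unpack()
  hom_minor <- unpack()
  structure(list(
    ids = h$ids, n = n, m = m,
    marker_id = h$marker_id, chrom = h$chrom,
    bp = as.integer(h$bp), cm = as.numeric(h$cm), maf = as.numeric(h$maf),
    major_allele = h$major_allele, minor_allele = h$minor_allele,
    hom_major = hom_major, hom_minor = hom_minor,
    label_major = as.integer(h$label_major),
    label_minor = as.integer(h$label_minor),
    low_maf_excluded = as.logical(h$low_maf_excluded),
    J_th = h$J_th, maf_cutoff = h$maf_cutoff,
    version = 1L
  ), class = "filter_index")
}
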