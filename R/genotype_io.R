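#' Construct a marker map
#'
#' Per-marker metadata table: identifier, chromosome, physical position (bp,
#' 1-based), genetic position (cM, non-decreasing within chromosome), the
#' major/minor allele symbols and the minor allele frequency.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome labels.
#' @param bp integer physical positions (1-based).
#' @param cm genetic positions in centimorgans.
#' @param major_allele,minor_allele allele symbols.
#' @param maf minor allele frequencies in `[0, 0.5]` (may be `NA` before
#'   [compute_allele_stats()] is run).
#' @return a `data.frame` of class `marker_map`.
#' @export
marker_map <- function(marker_id, chrom, bp, cm,
                       major_allele = NA_character_,
                       minor_allele = NA_character_,
                       maf = NA_real_) {
  map <- data.frame(marker_id = as.character(marker_id),
                    chrom = as.character(chrom),
                    bp = as.integer(bp),
                    cm = as.numeric(cm),
                    major_allele = as.character(major_allele),
                    minor_allele = as.character(minor_allele),
                    maf = as.numeric(maf),
                    stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

validate_marker_map <- function(map) {
  stopifnot(!anyDuplicated(map$marker_id))
  for (ch in unique(map$chrom)) {
    cm <- map$cm[map$chrom == ch]
    if (is.unsorted(cm)) {
      stop("cM positions must be non-decreasing within chromosome ", ch)
    }
  }
  ok <- is.na(map$maf) | (map$maf >= 0 & map$maf <= 0.5)
  if (!all(ok)) stop("maf must lie in [0, 0.5]")
  invisible(map)
}

#' Construct a genotype panel
#'
#' A panel holds `n` individuals genotyped at `m` biallelic markers as a
#' matrix of minor-allele counts (0, 1, 2; `NA` = missing call).
#'
#' @param ids unique individual identifiers (length `n`).
#' @param geno `n x m` integer matrix of allele counts.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(ids, geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(length(ids) == nrow(geno), !anyDuplicated(ids))
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L)) {
    stop("genotypes must be allele counts in {0, 1, 2} or NA")
  }
  structure(list(ids = as.character(ids), geno = geno),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Compute allele frequencies and orient genotypes to minor-allele counts
#'
#' Estimates each marker's allele frequency from the non-missing database
#' genotypes and re-orients the coding so that stored values count the minor
#' allele: columns whose counted-allele frequency exceeds 0.5 are flipped
#' (`g -> 2 - g`) and their allele labels swapped. At a frequency of exactly
#' 0.5 the lexicographically smaller allele symbol is taken as major.
#' Monomorphic markers keep `maf = 0`. The operation is idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param map the matching [marker_map()]; its `maf`, `major_allele` and
#'   `minor_allele` columns are (re)computed.
#' @return list with re-oriented `panel` and updated `map`.
#' @export
compute_allele_stats <- function(panel, map) {
  stopifnot(inherits(panel, "genotype_panel"), ncol(panel$geno) == nrow(map))
  geno <- panel$geno
  freq <- colMeans(geno, na.rm = TRUE) / 2   # frequency of the counted allele
  freq[is.nan(freq)] <- 0                    # all-missing marker
  flip <- freq > 0.5
  # tie at 0.5: the lexicographically smaller symbol is major, so flip when
  # the currently counted (minor-slot) allele is the smaller one
  tie <- !is.na(freq) & freq == 0.5 &
    !is.na(map$minor_allele) & !is.na(map$major_allele) &
    map$minor_allele < map$major_allele
  flip <- flip | tie
  if (any(flip)) {
    geno[, flip] <- 2L - geno[, flip]
    tmp <- map$major_allele[flip]
    map$major_allele[flip] <- map$minor_allele[flip]
    map$minor_allele[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  map$maf <- freq
  panel$geno <- geno
  list(panel = panel, map = map)
}

#' Read a genetic map table
#'
#' Whitespace-delimited three-column table: chromosome, bp position, cM
#' position. A header line is detected and skipped if the second field is not
#' numeric.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `bp`, `cm`.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- suppressWarnings(
    is.na(as.numeric(strsplit(trimws(first), "\\s+")[[1]][2])))
  gm <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(gm) < 3L) stop("genetic map needs 3 columns: chrom, bp, cm")
  names(gm)[1:3] <- c("chrom", "bp", "cm")
  gm$chrom <- as.character(gm$chrom)
  gm
}

#' Interpolate cM positions from a genetic map
#'
#' Linear interpolation between flanking map points within each chromosome;
#' constant extrapolation beyond the first/last map point.
#'
#' @param gmap data.frame from [read_genetic_map()].
#' @param chrom,bp vectors of marker coordinates.
#' @return numeric cM positions.
#' @export
interpolate_cm <- function(gmap, chrom, bp) {
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- gmap[gmap$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) {
      stop("no genetic-map entries for chromosome ", ch,
           "; cannot assign cM positions")
    }
    if (nrow(g) == 1L) {
      out[sel] <- g$cm[1]
    } else {
      out[sel] <- approx(g$bp, g$cm, xout = bp[sel], rule = 2, ties = "ordered")$y
    }
  }
  out
}

#' Read genotypes from VCF or PLINK text files
#'
#' Returns the panel coded as minor-allele counts together with its marker
#' map. Only biallelic sites with diploid calls are accepted.
#'
#' For `format = "vcf"`, genetic positions must be supplied through
#' `genetic_map` (a data.frame as returned by [read_genetic_map()], or a file
#' path); for `format = "plink_text"` they are taken from the `.map` file's
#' third column. `path` for PLINK input may be the `.ped` file or the common
#' prefix of the `.ped`/`.map` pair.
#'
#' @param path input file path (or PLINK prefix).
#' @param format `"vcf"` or `"plink_text"`.
#' @param genetic_map optional genetic map for VCF input.
#' @return list with elements `panel` ([genotype_panel()]) and `map`
#'   ([marker_map()]).
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text"),
                           genetic_map = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    read_genotypes_vcf(path, genetic_map)
  } else {
    read_genotypes_plink(path)
  }
}

read_genotypes_vcf <- function(path, genetic_map) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(bad)) {
    stop("non-biallelic VCF record at line for marker ",
         fix[which(bad)[1], "ID"], " (", fix[which(bad)[1], "CHROM"], ":",
         fix[which(bad)[1], "POS"], ")")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no samples with GT field")
  alleles <- gsub("\\|", "/", gt)
  if (any(!is.na(alleles) & !grepl("/", alleles))) {
    i <- which(!is.na(alleles) & !grepl("/", alleles), arr.ind = TRUE)[1, ]
    stop("haploid GT call at marker ", rownames(gt)[i[1]],
         " sample ", colnames(gt)[i[2]])
  }
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    known <- is.na(x) | x %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (!all(known)) stop("malformed GT value '", x[!known][1], "'")
    out
  }
  # vcfR returns variants x samples; panel wants samples x markers
  geno <- t(matrix(code(as.vector(alleles)), nrow(alleles), ncol(alleles)))
  ids <- colnames(gt)
  mid <- fix[, "ID"]
  mid[is.na(mid) | mid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(mid) | mid == "."]
  if (is.null(genetic_map)) {
    stop("VCF input requires a genetic map to assign cM positions")
  }
  if (is.character(genetic_map)) genetic_map <- read_genetic_map(genetic_map)
  cm <- interpolate_cm(genetic_map, fix[, "CHROM"], as.integer(fix[, "POS"]))
  map <- marker_map(mid, fix[, "CHROM"], as.integer(fix[, "POS"]), cm,
                    major_allele = fix[, "REF"], minor_allele = alt)
  panel <- genotype_panel(ids, geno)
  compute_allele_stats(panel, map)
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("malformed .map file (need 4 columns): ", map_path)
  m <- nrow(mp)
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(ped) != 6L + 2L * m) {
    stop("malformed .ped record: expected ", 6L + 2L * m,
         " fields for ", m, " markers, found ", ncol(ped))
  }
  n <- nrow(ped)
  ids <- ped[[2]]
  if (anyDuplicated(ids)) ids <- paste(ped[[1]], ped[[2]], sep = "_")
  geno <- matrix(NA_integer_, n, m)
  a1_sym <- character(m)
  a2_sym <- character(m)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    sym <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(sym) > 2L) {
      stop("marker ", mp[[2]][j], " has more than two alleles in ", ped_path)
    }
    if (length(sym) == 0L) sym <- c("N", "N")
    if (length(sym) == 1L) sym <- c(sym, "N")   # monomorphic: placeholder minor
    geno[!miss, j] <- (a1[!miss] == sym[2]) + (a2[!miss] == sym[2])
    a1_sym[j] <- sym[1]
    a2_sym[j] <- sym[2]
  }
  map <- marker_map(mp[[2]], mp[[1]], as.integer(mp[[4]]), as.numeric(mp[[3]]),
                    major_allele = a1_sym, minor_allele = a2_sym)
  panel <- genotype_panel(ids, geno)
  compute_allele_stats(panel, map)
}

#' Write genotypes to VCF or PLINK text files
#'
#' The inverse of [read_genotypes()]. For `"plink_text"`, writes
#' `<path>.ped` and `<path>.map` (the `.map` third column carries the cM
#' positions, so a PLINK round trip is lossless). For `"vcf"` a plain-text
#' VCF is written with REF = major and ALT = minor allele; cM positions are
#' not representable in VCF and must be re-supplied on reading.
#'
#' @param panel a [genotype_panel()] coded as minor-allele counts.
#' @param map the matching [marker_map()].
#' @param path output path (PLINK prefix, or VCF file name).
#' @param format `"vcf"` or `"plink_text"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, map, path,
                            format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  stopifnot(ncol(panel$geno) == nrow(map))
  if (format == "plink_text") {
    write.table(data.frame(map$chrom, map$marker_id, map$cm, map$bp),
                paste0(path, ".map"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    n <- nrow(panel$geno)
    g <- panel$geno
    maj <- map$major_allele
    mnr <- map$minor_allele
    lines <- vapply(seq_len(n), function(i) {
      gi <- g[i, ]
      a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, mnr, maj))
      a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, mnr, maj))
      paste(c(panel$ids[i], panel$ids[i], "0", "0", "0", "-9",
              as.vector(rbind(a1, a2))), collapse = " ")
    }, character(1))
    writeLines(lines, paste0(path, ".ped"))
  } else {
    gt <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(nrow(map)), function(j) {
      gj <- panel$geno[, j]
      calls <- ifelse(is.na(gj), "./.", gt[gj + 1L])
      paste(c(map$chrom[j], map$bp[j], map$marker_id[j],
              map$major_allele[j], map$minor_allele[j], ".", "PASS", ".",
              "GT", calls), collapse = "\t")
    }, character(1))
    header <- c("##fileformat=VCFv4.2",
                "##source=ibdscreen",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", panel$ids), collapse = "\t"))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Write a candidate report to a tab-delimited file
#'
#' Metadata (query id, parameters, candidate fraction) is written as leading
#' `#`-prefixed lines followed by a header line and one row per candidate
#' segment.
#'
#' @param report a `candidate_report` from [run_query()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  stopifnot(inherits(report, "candidate_report"))
  meta <- c(
    paste0("# query_id: ", report$query_id),
    paste0("# candidate_fraction: ",
           format(report$candidate_fraction, digits = 15)),
    paste0("# params: ", jsonlite::toJSON(report$params, auto_unbox = TRUE))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  suppressWarnings(write.table(report$segments, con, quote = FALSE,
                               sep = "\t", row.names = FALSE))
  invisible(path)
}

#' Read a candidate report written by [write_candidate_report()]
#'
#' @param path input file.
#' @return a `candidate_report` object.
#' @export
read_candidate_report <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), meta, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  segments <- if (length(body) > 1L) {
    read.table(text = body, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE, colClasses = c(indexed_id = "character",
                                                        chrom = "character"))
  } else {
    empty_segments()
  }
  structure(list(query_id = get("query_id"),
                 segments = segments,
                 candidate_fraction = as.numeric(get("candidate_fraction")),
                 params = jsonlite::fromJSON(get("params"))),
            class = "candidate_report")
}

empty_segments <- function() {
  data.frame(indexed_id = character(), chrom = character(),
             start_cm = numeric(), end_cm = numeric(),
             start_bp = integer(), end_bp = integer(),
             stringsAsFactors = FALSE)
}
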