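#' Construct a per-site allele-count table
#'
#' The basic container of the pipeline: one row per reference position with
#' read counts for the four nucleotides, an `other` count for ambiguous bases
#' (which contribute to depth but are never candidate alleles), and the number
#' of reads carrying indel evidence at or across the site. Depth is always the
#' row sum `A + C + G + T + other`.
#'
#' @param contig character vector of reference sequence names.
#' @param pos integer vector of 1-based positions.
#' @param ref reference base at each site, one of `A`, `C`, `G`, `T`, `N`.
#' @param A,C,G,T non-negative integer read counts per base.
#' @param other reads whose base is not one of the four nucleotides
#'   (e.g. `N` calls); counted in depth only.
#' @param indel number of reads with an insertion or deletion starting at or
#'   spanning the site.
#' @return A `data.frame` of class `site_counts` with columns `contig`, `pos`,
#'   `ref`, `A`, `C`, `G`, `T`, `other`, `indel`, `depth`.
#' @examples
#' site_counts("g1", 100, "A", A = 24, C = 6)
#' @export
site_counts <- function(contig, pos, ref, A = 0L, C = 0L, G = 0L, T = 0L,
                        other = 0L, indel = 0L) {
  n <- length(pos)
  df <- data.frame(
    contig = as.character(contig),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    A = as.integer(A), C = as.integer(C), G = as.integer(G), T = as.integer(T),
    other = as.integer(rep_len(other, n)),
    indel = as.integer(rep_len(indel, n)),
    stringsAsFactors = FALSE
  )
  cnt <- as.matrix(df[, c("A", "C", "G", "T", "other", "indel")])
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("site_counts: counts must be non-negative integers")
  }
  if (any(df$pos < 1L)) stop("site_counts: positions must be >= 1")
  if (!all(df$ref %in% c("A", "C", "G", "T", "N"))) {
    stop("site_counts: ref base must be one of A, C, G, T, N")
  }
  df$depth <- df$A + df$C + df$G + df$T + df$other
  class(df) <- c("site_counts", "data.frame")
  df
}

#' Read the native per-site count table
#'
#' Parses the tab-separated pileup dialect
#' `contig  pos  ref  A  C  G  T  indel_count` (no header, 1-based positions).
#' Depth is the sum of the four base counts. Rows are returned in file order.
#'
#' @param path path to a TSV file in the dialect above.
#' @return A [site_counts] data frame.
#' @seealso [write_pileup()] for the inverse, [read_sync()] for the
#'   PoPoolation2-style sync importer.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(site_counts(character(0), integer(0), character(0),
                       integer(0), integer(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    bad <- which(nf != 8L)[1L]
    stop(sprintf("read_pileup: malformed row at line %d (expected 8 fields, got %d)",
                 bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, c(2L, 4L:8L), drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 6L)
  if (any(is.na(num))) {
    bad <- which(apply(is.na(num), 1L, any))[1L]
    stop(sprintf("read_pileup: malformed row at line %d (non-numeric field)", bad))
  }
  if (any(num[, 2L:6L] < 0)) {
    bad <- which(apply(num[, 2L:6L, drop = FALSE] < 0, 1L, any))[1L]
    stop(sprintf("read_pileup: negative count at line %d", bad))
  }
  site_counts(contig = m[, 1L], pos = num[, 1L], ref = m[, 3L],
              A = num[, 2L], C = num[, 3L], G = num[, 4L], T = num[, 5L],
              indel = num[, 6L])
}

#' Write the native per-site count table
#'
#' Inverse of [read_pileup()]; a read/write round trip of a well-formed file
#' is byte-identical. The `other` column is not representable in the dialect
#' and must be zero.
#'
#' @param sites a [site_counts] data frame.
#' @param path output path.
#' @export
write_pileup <- function(sites, path) {
  if (any(sites$other != 0L)) {
    stop("write_pileup: the native dialect cannot carry 'other' base counts")
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%d\t%d\t%d",
                   sites$contig, sites$pos, sites$ref,
                   sites$A, sites$C, sites$G, sites$T, sites$indel)
  writeLines(lines, path)
  invisible(path)
}

#' Import an mpileup-derived sync count table
#'
#' Reads the PoPoolation2-style synchronized format: `contig  pos  ref` then
#' one `A:T:C:G:N:del` column per pool. `N` counts go to `other` (depth only)
#' and `del` counts become indel evidence.
#'
#' @param path path to a sync file.
#' @param pool which pool column to use (1-based), if several are present.
#' @return A [site_counts] data frame.
#' @export
read_sync <- function(path, pool = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(site_counts(character(0), integer(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L + pool)) {
    bad <- which(nf < 3L + pool)[1L]
    stop(sprintf("read_sync: line %d has no pool column %d", bad, pool))
  }
  m <- matrix(unlist(lapply(fields, `[`, c(1L:3L, 3L + pool))), ncol = 4L, byrow = TRUE)
  cnt <- strsplit(m[, 4L], ":", fixed = TRUE)
  if (any(lengths(cnt) != 6L)) {
    bad <- which(lengths(cnt) != 6L)[1L]
    stop(sprintf("read_sync: malformed count column at line %d", bad))
  }
  cm <- matrix(as.integer(unlist(cnt)), ncol = 6L, byrow = TRUE)
  site_counts(contig = m[, 1L], pos = as.integer(m[, 2L]), ref = m[, 3L],
              A = cm[, 1L], T = cm[, 2L], C = cm[, 3L], G = cm[, 4L],
              other = cm[, 5L], indel = cm[, 6L])
}

#' Coverage distribution over the targeted region
#'
#' For each depth threshold, the fraction of sites whose coverage is at least
#' that deep — the complementary CDF used to summarize enrichment success
#' (e.g. "50% of the target has coverage of 346x or more").
#'
#' @param depths per-site depths over the region of interest (non-empty).
#' @param thresholds integer depth cut-offs.
#' @return Named numeric vector: for each threshold `d`, the fraction of sites
#'   with `depth >= d`. Non-increasing in `d`.
#' @examples
#' coverage_cdf(c(10, 20, 30, 40), thresholds = c(5, 25, 50))
#' @export
coverage_cdf <- function(depths, thresholds) {
  if (length(depths) == 0L) stop("coverage_cdf: depths must be non-empty")
  out <- vapply(thresholds, function(d) mean(depths >= d), numeric(1))
  names(out) <- thresholds
  out
}
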