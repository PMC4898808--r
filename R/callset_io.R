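#' Construct a call set
#'
#' A keyed collection of pooled SNP calls. Each call carries the reference
#' base, the minor allele (second-most-frequent base in the pool), the
#' variant (non-reference) allele, the minor read count, total depth, the
#' pooled minor-allele frequency `af = minor_count / depth` and the estimated
#' copy class `k = clamp(round(af * pool_n), 1, pool_n - 1)` out of `pool_n`
#' chromosomes.
#'
#' @param contig,pos,ref,minor,alt,minor_count,depth call fields (vectors).
#' @param pool_n chromosomes in the pool.
#' @return A `data.frame` of class `call_set` with an additional `pool_n`
#'   attribute.
#' @export
call_set <- function(contig = character(0), pos = integer(0),
                     ref = character(0), minor = character(0),
                     alt = character(0), minor_count = integer(0),
                     depth = integer(0), pool_n = 20L) {
  af <- if (length(depth)) as.numeric(minor_count) / depth else numeric(0)
  k <- if (length(af)) pmin(pmax(round_half_up(af * pool_n), 1L), pool_n - 1L) else integer(0)
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = as.character(ref), minor = as.character(minor),
                   alt = as.character(alt),
                   minor_count = as.integer(minor_count),
                   depth = as.integer(depth),
                   af = af, k = as.integer(k), stringsAsFactors = FALSE)
  attr(df, "pool_n") <- as.integer(pool_n)
  class(df) <- c("call_set", "data.frame")
  df
}

# deterministic half-up rounding (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

callset_key <- function(cs, with_allele = TRUE) {
  if (with_allele) paste(cs$contig, cs$pos, cs$minor) else paste(cs$contig, cs$pos)
}

#' Write a call set as a VCF subset
#'
#' Emits a minimal VCF v4.2 file with one record per call: `CHROM POS ID REF
#' ALT QUAL FILTER INFO`, where INFO carries `MC` (minor-allele read count),
#' `DP` (depth) and `AF` (pooled minor-allele frequency). The ALT column holds
#' the variant (non-reference) allele.
#'
#' @param calls a [call_set].
#' @param path output path.
#' @export
write_callset_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolrens",
    sprintf("##poolrens_pool_n=%d", attr(calls, "pool_n")),
    '##INFO=<ID=MC,Number=1,Type=Integer,Description="Minor allele read count">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Pooled minor allele frequency">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMC=%d;DP=%d;AF=%s",
                  calls$contig, calls$pos, calls$ref, calls$alt,
                  calls$minor_count, calls$depth,
                  formatC(calls$af, format = "g", digits = 8))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a call set from a VCF file
#'
#' Imports VCF v4.x records into a [call_set]. Files written by
#' [write_callset_vcf()] round-trip exactly; externally produced VCFs (e.g.
#' from a diploid/pooled caller run) are accepted as long as they carry `DP`
#' and either `MC` or `AF` in INFO — missing counts are reconstructed from
#' `AF * DP`. The minor allele is the ALT allele when `AF <= 0.5`, otherwise
#' the REF base (frequencies fold onto the minor allele).
#'
#' @param path path to a VCF file.
#' @param pool_n chromosomes in the pool (read from the
#'   `##poolrens_pool_n` header line when present).
#' @return A [call_set].
#' @export
read_callset_vcf <- function(path, pool_n = 20L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  pn <- grep("^##poolrens_pool_n=", meta, value = TRUE)
  if (length(pn)) pool_n <- as.integer(sub("^##poolrens_pool_n=", "", pn[1L]))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(call_set(pool_n = pool_n))
  dp <- as.integer(vcfR::extract.info(v, "DP"))
  mc <- suppressWarnings(as.integer(vcfR::extract.info(v, "MC")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  if (all(is.na(mc))) {
    if (all(is.na(af))) stop("read_callset_vcf: INFO must carry MC or AF")
    mc <- as.integer(round_half_up(pmin(af, 1 - af) * dp))
  }
  af_full <- ifelse(is.na(af), mc / dp, af)
  minor <- ifelse(af_full <= 0.5, fix$ALT, fix$REF)
  call_set(contig = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
           minor = minor, alt = fix$ALT, minor_count = mc, depth = dp,
           pool_n = pool_n)
}
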