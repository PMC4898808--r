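#' Construct a CDS gene model
#'
#' Holds the coding structure of one gene: ordered CDS segments (1-based,
#' inclusive, genomic coordinates), strand and the phase of the first segment
#' in transcript orientation. Segments are stored 5'->3' in transcript
#' orientation, i.e. by decreasing genomic coordinate on the minus strand.
#'
#' @param gene_id gene identifier.
#' @param contig reference sequence name.
#' @param segments two-column matrix (start, end) of CDS segments, 1-based
#'   inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @param phase phase of the first segment (0, 1 or 2): bases to skip before
#'   the first complete codon.
#' @return A list of class `gene_model` with fields `gene_id`, `contig`,
#'   `segments`, `strand`, `phase`, `cds_length` and `codon_ok` (whether the
#'   phase-adjusted CDS length is a multiple of 3, hence usable for codon
#'   analysis).
#' @export
gene_model <- function(gene_id, contig, segments, strand = "+", phase = 0L) {
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (any(segments[, "end"] < segments[, "start"])) {
    stop("gene_model: segment end before start")
  }
  if (!strand %in% c("+", "-")) stop("gene_model: strand must be '+' or '-'")
  # order in transcript orientation and reject overlaps
  o <- order(segments[, "start"], decreasing = (strand == "-"))
  segments <- segments[o, , drop = FALSE]
  g <- segments[order(segments[, "start"]), , drop = FALSE]
  if (nrow(g) > 1L && any(g[-1L, "start"] <= g[-nrow(g), "end"])) {
    stop(sprintf("gene_model: overlapping CDS segments in gene '%s'", gene_id))
  }
  len <- sum(segments[, "end"] - segments[, "start"] + 1L)
  ok <- ((len - as.integer(phase)) %% 3L) == 0L
  structure(list(gene_id = as.character(gene_id), contig = as.character(contig),
                 segments = segments, strand = strand, phase = as.integer(phase),
                 cds_length = as.integer(len), codon_ok = ok),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s), %d segment(s), CDS %d bp%s\n",
              x$gene_id, x$contig, x$strand, nrow(x$segments), x$cds_length,
              if (x$codon_ok) "" else " [frame broken]"))
  invisible(x)
}

#' Read CDS gene models from a GFF3 file
#'
#' Assembles one [gene_model] per parent from the `CDS` features of a GFF3
#' file. Segments are ordered in transcript orientation; strand and the phase
#' of the first segment are honored. Genes whose phase-adjusted CDS length is
#' not a multiple of 3 are kept but flagged (`codon_ok = FALSE`) with a
#' warning: they are unusable for codon-based analysis.
#'
#' @param path path to a GFF3 file with CDS features carrying a `Parent` (or
#'   `ID`) attribute.
#' @return Named list of [gene_model] objects, keyed by gene id.
#' @export
read_gff_cds <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  parent <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  } else {
    as.character(gr$ID)
  }
  if (anyNA(parent)) stop("read_gff_cds: CDS feature without Parent/ID attribute")
  out <- lapply(split(seq_along(gr), parent), function(idx) {
    sub <- gr[idx]
    strand <- as.character(S4Vectors::runValue(GenomicRanges::strand(sub)))[1L]
    if (strand == "*") strand <- "+"
    st <- GenomicRanges::start(sub)
    en <- GenomicRanges::end(sub)
    o <- order(st, decreasing = (strand == "-"))
    ph <- suppressWarnings(as.integer(as.character(sub$phase)))
    ph1 <- ph[o][1L]
    if (is.na(ph1)) ph1 <- 0L
    gene_model(gene_id = parent[idx][1L],
               contig = as.character(GenomicRanges::seqnames(sub))[1L],
               segments = cbind(st, en)[o, , drop = FALSE],
               strand = strand, phase = ph1)
  })
  bad <- names(out)[!vapply(out, `[[`, logical(1), "codon_ok")]
  if (length(bad)) {
    warning(sprintf("read_gff_cds: CDS length not a multiple of 3 for: %s (flagged codon_ok = FALSE)",
                    paste(bad, collapse = ", ")))
  }
  out
}

#' Write CDS gene models to a GFF3 file
#'
#' Inverse of [read_gff_cds()]: emits one `CDS` feature per segment with a
#' `Parent` attribute. A write/read round trip preserves segment coordinates,
#' strand and phase.
#'
#' @param genes named list of [gene_model] objects.
#' @param path output path.
#' @export
write_gff_cds <- function(genes, path) {
  rows <- do.call(rbind, lapply(genes, function(g) {
    seg <- g$segments
    # phase of downstream segments from cumulative coding length
    lens <- seg[, "end"] - seg[, "start"] + 1L
    ph <- integer(nrow(seg))
    ph[1L] <- g$phase
    if (nrow(seg) > 1L) {
      for (i in 2L:nrow(seg)) ph[i] <- (3L - (sum(lens[1:(i - 1L)]) - ph[1L]) %% 3L) %% 3L
    }
    data.frame(contig = g$contig, start = seg[, "start"], end = seg[, "end"],
               strand = g$strand, phase = ph, parent = g$gene_id,
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  gr$source <- "poolrens"
  gr$type <- "CDS"
  gr$phase <- rows$phase
  gr$ID <- sprintf("cds-%s-%d", rows$parent, seq_len(nrow(rows)))
  gr$Parent <- rows$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Map genomic positions to CDS coordinates
#'
#' @param gene a [gene_model].
#' @param pos genomic positions (1-based).
#' @return Integer vector: 1-based index of each position along the coding
#'   sequence in transcript orientation, or `NA` for positions outside the
#'   CDS. The phase offset is already subtracted, so index 1 is the first base
#'   of the first complete codon.
#' @keywords internal
cds_index <- function(gene, pos) {
  seg <- gene$segments
  lens <- seg[, "end"] - seg[, "start"] + 1L
  offs <- cumsum(c(0L, lens[-length(lens)]))
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(seg))) {
    inside <- pos >= seg[i, "start"] & pos <= seg[i, "end"]
    within <- if (gene$strand == "+") pos - seg[i, "start"] else seg[i, "end"] - pos
    idx[inside] <- offs[i] + within[inside] + 1L
  }
  idx - gene$phase
}

#' Extract the coding sequence of a gene
#'
#' @param gene a [gene_model].
#' @param ref_seqs a [Biostrings::DNAStringSet] containing the gene's contig.
#' @return A `DNAString` with the phase-adjusted coding sequence in transcript
#'   orientation (reverse-complemented for minus-strand genes).
#' @export
cds_sequence <- function(gene, ref_seqs) {
  contig <- ref_seqs[[gene$contig]]
  seg <- gene$segments
  parts <- lapply(seq_len(nrow(seg)), function(i) {
    s <- Biostrings::subseq(contig, seg[i, "start"], seg[i, "end"])
    if (gene$strand == "-") Biostrings::reverseComplement(s) else s
  })
  out <- do.call(Biostrings::xscat, parts)
  if (gene$phase > 0L) out <- Biostrings::subseq(out, gene$phase + 1L)
  out
}
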