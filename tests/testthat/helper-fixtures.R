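# Small fixtures built in code, shared across test files.

# a tiny deterministic reference: 6 genes x 300 bp, one with an intron
tiny_reference <- function(seed = 11L) {
  generate_reference(sim_params(n_genes = 6L, gene_length_bp = 300L, seed = seed),
                     introns = TRUE)
}

# hand-built single-contig reference from an explicit sequence string
manual_reference <- function(seq, gene_id = "g1", strand = "+",
                             segments = cbind(1L, nchar(seq))) {
  seqs <- Biostrings::DNAStringSet(seq)
  names(seqs) <- gene_id
  genes <- list(gene_model(gene_id, gene_id, segments, strand = strand))
  names(genes) <- gene_id
  list(sequences = seqs, genes = genes)
}

# a pool_truth data frame from explicit fields
manual_truth <- function(contig, pos, ref, alt, k, effect = NA_character_,
                         pool_n = 20L) {
  df <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt, k = k,
                   effect = effect, stringsAsFactors = FALSE)
  attr(df, "pool_n") <- pool_n
  class(df) <- c("pool_truth", "data.frame")
  df
}

# independent whole-sequence translation oracle for substitution effects:
# mutate the contig, re-extract and translate the CDS, compare proteins.
oracle_effect <- function(pos, alt, gene, ref_seqs) {
  idx <- poolrens:::cds_index(gene, pos)
  if (is.na(idx) || idx < 1L) return("non-coding")
  mutated <- ref_seqs
  s <- as.character(mutated[[gene$contig]])
  substr(s, pos, pos) <- alt
  mutated[[gene$contig]] <- Biostrings::DNAString(s)
  p0 <- Biostrings::translate(cds_sequence(gene, ref_seqs))
  p1 <- Biostrings::translate(cds_sequence(gene, mutated))
  if (as.character(p0) == as.character(p1)) "synonymous" else "nonsynonymous"
}
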