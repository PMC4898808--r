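#' Simulation parameters for the pooled enrichment design
#'
#' Defaults emulate the study design the pipeline targets: a pool of 10
#' diploid plants (20 chromosomes, equal DNA per plant), 220 target genes
#' with kb-scale coding sequences, 13/220 genes carrying polymorphism, deep
#' exon-targeted coverage (median around 346x with the long overdispersed
#' spread characteristic of hybridization capture) and a small residual
#' per-base miscall rate after stringent quality trimming.
#'
#' @param n_genes number of target genes.
#' @param gene_length_bp coding length per gene (multiple of 3).
#' @param n_plants diploid plants in the pool.
#' @param pool_n chromosomes in the pool (`2 * n_plants`; must be even).
#' @param polymorphic_fraction probability a gene carries at least one
#'   segregating site (used when no propagation scenario is supplied).
#' @param snp_intensity expected segregating sites per polymorphic gene.
#' @param mean_coverage expected per-site depth.
#' @param coverage_dispersion negative-binomial size parameter of the depth
#'   distribution; smaller means more overdispersed. The default reproduces
#'   the observed first-quartile/median coverage relation of enrichment data
#'   (about 0.73).
#' @param error_rate per-base miscall probability after quality trimming,
#'   in `[0, 0.01]`.
#' @param seed RNG seed recorded with the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 220L, gene_length_bp = 1200L,
                       n_plants = 10L, pool_n = 2L * n_plants,
                       polymorphic_fraction = 13 / 220,
                       snp_intensity = 18,
                       mean_coverage = 346, coverage_dispersion = 6,
                       error_rate = 0.002, seed = 1L) {
  if (gene_length_bp %% 3L != 0L) stop("gene_length_bp must be a multiple of 3")
  if (pool_n %% 2L != 0L) stop("pool_n must be even")
  if (polymorphic_fraction < 0 || polymorphic_fraction > 1) {
    stop("polymorphic_fraction must be in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 0.01) stop("error_rate must be in [0, 0.01]")
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_bp = as.integer(gene_length_bp),
                 n_plants = as.integer(n_plants), pool_n = as.integer(pool_n),
                 polymorphic_fraction = polymorphic_fraction,
                 snp_intensity = snp_intensity,
                 mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_params")
}

SENSE_CODONS <- local({
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
})

#' Generate a synthetic reference with gene models
#'
#' Builds `n_genes` reference sequences, each an open reading frame starting
#' with `ATG` and free of internal stop codons, together with a [gene_model]
#' covering it. Every tenth gene is split into two exons by a 120-bp intron
#' to exercise multi-segment CDS assembly; the coding length is unchanged.
#' The annotated CDS covers coding positions only (no terminal stop codon),
#' so synonymous/nonsynonymous site totals sum exactly to the CDS length.
#'
#' @param params a [sim_params].
#' @param seed RNG seed (defaults to `params$seed`).
#' @param introns if `TRUE`, every tenth gene gets an intron.
#' @return List with `sequences` (a [Biostrings::DNAStringSet], one contig
#'   per gene) and `genes` (named list of [gene_model]).
#' @export
generate_reference <- function(params, seed = params$seed, introns = TRUE) {
  set.seed(seed)
  n_codons <- params$gene_length_bp %/% 3L
  seqs <- character(params$n_genes)
  genes <- vector("list", params$n_genes)
  ids <- sprintf("gene%03d", seq_len(params$n_genes))
  for (i in seq_len(params$n_genes)) {
    cds <- paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE),
                               collapse = ""))
    if (introns && i %% 10L == 0L) {
      # split mid-CDS at a codon boundary; intron carries a GT..AG skeleton
      cut <- 3L * (n_codons %/% 2L)
      intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"), 116L, replace = TRUE),
                                   collapse = ""), "AG")
      seqs[i] <- paste0(substr(cds, 1L, cut), intron,
                        substr(cds, cut + 1L, params$gene_length_bp))
      genes[[i]] <- gene_model(ids[i], ids[i],
                               segments = rbind(c(1L, cut),
                                                c(cut + 121L, params$gene_length_bp + 120L)),
                               strand = "+", phase = 0L)
    } else {
      seqs[i] <- cds
      genes[[i]] <- gene_model(ids[i], ids[i],
                               segments = cbind(1L, params$gene_length_bp),
                               strand = "+", phase = 0L)
    }
  }
  names(genes) <- ids
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ids
  list(sequences = sequences, genes = genes)
}

#' Generate the pooled population truth
#'
#' Draws, for each gene, whether it segregates in the sampled pool and at
#' which minor-allele copy number, then places segregating sites on the
#' coding sequence. With a [propagation_scenario], each gene is treated as a
#' locus of the propagation history: founded polymorphic with probability
#' `H0`, surviving the founding step with probability [founder_factor()],
#' drifting through `t_total - 1` Wright-Fisher rounds of `2N` chromosomes,
#' and finally sampled as `k ~ Binomial(pool_n, p)` alternative chromosomes.
#' All SNPs within a gene share the gene's copy number `k` — the pool
#' segregates two haplotypes per polymorphic gene, as expected after serial
#' bottlenecks of a selfing population. Without a scenario, genes segregate
#' with probability `polymorphic_fraction` at a copy number drawn directly
#' from the founding heterozygote (`k ~ Binomial(pool_n, 0.5)`).
#'
#' @param reference output of [generate_reference()].
#' @param params a [sim_params].
#' @param scenario optional [propagation_scenario] with `H0` set.
#' @param seed RNG seed (defaults to `params$seed + 1`).
#' @return A `data.frame` of class `pool_truth` with columns `contig`, `pos`,
#'   `ref`, `alt`, `k` (alternative-allele copies out of `pool_n`) and
#'   `effect` (`synonymous`, `nonsynonymous` or `non-coding`).
#' @export
generate_pool <- function(reference, params, scenario = NULL,
                          seed = params$seed + 1L) {
  set.seed(seed)
  n <- params$pool_n
  ng <- params$n_genes
  if (!is.null(scenario)) {
    if (is.na(scenario$H0)) stop("generate_pool: scenario must have H0 set")
    p <- simulate_locus_frequencies(ng, scenario)
    k_gene <- stats::rbinom(ng, n, p)
  } else {
    poly <- stats::rbinom(ng, 1L, params$polymorphic_fraction)
    k_gene <- poly * stats::rbinom(ng, n, 0.5)
  }
  seg <- which(k_gene >= 1L & k_gene <= n - 1L)
  rows <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seg) {
    g <- reference$genes[[i]]
    n_sites <- max(1L, stats::rpois(1L, params$snp_intensity))
    n_sites <- min(n_sites, g$cds_length)
    cds_pos <- genomic_cds_positions(g)
    pos <- sort(sample(cds_pos, n_sites))
    contig_seq <- as.character(reference$sequences[[g$contig]])
    ref_b <- substring(contig_seq, pos, pos)
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1L), character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      contig = g$contig, pos = pos, ref = ref_b, alt = alt_b,
      k = k_gene[i], stringsAsFactors = FALSE, row.names = NULL)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), k = integer(0), stringsAsFactors = FALSE)
  truth$effect <- if (nrow(truth)) {
    vapply(seq_len(nrow(truth)), function(j) {
      g <- reference$genes[[truth$contig[j]]]
      classify_substitution_effect(truth$pos[j], truth$alt[j], g, reference$sequences)
    }, character(1))
  } else character(0)
  attr(truth, "pool_n") <- n
  class(truth) <- c("pool_truth", "data.frame")
  truth
}

# all genomic positions covered by a gene's CDS segments, transcript order ignored
genomic_cds_positions <- function(gene) {
  unlist(lapply(seq_len(nrow(gene$segments)), function(i) {
    seq.int(gene$segments[i, "start"], gene$segments[i, "end"])
  }), use.names = FALSE)
}

#' Sample pooled read counts for one or more sites
#'
#' The count model behind [generate_pileup()], exposed for direct use: each
#' of `depth` reads carries the alternative allele with probability
#' `alt_freq`, then every read base is independently miscalled to one of the
#' three other bases (uniformly) with probability `error_rate`.
#'
#' @param depth integer vector of read depths.
#' @param ref,alt reference and alternative base per site (alt ignored where
#'   `alt_freq` is 0).
#' @param alt_freq true alternative-allele frequency per site.
#' @param error_rate per-base miscall probability.
#' @return Integer matrix with columns `A`, `C`, `G`, `T`.
#' @export
sample_site_counts <- function(depth, ref, alt = ref, alt_freq = 0,
                               error_rate = 0) {
  ns <- length(depth)
  ref <- rep_len(ref, ns); alt <- rep_len(alt, ns)
  alt_freq <- rep_len(alt_freq, ns)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = ns, ncol = 4L, dimnames = list(NULL, bases))
  alt_n <- stats::rbinom(ns, depth, alt_freq)
  ref_n <- depth - alt_n
  ri <- match(ref, bases); ai <- match(alt, bases)
  p1 <- error_rate / 3
  for (src in list(list(n = ref_n, b = ri), list(n = alt_n, b = ai))) {
    # multinomial split (kept, err1, err2, err3) via sequential binomials
    x1 <- stats::rbinom(ns, src$n, p1)
    x2 <- stats::rbinom(ns, src$n - x1, if (p1 > 0) p1 / (1 - p1) else 0)
    x3 <- stats::rbinom(ns, src$n - x1 - x2, if (p1 > 0) p1 / (1 - 2 * p1) else 0)
    kept <- src$n - x1 - x2 - x3
    counts[cbind(seq_len(ns), src$b)] <- counts[cbind(seq_len(ns), src$b)] + kept
    # the three miscall targets per site: the bases other than the source
    others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
    tgt <- others[src$b, , drop = FALSE]
    counts[cbind(seq_len(ns), tgt[, 1L])] <- counts[cbind(seq_len(ns), tgt[, 1L])] + x1
    counts[cbind(seq_len(ns), tgt[, 2L])] <- counts[cbind(seq_len(ns), tgt[, 2L])] + x2
    counts[cbind(seq_len(ns), tgt[, 3L])] <- counts[cbind(seq_len(ns), tgt[, 3L])] + x3
  }
  counts
}

#' Generate pileup-style counts from reference and truth
#'
#' Per-site depths are drawn from a negative binomial with mean
#' `mean_coverage` and size `coverage_dispersion` (enrichment capture makes
#' coverage strongly overdispersed). At segregating sites each read carries
#' the alternative allele with probability `k / pool_n`; every read base is
#' then miscalled uniformly to another base with probability `error_rate`.
#' Optionally, indel evidence is injected at chosen positions to exercise
#' the caller's indel-proximity mask.
#'
#' @param reference output of [generate_reference()].
#' @param truth a `pool_truth` from [generate_pool()].
#' @param params a [sim_params].
#' @param seed RNG seed (defaults to `params$seed + 2`).
#' @param indel_positions optional `data.frame(contig, pos)` where indel
#'   evidence (10% of reads) should be recorded.
#' @return A [site_counts] data frame covering every position of every
#'   contig, in reference order.
#' @export
generate_pileup <- function(reference, truth, params, seed = params$seed + 2L,
                            indel_positions = NULL) {
  set.seed(seed)
  widths <- Biostrings::width(reference$sequences)
  contigs <- rep(names(reference$sequences), widths)
  pos <- unlist(lapply(widths, seq_len), use.names = FALSE)
  refb <- unlist(strsplit(as.character(reference$sequences), ""), use.names = FALSE)
  ns <- length(pos)
  depth <- stats::rnbinom(ns, size = params$coverage_dispersion,
                          mu = params$mean_coverage)
  key <- paste(contigs, pos)
  alt <- refb
  altf <- numeric(ns)
  if (nrow(truth)) {
    idx <- match(paste(truth$contig, truth$pos), key)
    alt[idx] <- truth$alt
    altf[idx] <- truth$k / params$pool_n
  }
  cm <- sample_site_counts(depth, refb, alt, altf, params$error_rate)
  indel <- integer(ns)
  if (!is.null(indel_positions) && nrow(indel_positions)) {
    ii <- match(paste(indel_positions$contig, indel_positions$pos), key)
    indel[ii] <- pmax(1L, as.integer(round(0.1 * depth[ii])))
  }
  site_counts(contig = contigs, pos = pos, ref = refb,
              A = cm[, "A"], C = cm[, "C"], G = cm[, "G"], T = cm[, "T"],
              indel = indel)
}

#' Write / read the truth table
#'
#' Plain-TSV serialization of a `pool_truth` (`contig pos ref alt k effect`,
#' with header).
#'
#' @param truth a `pool_truth`.
#' @param path file path.
#' @param pool_n chromosomes in the pool (for [read_truth()]).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path, pool_n = 20L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "character", "integer", "character"))
  attr(df, "pool_n") <- as.integer(pool_n)
  class(df) <- c("pool_truth", "data.frame")
  df
}
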