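test_that("Nei-Gojobori site counts match frozen values and conserve 3 per codon", {
  atg <- ng_site_counts("ATG")
  expect_equal(atg$n_sites, 3)
  expect_equal(atg$s_sites, 0)

  ttt <- ng_site_counts("TTT")
  expect_equal(ttt$n_sites, 8 / 3)
  expect_equal(ttt$s_sites, 1 / 3)

  expect_error(ng_site_counts("ANT"), "unambiguous")
  expect_true(ng_site_counts("TAA")$is_stop)
})

test_that("site counts agree with exhaustive 9-mutant enumeration for all 61 sense codons", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  for (codon in sense) {
    # independent oracle: enumerate the 9 single-base mutants directly
    b <- strsplit(codon, "")[[1]]
    syn <- 0
    for (p in 1:3) for (nb in setdiff(bases, b[p])) {
      m <- b; m[p] <- nb
      if (code[paste(m, collapse = "")] == code[codon]) syn <- syn + 1
    }
    got <- ng_site_counts(codon)
    expect_equal(got$s_sites, syn / 3, info = codon)
    expect_equal(got$n_sites + got$s_sites, 3, info = codon)
  }
})

test_that("SNP effects are classified against the reference codon", {
  # TTT -> TTC is synonymous (Phe/Phe); ATG -> GTG is Met -> Val
  ref <- manual_reference(paste0("ATG", "TTT", "GGC"), gene_id = "g1")
  mkcall <- function(pos, alt) {
    call_set(contig = "g1", pos = pos, ref = "X", minor = alt, alt = alt,
             minor_count = 6L, depth = 30L)
  }
  expect_equal(classify_snp_effect(mkcall(6L, "C"), ref$genes$g1, ref$sequences),
               "synonymous")
  expect_equal(classify_snp_effect(mkcall(1L, "G"), ref$genes$g1, ref$sequences),
               "nonsynonymous")

  # intron position of a two-exon gene is non-coding
  two <- manual_reference(paste0("ATGTTT", paste(rep("A", 30), collapse = ""), "GGCTAG"),
                          gene_id = "g2",
                          segments = rbind(c(1L, 6L), c(37L, 42L)))
  expect_equal(classify_snp_effect(mkcall(20L, "C"), two$genes$g2, two$sequences),
               "non-coding")

  # minus-strand gene: evaluated on the reverse complement
  # genomic CCCCAT reversed-complemented is ATGGGG (Met-Gly)
  minus <- manual_reference("CCCCAT", gene_id = "g3",
                            segments = cbind(1L, 6L))
  minus$genes$g3 <- gene_model("g3", "g3", cbind(1L, 6L), strand = "-")
  # genomic position 1 is the last CDS base; C->T there makes GGG -> GGA (Gly/Gly)
  expect_equal(classify_snp_effect(mkcall(1L, "T"), minus$genes$g3, minus$sequences),
               "synonymous")
  # genomic position 6 is the first CDS base; T->C makes ATG -> GTG... on the
  # reverse complement A->G, Met -> Val
  expect_equal(classify_snp_effect(mkcall(6L, "C"), minus$genes$g3, minus$sequences),
               "nonsynonymous")
})

test_that("classification matches the translation oracle on generated data", {
  p <- sim_params(n_genes = 12L, gene_length_bp = 300L,
                  polymorphic_fraction = 0.8, snp_intensity = 5, seed = 41L)
  ref <- generate_reference(p)
  truth <- generate_pool(ref, p)
  expect_gt(nrow(truth), 10L)
  for (j in seq_len(nrow(truth))) {
    g <- ref$genes[[truth$contig[j]]]
    cl <- call_set(contig = truth$contig[j], pos = truth$pos[j],
                   ref = truth$ref[j], minor = truth$alt[j],
                   alt = truth$alt[j], minor_count = 6L, depth = 30L)
    expect_equal(classify_snp_effect(cl, g, ref$sequences),
                 oracle_effect(truth$pos[j], truth$alt[j], g, ref$sequences))
  }
})

test_that("per-site diversity applies the pooled unbiasedness factor", {
  expect_equal(site_pi(0, 20), 0)
  expect_equal(site_pi(0.5, 20), 0.5 * 20 / 19)
  expect_equal(site_pi(0.2, 20), 0.32 * 20 / 19)
  expect_equal(site_pi(0.5, 20, unbiased = FALSE), 0.5)
  expect_error(site_pi(1.2, 20), "\\[0, 1\\]")
})

test_that("gene_diversity matches an independent hand computation", {
  # 300-bp toy gene: one synonymous SNP at af 0.3, one nonsynonymous at af 0.1
  p <- sim_params(n_genes = 1L, gene_length_bp = 300L, seed = 55L)
  ref <- generate_reference(p, introns = FALSE)
  g <- ref$genes[[1]]
  cds <- as.character(cds_sequence(g, ref$sequences))

  # find a synonymous and a nonsynonymous single-base change by scanning
  code <- Biostrings::GENETIC_CODE
  syn_pos <- NA; syn_alt <- NA; non_pos <- NA; non_alt <- NA
  for (pos in seq_len(nchar(cds))) {
    cstart <- 3 * ((pos - 1) %/% 3) + 1
    codon <- substr(cds, cstart, cstart + 2)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(cds, pos, pos))) {
      mut <- codon
      substr(mut, pos - cstart + 1, pos - cstart + 1) <- alt
      if (code[mut] == "*") next
      if (is.na(syn_pos) && code[mut] == code[codon]) { syn_pos <- pos; syn_alt <- alt }
      if (is.na(non_pos) && code[mut] != code[codon]) { non_pos <- pos; non_alt <- alt }
    }
    if (!is.na(syn_pos) && !is.na(non_pos)) break
  }
  calls <- rbind(
    call_set("gene001", syn_pos, ref = substr(cds, syn_pos, syn_pos),
             minor = syn_alt, alt = syn_alt, minor_count = 30L, depth = 100L),
    call_set("gene001", non_pos, ref = substr(cds, non_pos, non_pos),
             minor = non_alt, alt = non_alt, minor_count = 10L, depth = 100L))
  class(calls) <- c("call_set", "data.frame")
  attr(calls, "pool_n") <- 20L

  ds <- gene_diversity(g, calls, ref$sequences, pool_n = 20L)

  # oracle: sum the per-codon enumeration and the two site formulas directly
  Ns <- 0; Ss <- 0
  for (ci in seq_len(nchar(cds) / 3)) {
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    b <- strsplit(codon, "")[[1]]
    syn <- 0
    for (q in 1:3) for (nb in setdiff(c("A", "C", "G", "T"), b[q])) {
      m <- b; m[q] <- nb
      if (code[paste(m, collapse = "")] == code[codon]) syn <- syn + 1
    }
    Ss <- Ss + syn / 3; Ns <- Ns + 3 - syn / 3
  }
  pi_syn <- 2 * 0.3 * 0.7 * 20 / 19
  pi_non <- 2 * 0.1 * 0.9 * 20 / 19
  expect_equal(ds$N_sites, Ns)
  expect_equal(ds$S_sites, Ss)
  expect_equal(ds$N_sites + ds$S_sites, 300)
  expect_equal(ds$piS, pi_syn / Ss)
  expect_equal(ds$piN, pi_non / Ns)
  expect_equal(ds$pi_per_gene, (pi_syn + pi_non) / 300)
  expect_equal(ds$piN_piS, (pi_non / Ns) / (pi_syn / Ss))
  expect_equal(ds$n_snps, 2L)
})

test_that("piN/piS edge conventions: undefined when piS = 0, zero when piN = 0", {
  p <- sim_params(n_genes = 1L, gene_length_bp = 300L, seed = 56L)
  ref <- generate_reference(p, introns = FALSE)
  g <- ref$genes[[1]]

  none <- gene_diversity(g, call_set(), ref$sequences)
  expect_equal(none$piN, 0)
  expect_equal(none$piS, 0)
  expect_true(is.na(none$piN_piS))

  # a gene with only a synonymous SNP has ratio 0
  cds <- as.character(cds_sequence(g, ref$sequences))
  code <- Biostrings::GENETIC_CODE
  found <- NULL
  for (pos in seq_len(nchar(cds))) {
    cstart <- 3 * ((pos - 1) %/% 3) + 1
    codon <- substr(cds, cstart, cstart + 2)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(cds, pos, pos))) {
      mut <- codon
      substr(mut, pos - cstart + 1, pos - cstart + 1) <- alt
      if (code[mut] == code[codon]) { found <- list(pos = pos, alt = alt); break }
    }
    if (!is.null(found)) break
  }
  syn_call <- call_set("gene001", found$pos, ref = substr(cds, found$pos, found$pos),
                       minor = found$alt, alt = found$alt,
                       minor_count = 10L, depth = 50L)
  only_syn <- gene_diversity(g, syn_call, ref$sequences)
  expect_equal(only_syn$piN, 0)
  expect_gt(only_syn$piS, 0)
  expect_equal(only_syn$piN_piS, 0)
})

test_that("gene_diversity is invariant to the order of SNPs", {
  p <- sim_params(n_genes = 1L, gene_length_bp = 300L,
                  polymorphic_fraction = 1, snp_intensity = 8, seed = 57L)
  ref <- generate_reference(p, introns = FALSE)
  truth <- generate_pool(ref, p)
  calls <- call_set(contig = truth$contig, pos = truth$pos, ref = truth$ref,
                    minor = truth$alt, alt = truth$alt,
                    minor_count = 6L + seq_len(nrow(truth)),
                    depth = 60L + seq_len(nrow(truth)))
  suppressWarnings({
    d1 <- gene_diversity(ref$genes[[1]], calls, ref$sequences)
    perm <- calls[rev(seq_len(nrow(calls))), , drop = FALSE]
    class(perm) <- c("call_set", "data.frame")
    d2 <- gene_diversity(ref$genes[[1]], perm, ref$sequences)
  })
  expect_equal(d1[setdiff(names(d1), "gene_id")], d2[setdiff(names(d2), "gene_id")])
})

test_that("Ts/Tv counts transitions among reference-to-variant pairs", {
  mk <- function(ref, alt) {
    call_set("g", seq_along(ref), ref = ref, minor = alt, alt = alt,
             minor_count = 6L, depth = 30L)
  }
  expect_equal(as.numeric(ts_tv(mk(c("A", "C", "A"), c("G", "T", "C")))), 2)
  all_ts <- ts_tv(mk(c("A", "C"), c("G", "T")))
  expect_true(is.na(as.numeric(all_ts)))
  expect_equal(attr(all_ts, "ts"), 2L)
  empty <- ts_tv(call_set())
  expect_true(is.na(as.numeric(empty)))
})

test_that("SNP-count correlations use the closed-form Pearson formula", {
  # proportionality gives r = 1
  expect_equal(unname(snp_count_correlates(c(1, 2, 3), c(10, 20, 30),
                                           c(5, 9, 2))["r_length"]), 1)
  # constant counts: undefined
  expect_true(is.na(snp_count_correlates(c(2, 2, 2), c(10, 20, 30),
                                         c(5, 9, 2))["r_length"]))
  # small worked vector against the closed form
  x <- c(1, 2, 3); y <- c(10, 20, 15)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(snp_count_correlates(x, y, y)["r_length"]), r_manual)
  expect_error(snp_count_correlates(c(1, 2), c(1, 2), c(1, 2)), "at least 3")
})
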