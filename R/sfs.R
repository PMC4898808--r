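#' Assign a pooled frequency to a folded copy class
#'
#' Converts a pooled allele frequency to a chromosome copy class out of
#' `pool_n` (half-up rounding, clamped to `1..pool_n-1` — a called SNP is
#' segregating by definition) and folds it onto the minor-allele side:
#' `k = min(k0, pool_n - k0)`.
#'
#' @param p_hat pooled frequency, strictly between 0 and 1.
#' @param pool_n chromosomes in the pool (even).
#' @return Integer folded class in `1..pool_n/2`. Vectorized.
#' @examples
#' assign_frequency_class(0.5, 20)   # 10
#' assign_frequency_class(0.2, 20)   # 4
#' assign_frequency_class(0.55, 20)  # 9
#' @export
assign_frequency_class <- function(p_hat, pool_n = 20L) {
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("assign_frequency_class: p_hat must be strictly inside (0, 1) for a SNP")
  }
  k0 <- pmin(pmax(round_half_up(p_hat * pool_n), 1L), pool_n - 1L)
  as.integer(pmin(k0, pool_n - k0))
}

#' Build a folded site-frequency spectrum from pooled calls
#'
#' Counts SNPs per minor-allele copy class `1..pool_n/2` from their pooled
#' frequencies, with the relative (sum-to-one) spectrum attached. Per-gene
#' spectra can be computed alongside by assigning calls to the gene whose CDS
#' contains them.
#'
#' @param calls a [call_set].
#' @param pool_n chromosomes in the pool (defaults to the call set's).
#' @param per_gene also return one spectrum per gene?
#' @param genes named list of [gene_model]s (required when `per_gene`).
#' @return A list of class `folded_sfs` with `pool_n`, `counts` (named
#'   integer vector over classes `1..pool_n/2`), `relative` (`NA` when there
#'   are no SNPs) and, when requested, `per_gene` (named list of
#'   `folded_sfs`).
#' @export
build_folded_sfs <- function(calls, pool_n = attr(calls, "pool_n"),
                             per_gene = FALSE, genes = NULL) {
  half <- pool_n %/% 2L
  counts <- integer(half)
  names(counts) <- as.character(seq_len(half))
  if (nrow(calls)) {
    k <- assign_frequency_class(calls$af, pool_n)
    tab <- table(factor(k, levels = seq_len(half)))
    counts <- stats::setNames(as.integer(tab), names(counts))
  }
  rel <- if (sum(counts) > 0L) counts / sum(counts) else
    stats::setNames(rep(NA_real_, half), names(counts))
  out <- structure(list(pool_n = as.integer(pool_n), counts = counts,
                        relative = rel),
                   class = "folded_sfs")
  if (per_gene) {
    if (is.null(genes)) stop("build_folded_sfs: per_gene requires gene models")
    assign <- rep(NA_character_, nrow(calls))
    for (g in genes) {
      ci <- cds_index(g, calls$pos)
      hit <- calls$contig == g$contig & !is.na(ci) & ci >= 1L
      assign[hit & is.na(assign)] <- g$gene_id
    }
    out$per_gene <- lapply(split(seq_len(nrow(calls))[!is.na(assign)],
                                 assign[!is.na(assign)]),
                           function(ii) build_folded_sfs(calls[ii, , drop = FALSE],
                                                         pool_n = pool_n))
  }
  out
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("<folded_sfs> pool of %d chromosomes, %d SNPs\n",
              x$pool_n, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Compare two folded spectra
#'
#' Pearson correlation of the relative spectra over classes `1..pool_n/2` —
#' the congruence measure for spectra derived from different estimation
#' routes.
#'
#' @param a,b two `folded_sfs` with the same `pool_n`.
#' @return Correlation coefficient, or `NA` when either spectrum is degenerate
#'   (zero variance or no SNPs).
#' @export
compare_sfs <- function(a, b) {
  if (a$pool_n != b$pool_n) stop("compare_sfs: spectra have different pool_n")
  ra <- a$relative; rb <- b$relative
  if (anyNA(ra) || anyNA(rb)) return(NA_real_)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  stats::cor(ra, rb)
}
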