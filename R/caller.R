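#' Caller thresholds for pooled SNP detection
#'
#' The detection rule for pooled data: a site is called polymorphic when its
#' depth reaches `min_cov` and the second-most-frequent base is seen at least
#' `min_count` times. With the defaults (depth 30, count 6, 20 chromosomes)
#' minor alleles at frequency 4/20 are still detectable in expectation, while
#' singletons require depth near 120. Sites within `indel_window` bp of indel
#' evidence and sites above the per-contig `max_cov_quantile` depth quantile
#' (a PCR-bias guard) are masked before calling.
#'
#' @param min_cov minimum depth.
#' @param min_count minimum minor-allele read count.
#' @param pool_n chromosomes in the pool (even).
#' @param indel_window bp radius around indel evidence to exclude.
#' @param max_cov_quantile per-contig depth quantile above which sites are
#'   excluded.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_cov = 30L, min_count = 6L, pool_n = 20L,
                          indel_window = 5L, max_cov_quantile = 0.98) {
  if (min_cov < 1L) stop("min_cov must be >= 1")
  if (max_cov_quantile <= 0 || max_cov_quantile > 1) {
    stop("max_cov_quantile must be in (0, 1]")
  }
  if (pool_n %% 2L != 0L) stop("pool_n must be even")
  structure(list(min_cov = as.integer(min_cov), min_count = as.integer(min_count),
                 pool_n = as.integer(pool_n), indel_window = as.integer(indel_window),
                 max_cov_quantile = max_cov_quantile),
            class = "caller_params")
}

# vectorized core: classify every site, returning reason + call fields.
# masked_reason: NA or a masking reason per site, applied before thresholds.
classify_sites <- function(sites, params, masked_reason = NULL) {
  cm <- as.matrix(sites[, c("A", "C", "G", "T")])
  ns <- nrow(cm)
  bases <- c("A", "C", "G", "T")
  # ranks 1..3 by count, ties broken alphabetically (stable)
  idx <- seq_len(ns)
  tmp <- cm
  top_i <- max.col(tmp, ties.method = "first"); tmp[cbind(idx, top_i)] <- -1L
  sec_i <- max.col(tmp, ties.method = "first"); tmp[cbind(idx, sec_i)] <- -1L
  thr_i <- max.col(tmp, ties.method = "first")
  # tie between top two counts: prefer the reference base as major so the
  # minor allele is the non-reference one
  ri <- match(sites$ref, bases)
  tie <- !is.na(ri) & cm[cbind(seq_len(ns), sec_i)] == cm[cbind(seq_len(ns), top_i)] &
    sec_i == ri
  if (any(tie)) {
    tmp <- top_i[tie]; top_i[tie] <- sec_i[tie]; sec_i[tie] <- tmp
  }
  top_n <- cm[cbind(seq_len(ns), top_i)]
  sec_n <- cm[cbind(seq_len(ns), sec_i)]
  thr_n <- cm[cbind(seq_len(ns), thr_i)]
  reason <- rep("call", ns)
  reason[sec_n < params$min_count] <- "low_count"
  reason[sec_n == 0L] <- "monomorphic"
  reason[thr_n >= params$min_count] <- "multiallelic"
  reason[sites$depth < params$min_cov] <- "low_coverage"
  if (!is.null(masked_reason)) reason[!is.na(masked_reason)] <- masked_reason[!is.na(masked_reason)]
  major <- bases[top_i]
  minor <- bases[sec_i]
  alt <- ifelse(minor != sites$ref, minor,
                ifelse(major != sites$ref, major, minor))
  list(reason = reason, major = major, minor = minor, alt = alt,
       minor_count = sec_n)
}

#' Call a single pooled site
#'
#' Applies the detection rule of [caller_params] to one [site_counts] row.
#' A call is emitted iff `depth >= min_cov` and the second-most-frequent base
#' count reaches `min_count`; a third base also reaching `min_count` makes
#' the site multiallelic (not called, but preserved for inspection). The
#' masking rules (indel proximity, excess coverage) operate at the pileup
#' level — see [call_pileup()].
#'
#' @param site a single-row [site_counts].
#' @param params a [caller_params].
#' @return A one-row [call_set] on success; otherwise `NULL` with the no-call
#'   reason in attribute `reason` (`low_coverage`, `low_count`,
#'   `multiallelic`, `monomorphic`).
#' @examples
#' s <- site_counts("g1", 100, "A", A = 24, C = 6)
#' call_site(s, caller_params())  # called: af 0.2, copy class 4/20
#' @export
call_site <- function(site, params = caller_params()) {
  stopifnot(nrow(site) == 1L)
  cl <- classify_sites(site, params)
  if (cl$reason != "call") {
    return(structure(list(reason = cl$reason), class = "no_call"))
  }
  call_set(contig = site$contig, pos = site$pos, ref = site$ref,
           minor = cl$minor, alt = cl$alt, minor_count = cl$minor_count,
           depth = site$depth, pool_n = params$pool_n)
}

#' Call SNPs across a pileup
#'
#' Applies the full pooled detection procedure: first computes the per-contig
#' excess-coverage mask (depth above the `max_cov_quantile` empirical
#' quantile, a PCR-bias guard) and the indel-proximity mask (within
#' `indel_window` bp of any site with indel evidence), then applies the
#' [call_site()] thresholds to every unmasked site. Deterministic; input must
#' be sorted by contig then position.
#'
#' @param sites a [site_counts], sorted by contig and position.
#' @param params a [caller_params].
#' @return A list with `calls` (a [call_set], sorted) and `log` (a
#'   `data.frame` with `contig`, `pos` and the per-site `reason` code:
#'   `call`, `low_coverage`, `low_count`, `monomorphic`, `multiallelic`,
#'   `indel_proximal`, `excess_coverage`).
#' @export
call_pileup <- function(sites, params = caller_params()) {
  if (nrow(sites) > 1L) {
    o <- order(sites$contig, sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      stop("call_pileup: input must be sorted by contig, pos")
    }
  }
  masked <- rep(NA_character_, nrow(sites))
  for (idx in split(seq_len(nrow(sites)), sites$contig)) {
    qd <- stats::quantile(sites$depth[idx], params$max_cov_quantile,
                          names = FALSE, type = 7)
    masked[idx[sites$depth[idx] > qd]] <- "excess_coverage"
    ipos <- sites$pos[idx][sites$indel[idx] > 0L]
    if (length(ipos)) {
      near <- vapply(sites$pos[idx],
                     function(p) any(abs(p - ipos) <= params$indel_window),
                     logical(1))
      masked[idx[near]] <- "indel_proximal"
    }
  }
  cl <- classify_sites(sites, params, masked_reason = masked)
  keep <- cl$reason == "call"
  calls <- call_set(contig = sites$contig[keep], pos = sites$pos[keep],
                    ref = sites$ref[keep], minor = cl$minor[keep],
                    alt = cl$alt[keep], minor_count = cl$minor_count[keep],
                    depth = sites$depth[keep], pool_n = params$pool_n)
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  list(calls = calls,
       log = data.frame(contig = sites$contig, pos = sites$pos,
                        reason = cl$reason, stringsAsFactors = FALSE))
}

#' Smallest detectable minor-allele copy class
#'
#' The smallest copy number `k` out of `pool_n` chromosomes whose expected
#' read count at the given depth reaches `min_count`:
#' `ceil(min_count * pool_n / depth)`. At depth 30 with count 6 and 20
#' chromosomes this is 4/20; singletons (1/20) require depth 120.
#'
#' @param depth read depth (`>= 1`).
#' @param params a [caller_params].
#' @return Integer copy class, capped at `pool_n / 2`; attribute `infeasible`
#'   is `TRUE` when even the maximal folded class `pool_n / 2` falls short of
#'   `min_count` in expectation.
#' @export
detectability_threshold <- function(depth, params = caller_params()) {
  if (any(depth < 1)) stop("detectability_threshold: depth must be >= 1")
  k <- as.integer(ceiling(params$min_count * params$pool_n / depth))
  half <- params$pool_n %/% 2L
  infeasible <- k > half
  k <- pmin(k, half)
  attr(k, "infeasible") <- infeasible
  k
}

#' Remove fixed differences to the reference
#'
#' A variant caller run against a reference genome reports sites where the
#' sample differs from the reference even when the sample itself is
#' monomorphic there. For within-population analysis such fixed differences
#' are not SNPs: this filter drops every call whose pooled counts show a
#' single effective allele (second-most-frequent base count below
#' `min_count`) differing from the reference base.
#'
#' @param calls a [call_set] (e.g. imported from an external caller).
#' @param sites the [site_counts] covering every call position.
#' @param params a [caller_params] (supplies `min_count`).
#' @return The filtered [call_set].
#' @export
filter_fixed_differences <- function(calls, sites, params = caller_params()) {
  if (nrow(calls) == 0L) return(calls)
  idx <- match(paste(calls$contig, calls$pos), paste(sites$contig, sites$pos))
  if (anyNA(idx)) {
    stop(sprintf("filter_fixed_differences: no site counts for %s:%d",
                 calls$contig[which(is.na(idx))[1L]],
                 calls$pos[which(is.na(idx))[1L]]))
  }
  cm <- as.matrix(sites[idx, c("A", "C", "G", "T"), drop = FALSE])
  bases <- c("A", "C", "G", "T")
  drop <- logical(nrow(calls))
  for (j in seq_len(nrow(calls))) {
    cnt <- sort(cm[j, ], decreasing = TRUE)
    top_base <- bases[which.max(cm[j, ])]
    drop[j] <- cnt[2L] < params$min_count && top_base != calls$ref[j]
  }
  out <- calls[!drop, , drop = FALSE]
  attr(out, "pool_n") <- attr(calls, "pool_n")
  out
}

#' Intersect two call sets
#'
#' Multi-caller consensus: calls present in both sets (matched on contig,
#' position and minor allele by default, or position only) form the
#' high-confidence set; the two difference sets are returned alongside. The
#' three outputs partition the union. `both` carries the first argument's
#' frequency estimates.
#'
#' @param a,b two [call_set]s.
#' @param match `"pos_allele"` (default) or `"pos"`.
#' @return A list with `both`, `only_a`, `only_b` (all [call_set]s).
#' @export
intersect_callsets <- function(a, b, match = c("pos_allele", "pos")) {
  match <- match.arg(match)
  wa <- match == "pos_allele"
  ka <- callset_key(a, wa); kb <- callset_key(b, wa)
  both <- a[ka %in% kb, , drop = FALSE]
  only_a <- a[!(ka %in% kb), , drop = FALSE]
  only_b <- b[!(kb %in% ka), , drop = FALSE]
  attr(both, "pool_n") <- attr(a, "pool_n")
  attr(only_a, "pool_n") <- attr(a, "pool_n")
  attr(only_b, "pool_n") <- attr(b, "pool_n")
  list(both = both, only_a = only_a, only_b = only_b)
}

#' Score calls against a truth set
#'
#' Restricted to a set of validated intervals (the analogue of the
#' Sanger-sequenced regions), counts calls matching a truth site (position
#' plus variant allele), spurious calls and missed truth sites, and reports
#' `fp_rate = fp / (tp + fp)` and `fn_rate = fn / (tp + fn)`. Truth copy
#' numbers above `pool_n / 2` are matched through the call's variant allele,
#' so a majority alternative allele still validates its call.
#'
#' @param calls a [call_set].
#' @param truth a `pool_truth` (columns `contig`, `pos`, `alt`).
#' @param region `data.frame(contig, start, end)` of validated intervals,
#'   1-based inclusive; must be non-empty.
#' @param match_allele require the variant allele to match (default) or
#'   position only.
#' @return A list of class `validation_report`: `tp`, `fp`, `fn`, `fp_rate`,
#'   `fn_rate` (a rate is `NA` with `*_defined = FALSE` when its denominator
#'   is zero) and `region_restricted = TRUE`.
#' @export
validate_against_truth <- function(calls, truth, region, match_allele = TRUE) {
  if (is.null(region) || nrow(region) == 0L) {
    stop("validate_against_truth: region must be a non-empty set of intervals")
  }
  in_region <- function(contig, pos) {
    hit <- logical(length(pos))
    for (r in seq_len(nrow(region))) {
      hit <- hit | (contig == region$contig[r] &
                      pos >= region$start[r] & pos <= region$end[r])
    }
    hit
  }
  calls_r <- calls[in_region(calls$contig, calls$pos), , drop = FALSE]
  truth_r <- truth[in_region(truth$contig, truth$pos), , drop = FALSE]
  kc <- if (match_allele) paste(calls_r$contig, calls_r$pos, calls_r$alt) else
    paste(calls_r$contig, calls_r$pos)
  kt <- if (match_allele) paste(truth_r$contig, truth_r$pos, truth_r$alt) else
    paste(truth_r$contig, truth_r$pos)
  tp <- sum(kc %in% kt)
  fp <- sum(!(kc %in% kt))
  fn <- sum(!(kt %in% kc))
  fp_rate <- if (tp + fp > 0L) fp / (tp + fp) else NA_real_
  fn_rate <- if (tp + fn > 0L) fn / (tp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 fp_defined = tp + fp > 0L, fn_defined = tp + fn > 0L,
                 region_restricted = TRUE),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> tp=%d fp=%d fn=%d  fp_rate=%s fn_rate=%s\n",
              x$tp, x$fp, x$fn,
              if (x$fp_defined) sprintf("%.3f", x$fp_rate) else "undefined",
              if (x$fn_defined) sprintf("%.3f", x$fn_rate) else "undefined"))
  invisible(x)
}
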