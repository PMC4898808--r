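test_that("call_site applies the depth and minor-count thresholds", {
  p <- caller_params()

  # minor allele at 4/20 detectable at depth 30 with count 6
  call <- call_site(site_counts("g1", 100, "A", A = 24, C = 6), p)
  expect_s3_class(call, "call_set")
  expect_equal(call$minor, "C")
  expect_equal(call$af, 0.2)
  expect_equal(call$k, 4L)

  nc <- call_site(site_counts("g1", 100, "A", A = 23, C = 6), p)
  expect_s3_class(nc, "no_call")
  expect_equal(nc$reason, "low_coverage")

  nc <- call_site(site_counts("g1", 100, "A", A = 295, C = 5), p)
  expect_equal(nc$reason, "low_count")

  sym <- call_site(site_counts("g1", 100, "A", A = 20, C = 20), p)
  expect_equal(sym$af, 0.5)
  expect_equal(sym$k, 10L)
  expect_equal(sym$minor, "C")  # reference base kept as major on ties

  nc <- call_site(site_counts("g1", 100, "A", A = 40), p)
  expect_equal(nc$reason, "monomorphic")

  nc <- call_site(site_counts("g1", 100, "A", A = 20, C = 10, G = 8), p)
  expect_equal(nc$reason, "multiallelic")
})

test_that("caller agrees with a brute-force oracle on all two-allele vectors to depth 60", {
  p <- caller_params()
  # independent restatement of the rules: called iff depth >= 30 and the
  # smaller of the two allele counts >= 6
  for (a in 0:60) {
    for (b in 0:(60 - a)) {
      oracle_called <- (a + b) >= 30 && min(a, b) >= 6 && min(a, b) > 0
      got <- call_site(site_counts("c", 1, "A", A = a, C = b), p)
      if (oracle_called) {
        expect_s3_class(got, "call_set")
        expect_equal(got$minor_count, min(a, b))
        expect_equal(got$af, min(a, b) / (a + b))
      } else {
        expect_s3_class(got, "no_call")
      }
    }
  }
})

test_that("raising any threshold never increases the number of calls", {
  set.seed(31)
  params <- sim_params(n_genes = 4L, gene_length_bp = 300L,
                       polymorphic_fraction = 0.9, snp_intensity = 8,
                       mean_coverage = 60, seed = 31L)
  ref <- generate_reference(params, introns = FALSE)
  truth <- generate_pool(ref, params)
  pu <- generate_pileup(ref, truth, params)
  n0 <- nrow(call_pileup(pu, caller_params(min_cov = 30, min_count = 4))$calls)
  for (pp in list(caller_params(min_cov = 40, min_count = 4),
                  caller_params(min_cov = 30, min_count = 6),
                  caller_params(min_cov = 30, min_count = 4, max_cov_quantile = 0.9))) {
    expect_lte(nrow(call_pileup(pu, pp)$calls), n0)
  }
})

test_that("indel-proximity masking excludes sites within the window only", {
  p <- caller_params(indel_window = 5L)
  mk <- function(pos, indel = 0L) {
    site_counts("g1", pos, "A", A = 24, C = 6, indel = indel)
  }
  base <- rbind(mk(100, indel = 1L), mk(103), mk(106), mk(90))
  class(base) <- c("site_counts", "data.frame")
  base <- base[order(base$pos), ]
  res <- call_pileup(base, p)
  lg <- res$log
  expect_equal(lg$reason[lg$pos == 103], "indel_proximal")  # 3 bp away
  expect_equal(lg$reason[lg$pos == 106], "call")            # 6 bp away
  expect_equal(lg$reason[lg$pos == 90], "call")
})

test_that("excess-coverage masking uses the per-contig quantile", {
  rows <- lapply(1:100, function(i) {
    site_counts("g1", i, "A", A = if (i == 50) 5000L else 24L,
                C = if (i == 50) 1000L else 6L)
  })
  sites <- do.call(rbind, rows)
  class(sites) <- c("site_counts", "data.frame")
  res <- call_pileup(sites, caller_params(max_cov_quantile = 0.98))
  expect_equal(res$log$reason[res$log$pos == 50], "excess_coverage")
  expect_equal(sum(res$log$reason == "excess_coverage"), 1L)
})

test_that("call_pileup rejects unsorted input", {
  s <- rbind(site_counts("g1", 5, "A", A = 30, C = 6),
             site_counts("g1", 2, "A", A = 30, C = 6))
  class(s) <- c("site_counts", "data.frame")
  expect_error(call_pileup(s), "sorted")
})

test_that("detectability threshold follows ceil(min_count * pool_n / depth)", {
  expect_equal(as.integer(detectability_threshold(30)), 4L)
  expect_equal(as.integer(detectability_threshold(120)), 1L)  # singleton at deep coverage
  expect_equal(as.integer(detectability_threshold(20)), 6L)
  low <- detectability_threshold(10)  # even 10/20 cannot reach 6 reads in expectation
  expect_equal(as.integer(low), 10L)
  expect_true(attr(low, "infeasible"))
  expect_false(attr(detectability_threshold(30), "infeasible"))
})

test_that("fixed differences to the reference are filtered, polymorphic sites kept", {
  sites <- rbind(site_counts("g1", 10, "A", T = 30),
                 site_counts("g1", 20, "A", T = 24, A = 6))
  class(sites) <- c("site_counts", "data.frame")
  calls <- call_set(contig = c("g1", "g1"), pos = c(10L, 20L),
                    ref = c("A", "A"), minor = c("A", "A"), alt = c("T", "T"),
                    minor_count = c(0L, 6L), depth = c(30L, 30L))
  out <- filter_fixed_differences(calls, sites)
  expect_equal(out$pos, 20L)

  expect_equal(nrow(filter_fixed_differences(call_set(), sites)), 0L)
  orphan <- call_set(contig = "g1", pos = 99L, ref = "A", minor = "C",
                     alt = "C", minor_count = 6L, depth = 30L)
  expect_error(filter_fixed_differences(orphan, sites), "no site counts")
})

test_that("call-set intersection partitions the union", {
  mk <- function(pos, minor) {
    call_set(contig = "g1", pos = pos, ref = "A", minor = minor, alt = minor,
             minor_count = 6L + pos %% 3L, depth = 30L + pos)
  }
  a <- rbind(mk(1L, "C"), mk(2L, "G"))
  b <- rbind(mk(2L, "G"), mk(3L, "T"))
  class(a) <- class(b) <- c("call_set", "data.frame")
  res <- intersect_callsets(a, b)
  expect_equal(res$both$pos, 2L)
  expect_equal(res$only_a$pos, 1L)
  expect_equal(res$only_b$pos, 3L)
  # both carries a's estimates
  expect_equal(res$both$depth, 32L)

  # same position, different minor allele: not a shared call
  res2 <- intersect_callsets(mk(5L, "C"), mk(5L, "G"))
  expect_equal(nrow(res2$both), 0L)
  expect_equal(nrow(res2$only_a), 1L)
  expect_equal(nrow(res2$only_b), 1L)
  # but matched when keyed on position only
  res3 <- intersect_callsets(mk(5L, "C"), mk(5L, "G"), match = "pos")
  expect_equal(nrow(res3$both), 1L)

  # identity
  res4 <- intersect_callsets(a, a)
  expect_equal(nrow(res4$both), nrow(a))
  expect_equal(nrow(res4$only_a), 0L)
  expect_equal(nrow(res4$only_b), 0L)

  # property: the three outputs partition the union, |both| <= min(|a|, |b|)
  set.seed(77)
  for (i in 1:10) {
    pa <- sample(1:30, 12); pb <- sample(1:30, 12)
    aa <- do.call(rbind, lapply(pa, mk, minor = "C"))
    bb <- do.call(rbind, lapply(pb, mk, minor = "C"))
    class(aa) <- class(bb) <- c("call_set", "data.frame")
    r <- intersect_callsets(aa, bb)
    expect_equal(nrow(r$both) + nrow(r$only_a) + nrow(r$only_b),
                 length(union(pa, pb)))
    expect_lte(nrow(r$both), min(nrow(aa), nrow(bb)))
  }
})

test_that("validation against truth counts tp/fp/fn under the stated denominators", {
  region <- data.frame(contig = "g1", start = 1L, end = 1000L)
  mkc <- function(pos, alt = "C") {
    call_set(contig = "g1", pos = pos, ref = "A", minor = alt, alt = alt,
             minor_count = 6L, depth = 30L)
  }
  truth <- manual_truth("g1", 1:25, ref = "A", alt = "C", k = 4L)

  # perfect recovery
  calls <- do.call(rbind, lapply(1:25, mkc))
  class(calls) <- c("call_set", "data.frame")
  rep0 <- validate_against_truth(calls, truth, region)
  expect_equal(rep0$fp_rate, 0)
  expect_equal(rep0$fn_rate, 0)

  # 24 of 25 recovered plus one spurious call
  calls <- do.call(rbind, lapply(c(1:24, 500L), mkc))
  class(calls) <- c("call_set", "data.frame")
  rep1 <- validate_against_truth(calls, truth, region)
  expect_equal(rep1$tp, 24L)
  expect_equal(rep1$fp, 1L)
  expect_equal(rep1$fn, 1L)
  expect_equal(rep1$fp_rate, 1 / 25)
  expect_equal(rep1$fn_rate, 1 / 25)

  # no calls at all: fn_rate 1, fp_rate undefined
  rep2 <- validate_against_truth(call_set(), truth, region)
  expect_equal(rep2$fn_rate, 1)
  expect_false(rep2$fp_defined)
  expect_true(is.na(rep2$fp_rate))

  # allele must match by default
  wrong <- mkc(1L, alt = "G")
  rep3 <- validate_against_truth(wrong, truth[1, , drop = FALSE], region)
  expect_equal(rep3$tp, 0L)
  expect_equal(rep3$fp, 1L)

  expect_error(validate_against_truth(calls, truth, region[0, ]), "non-empty")
})
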