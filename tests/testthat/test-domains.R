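test_that("stitch joins peaks within the stitching window", {
  peaks <- gr0("c1", c(0, 10000), c(500, 10500))
  one <- stitch(peaks, stitch_gap = 12500)
  expect_length(one, 1L)
  expect_equal(c(start(one) - 1L, end(one)), c(0L, 10500L))
  expect_length(stitch(peaks, stitch_gap = 5000), 2L)
  single <- stitch(gr0("c1", 100, 600), stitch_gap = 12500)
  expect_equal(width(single), 500L)
})

test_that("stitch can exclude promoter-proximal peaks", {
  peaks <- gr0("c1", c(0, 50000), c(500, 50400))
  tss <- gr0("c1", 50100, 50101)
  out <- stitch(peaks, stitch_gap = 1000, tss = tss, tss_flank = 2500)
  expect_length(out, 1L)
  expect_equal(start(out) - 1L, 0L)
  expect_warning(stitch(gr0("c1", 50000, 50400), stitch_gap = 1000,
                        tss = tss, tss_flank = 2500), "TSS")
})

test_that("score_regions subtracts input and clips at zero", {
  regions <- gr0("c1", 0, 100)
  treat <- gr0("c1", 0, 100, score = 1)
  ctrl <- gr0("c1", 0, 100, score = 0.3)
  expect_equal(mcols(score_regions(regions, treat, ctrl))$score, 70)
  big_ctrl <- gr0("c1", 0, 100, score = 5)
  expect_equal(mcols(score_regions(regions, treat, big_ctrl))$score, 0)
  expect_equal(mcols(score_regions(regions, treat))$score, 100)
})

test_that("tangent_cutoff finds the first slope-1 crossing of the scaled curve", {
  res <- tangent_cutoff(c(1, 2, 3, 4, 100))
  expect_equal(res$cutoff_score, 4)
  expect_equal(res$cutoff_rank, 4L)
  expect_warning(res_flat <- tangent_cutoff(rep(3, 10)), "slope")
  expect_equal(res_flat$cutoff_score, 3)
  expect_equal(sum(rep(3, 10) > res_flat$cutoff_score), 0L)
  expect_error(tangent_cutoff(5), "at least 2")
  expect_error(tangent_cutoff(c(3, 1)), "ascending")
})

test_that("tangent_cutoff matches the independent rank-scan oracle", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(10:5000, 1)
    scores <- sort(rexp(n, rate = 1 / 10^runif(1, 0, 3)))
    res <- suppressWarnings(tangent_cutoff(scores))
    ora <- oracle_tangent(scores)
    expect_identical(res$cutoff_rank, ora$cutoff_rank)
    expect_identical(res$cutoff_score, ora$cutoff_score)
    ## invariant under positive rescaling
    res2 <- suppressWarnings(tangent_cutoff(scores * 37.5))
    expect_identical(res2$cutoff_rank, res$cutoff_rank)
  }
})

test_that("call_super_enhancers recovers planted high-signal clusters exactly", {
  set.seed(5)
  ## 500 typical enhancers plus 10 planted clusters at >= 20x signal
  typ_start <- seq(0, by = 40000, length.out = 500)
  planted_start <- seq(500 * 40000, by = 60000, length.out = 10)
  peaks <- c(gr0("c1", typ_start, typ_start + 1000),
             gr0("c1", planted_start, planted_start + 15000))
  track <- c(gr0("c1", typ_start, typ_start + 1000,
                 score = runif(500, 0.5, 1.5)),
             gr0("c1", planted_start, planted_start + 15000,
                 score = runif(10, 20, 30)))
  rrs <- call_super_enhancers(peaks, track, stitch_gap = 12500)
  sup <- rrs$regions[mcols(rrs$regions)$is_super]
  expect_length(sup, 10L)
  expect_true(all(start(sup) - 1L == sort(planted_start)))
  ## partition and monotonicity: no typical region outscores a super region
  sc <- mcols(rrs$regions)$score
  is_sup <- mcols(rrs$regions)$is_super
  expect_equal(sum(is_sup) + sum(!is_sup), length(rrs$regions))
  expect_true(min(sc[is_sup]) >= max(sc[!is_sup]))
  expect_true(all(sc[is_sup] > rrs$cutoff_score))
})

test_that("call_super_enhancers handles an empty peak set", {
  expect_warning(rrs <- call_super_enhancers(GRanges(), GRanges()), "empty")
  expect_length(rrs$regions, 0L)
})

test_that("call_broad_domains keeps ceil(top_fraction * n) widest peaks", {
  ## widths 1..40 kb: ceil(0.05 * 40) = 2 -> widths 40 and 39 kb
  w <- (1:40) * 1000
  peaks <- gr0("c1", seq(0, by = 100000, length.out = 40),
               seq(0, by = 100000, length.out = 40) + w)
  bd <- call_broad_domains(peaks, 0.05)
  expect_length(bd$domains, 2L)
  expect_setequal(width(bd$domains), c(40000L, 39000L))
  expect_equal(bd$width_threshold, 39000L)

  ## ties resolved by (chrom, start) ascending
  same <- gr0("c1", seq(0, by = 5000, length.out = 100),
              seq(0, by = 5000, length.out = 100) + 2000)
  bd2 <- call_broad_domains(same, 0.05)
  expect_length(bd2$domains, 5L)
  expect_equal(start(bd2$domains) - 1L, seq(0, by = 5000, length.out = 5))

  ## n * f < 1 keeps one peak with a warning
  expect_warning(bd3 <- call_broad_domains(same[1:10], 0.05), "single")
  expect_length(bd3$domains, 1L)
})

test_that("broad-domain count law holds over random (n, f) cases", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(1:400, 1)
    f <- runif(1, 0.01, 0.99)
    starts <- seq(0, by = 10000, length.out = n)
    peaks <- gr0("c1", starts, starts + sample(500:5000, n, replace = TRUE))
    bd <- suppressWarnings(call_broad_domains(peaks, f))
    expect_length(bd$domains, as.integer(ceiling(f * n)))
    expect_true(all(width(bd$domains) >= bd$width_threshold))
  }
})
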