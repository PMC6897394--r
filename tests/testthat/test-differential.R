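make_rc <- function(t_counts, c_counts, regions = NULL) {
  n <- length(t_counts)
  if (is.null(regions)) {
    regions <- gr0("c1", seq(0, by = 2000, length.out = n),
                   seq(0, by = 2000, length.out = n) + 1000)
  }
  counts <- cbind(treated_1 = t_counts, control_1 = c_counts)
  samples <- list(treated_1 = NULL, control_1 = NULL)
  structure(list(regions = regions, counts = counts,
                 condition = c(treated_1 = "treated", control_1 = "control"),
                 library_size = colSums(counts)),
            class = "RegionCounts")
}

test_that("count_in_regions assigns fragments by midpoint, half-open", {
  regions <- gr0("c1", 0, 100)
  frags <- gr0("c1", c(10, 40, 80, 90, 190), c(30, 60, 100, 110, 210))
  ## midpoints (0-based): 20, 50, 90, 100, 200 -> 100 is at the region end
  rc <- count_in_regions(regions, list(t = frags, c = frags[1]),
                         c(t = "treated", c = "control"))
  expect_equal(unname(rc$counts[1, "t"]), 3L)
  expect_equal(unname(rc$library_size["t"]), 3)
})

test_that("count_in_regions matches a per-fragment brute-force oracle", {
  set.seed(29)
  regions <- GenomicRanges::reduce(random_intervals(20))
  frags <- random_intervals(200)
  rc <- count_in_regions(regions, list(t = frags, c = frags),
                         c(t = "treated", c = "control"))
  mid0 <- (start(frags) - 1L + end(frags)) %/% 2L
  manual <- vapply(seq_along(regions), function(i) {
    sum(as.character(seqnames(frags)) == as.character(seqnames(regions))[i] &
          mid0 >= start(regions)[i] - 1L & mid0 < end(regions)[i])
  }, numeric(1))
  expect_equal(unname(rc$counts[, "t"]), as.integer(manual))
})

test_that("count_in_regions uses rounded signal area for tracks", {
  regions <- gr0("c1", 0, 100)
  track <- gr0("c1", 0, 50, score = 0.5)
  rc <- count_in_regions(regions, list(t = track, c = gr0("c1", 0, 10, score = 1)),
                         c(t = "treated", c = "control"))
  expect_equal(unname(rc$counts[1, "t"]), 25L)
})

test_that("differential_regions reproduces the exact binomial worked example", {
  ## single changed region among stable ones so library sizes stay balanced;
  ## the expected p for (t=100, c=50) at p0 = 0.5 is frozen from the
  ## independent tail-sum oracle
  t_counts <- c(100L, rep(75L, 10))
  c_counts <- c(50L, rep(80L, 10))
  stopifnot(sum(t_counts) == sum(c_counts))
  res <- differential_regions(make_rc(t_counts, c_counts),
                              normalization = "library-size")
  expect_equal(res$p_value[1], 5.447533e-05, tolerance = 1e-6)
  expect_equal(res$p_value[1], oracle_binom_two_sided(100, 150, 0.5),
               tolerance = 1e-12)
  expect_equal(res$direction[1], factor("increased",
               levels = c("increased", "decreased", "unchanged")))
  expect_equal(res$log2fc[1], log2(101 / 51), tolerance = 1e-12)
})

test_that("differential_regions handles symmetric and degenerate regions", {
  res <- differential_regions(make_rc(c(40L, 0L), c(40L, 0L)),
                              normalization = "library-size")
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$direction == "unchanged"))
  ## single-region input: fdr equals p
  one <- differential_regions(make_rc(30L, 10L), normalization = "library-size")
  expect_equal(one$fdr, one$p_value)
})

test_that("swapping condition labels negates log2fc and preserves p-values", {
  set.seed(41)
  t_counts <- rpois(300, 30)
  c_counts <- rpois(300, 25)
  rc <- make_rc(t_counts, c_counts)
  rc_swapped <- make_rc(c_counts, t_counts)
  for (norm in c("median-ratio", "library-size")) {
    a <- differential_regions(rc, normalization = norm)
    b <- differential_regions(rc_swapped, normalization = norm)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
    expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-9)
  }
})

test_that("null simulation stays within BH control and planted effects are found", {
  null_sim <- simulate_treatment(frac_increased = 0, frac_decreased = 0,
                                 seed = 101)
  res0 <- differential_regions(null_sim$rc)
  expect_lte(mean(res0$direction != "unchanged"), 0.12)

  sim <- simulate_treatment(seed = 102)
  res <- differential_regions(sim$rc)
  sig <- res$direction != "unchanged"
  expect_gte(mean(sig[sim$truth != "null"]), 0.9)
  expect_lte(sum(sig & sim$truth == "null") / max(1, sum(sig)), 0.15)
  ## directions match the planted sign
  inc <- sim$truth == "increased" & sig
  expect_true(all(res$direction[inc] == "increased"))
})

test_that("annotate_location applies promoter > intragenic > distal precedence", {
  gm <- gene_model(data.frame(
    gene_id = c("g1", "g2"), chrom = "c1", strand = c("+", "-"),
    start = c(10000, 50000), end = c(20000, 60000)))
  regions <- gr0("c1", c(9500, 15000, 500000, 59000),
                 c(10500, 16000, 501000, 61000))
  lab <- annotate_location(regions, gm)
  ## region 1 spans g1's TSS; region 4 spans g2's (minus-strand) TSS
  expect_equal(as.character(lab),
               c("promoter", "intragenic", "distal intergenic", "promoter"))
  expect_equal(sum(table(lab)), length(regions))
})

test_that("assign_genes links TSSs within the window with exact distances", {
  gm <- gene_model(data.frame(
    gene_id = c("near", "far", "inside"), chrom = "c1", strand = "+",
    start = c(60000, 160000, 5000), end = c(70000, 170000, 6000)))
  region <- gr0("c1", 0, 10000)
  links <- assign_genes(region, gm, window = 100000)
  expect_setequal(links$gene_id, c("near", "inside"))
  expect_equal(links$distance[links$gene_id == "near"], 50000L)
  expect_equal(links$distance[links$gene_id == "inside"], 0L)
})

test_that("expression_change_by_category runs Welch tests with degenerate guards", {
  same <- list(a = paste0("g", 1:10), b = paste0("g", 1:10))
  expr <- setNames(rep(2, 10), paste0("g", 1:10))
  res <- expression_change_by_category(same, expr)
  expect_equal(res$tests$t, 0)
  expect_equal(res$tests$p_value, 1)

  set.seed(59)
  genes <- paste0("g", 1:100)
  expr2 <- setNames(c(rnorm(50, 1, 0.1), rnorm(50, 0, 0.1)), genes)
  cats <- list(up = genes[1:50], null = genes[51:100])
  res2 <- expression_change_by_category(cats, expr2)
  expect_lt(res2$tests$p_value, 1e-10)
  ## agrees with the closed-form Welch computation
  x <- expr2[1:50]; y <- expr2[51:100]
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 50 + var(y) / 50)
  expect_equal(res2$tests$t, unname(tw), tolerance = 1e-9)

  expect_warning(
    res3 <- expression_change_by_category(c(cats, list(tiny = genes[1])), expr2),
    "tiny")
  expect_equal(sort(names(res3$values)), c("null", "up"))
})

test_that("Welch p-values are uniform under the null", {
  set.seed(61)
  pvals <- replicate(500, {
    x <- rnorm(30); y <- rnorm(30)
    expression_change_by_category(
      list(a = paste0("a", 1:30), b = paste0("b", 1:30)),
      setNames(c(x, y), c(paste0("a", 1:30), paste0("b", 1:30))))$tests$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
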