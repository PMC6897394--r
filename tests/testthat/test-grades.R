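panel_of <- function(sets, groups) sample_panel(sets, groups)

test_that("sample_panel validates its inputs", {
  g <- gr0("c1", 0, 100)
  expect_error(sample_panel(list(), c()), "empty")
  expect_error(sample_panel(list(a = g), c(a = "High")), "per group")
  expect_error(sample_panel(list(a = g, b = g), c(a = "Hi", b = "Low")), "High")
})

test_that("build_membership forms union regions with per-sample occupancy", {
  g <- gr0("c1", 100, 500)
  pan <- panel_of(list(s1 = g, s2 = g), c(s1 = "High", s2 = "Low"))
  mm <- build_membership(pan)
  expect_length(mm$union_regions, 1L)
  expect_equal(unname(mm$occupancy[1, ]), c(1L, 1L))

  pan2 <- panel_of(list(s1 = gr0("c1", 0, 100), s2 = gr0("c1", 5000, 5100)),
                   c(s1 = "High", s2 = "Low"))
  mm2 <- build_membership(pan2)
  expect_length(mm2$union_regions, 2L)
  expect_equal(unname(rowSums(mm2$occupancy)), c(1, 1))
})

test_that("build_membership matches a brute-force overlap oracle", {
  set.seed(17)
  groups <- c(a = "High", b = "High", c = "Low", d = "Low", e = "Low")
  for (rep in 1:25) {
    sets <- lapply(1:5, function(i) random_intervals(sample(5:30, 1)))
    names(sets) <- names(groups)
    mm <- build_membership(panel_of(sets, groups))
    for (s in names(sets)) {
      expect_identical(unname(mm$occupancy[, s] == 1L),
                       oracle_overlaps(mm$union_regions, sets[[s]]),
                       info = paste("rep", rep, "sample", s))
    }
    expect_true(all(rowSums(mm$occupancy) >= 1))
  }
})

seven_panel_row <- function(occ_row) {
  ## build a 7-sample membership matrix holding a single union region with
  ## the given occupancy pattern (first 3 samples High)
  groups <- c(H1 = "High", H2 = "High", H3 = "High",
              L1 = "Low", L2 = "Low", L3 = "Low", L4 = "Low")
  region <- gr0("c1", 0, 1000)
  sets <- lapply(seq_along(groups), function(i) {
    if (occ_row[i] == 1) region else gr0("c1", 90000, 91000)
  })
  names(sets) <- names(groups)
  mm <- build_membership(panel_of(sets, groups))
  idx <- which(start(mm$union_regions) == 1L)
  list(mm = mm, idx = idx)
}

test_that("classify_regions applies the uniqueness rule", {
  all_ones <- seven_panel_row(rep(1, 7))
  expect_equal(as.character(classify_regions(all_ones$mm)[all_ones$idx]),
               "common")
  hgu <- seven_panel_row(c(1, 1, 1, 0, 0, 0, 0))
  expect_equal(as.character(classify_regions(hgu$mm)[hgu$idx]), "HGU")
  partial <- seven_panel_row(c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(as.character(classify_regions(partial$mm)[partial$idx]), "other")
  expect_equal(as.character(
    classify_regions(partial$mm, min_in_group = 1)[partial$idx]), "HGU")
})

test_that("classification is a partition and symmetric under group swap", {
  set.seed(23)
  groups <- c(H1 = "High", H2 = "High", H3 = "High",
              L1 = "Low", L2 = "Low", L3 = "Low", L4 = "Low")
  sets <- lapply(seq_along(groups), function(i) random_intervals(30))
  names(sets) <- names(groups)
  mm <- build_membership(panel_of(sets, groups))
  lab <- classify_regions(mm)
  expect_equal(sum(table(lab)), length(mm$union_regions))

  swapped <- ifelse(groups == "High", "Low", "High")
  names(swapped) <- names(groups)
  mm2 <- build_membership(panel_of(sets, swapped))
  lab2 <- classify_regions(mm2)
  expect_identical(lab == "HGU", lab2 == "LGU")
  expect_identical(lab == "LGU", lab2 == "HGU")
  expect_identical(lab == "common", lab2 == "common")
})

test_that("overlap_domain_types counts cross-type overlaps per category", {
  se <- gr0("c1", c(0, 5000), c(1000, 6000))
  se_lab <- factor(c("LGU", "HGU"), levels = c("common", "HGU", "LGU", "other"))
  ## identical LGU region in both -> one B-S overlap; HGU regions disjoint
  broad <- gr0("c1", c(0, 90000), c(1000, 91000))
  broad_lab <- factor(c("LGU", "HGU"), levels = levels(se_lab))
  ov <- overlap_domain_types(se, se_lab, broad, broad_lab)
  expect_equal(ov$LGU$n_b_overlap, 1L)
  expect_equal(ov$LGU$n_s_overlap, 1L)
  expect_equal(ov$HGU$n_b_overlap, 0L)
  expect_equal(ov$HGU$n_b_only, 1L)
  expect_equal(ov$common$n_b, 0L)
})

test_that("planted cross-type overlaps are recovered exactly on a noise-free panel", {
  panel <- simulate_panel(n_common = 10, n_hgu = 40, n_lgu = 100,
                          n_background = 30, noise_sd = 0,
                          n_shared = c(common = 0, HGU = 34, LGU = 87),
                          seed = 77)
  labs <- list()
  regions <- list()
  for (mk in c("H3K27ac", "H3K4me3")) {
    pan <- sample_panel(panel$marks[[mk]]$peaks, panel$groups)
    mm <- build_membership(pan)
    labs[[mk]] <- classify_regions(mm)
    regions[[mk]] <- mm$union_regions
  }
  ov <- overlap_domain_types(regions$H3K27ac, labs$H3K27ac,
                             regions$H3K4me3, labs$H3K4me3)
  expect_equal(ov$LGU$n_s_overlap, 87L)
  expect_equal(ov$HGU$n_s_overlap, 34L)
  expect_equal(ov$common$n_s_overlap, 0L)
})

test_that("signal_matrix equals the per-cell region_signal composition", {
  regions <- gr0("c1", c(0, 1000, 2000), c(500, 1500, 2500))
  const <- gr0("c1", 0, 10000, score = 4)
  tracks <- list(s1 = const, s2 = gr0("c1", 0, 250, score = 2),
                 s3 = GRanges(score = numeric()))
  m <- signal_matrix(regions, tracks)
  expect_equal(unname(m[, "s1"]), rep(4, 3))
  expect_equal(unname(m[, "s2"]), c(1, 0, 0))  # half-covered region
  expect_equal(unname(m[, "s3"]), rep(0, 3))
  set.seed(3)
  rnd <- random_intervals(10)
  tr <- lapply(1:3, function(i) {
    s <- sort(random_intervals(5))
    s <- GenomicRanges::reduce(s)
    mcols(s)$score <- runif(length(s), 0, 2)
    s
  })
  names(tr) <- paste0("t", 1:3)
  m2 <- signal_matrix(rnd, tr, mode = "area")
  srt <- sort(rnd)
  for (j in 1:3) {
    expect_equal(unname(m2[, j]), region_signal(tr[[j]], srt, "area"))
  }
})
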