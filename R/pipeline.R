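## Pipeline orchestration: runs the stages on the bundled synthetic fixture
## with a single declarative config, writing deterministic files with stable
## names. A thin command-line wrapper around run_pipeline() is installed at
## inst/scripts/broadomains-cli.R.

#' Default pipeline configuration
#'
#' One declarative document holding every stage parameter. Unknown keys in a
#' user config are rejected; the resolved config is written next to the
#' outputs of every run.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_high = 3L, n_low = 4L, n_common = 12L, n_hgu = 10L, n_lgu = 16L,
      n_background = 60L, shared_common = 0L, shared_hgu = 4L, shared_lgu = 6L,
      genome = list(chrA = 3e7, chrB = 3e7, chrC = 3e7),
      signal_contrast = 20, noise_sd = 0.25
    ),
    domains = list(stitch_gap = 12500L, top_fraction = 0.05),
    classify = list(min_in_group = "all", max_in_other = 0L, merge_gap = 0L),
    differential = list(
      n_regions = 1000L, frac_increased = 0.05, frac_decreased = 0.05,
      effect_fold = 4, poisson_mean = 20, n_reps = 2L, fdr_threshold = 0.1,
      normalization = "median-ratio"
    ),
    tads = list(
      tad_sizes = c(12L, 8L, 20L, 10L, 15L, 9L, 14L, 12L),
      contrast = 10, noise_sd = 0.1, bin_size = 40000L,
      w = 5L, min_domain_bins = 2L, flank = 20000L
    ),
    enrich = list(n_perm = 1000L, n_bins_drawn = "auto",
                  n_boundary_features = 40L, n_uniform_features = 40L)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !key %in% c("genome", "tad_sizes")) {
      if (!is.list(user[[key]])) stop("config key must be a section: ", full)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

load_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(base, config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_line <- function(outdir, ...) {
  cat(paste0(..., "\n"), file = file.path(outdir, "run.log"), append = TRUE)
}

fixture_path <- function(outdir, ...) file.path(outdir, "fixture", ...)

require_file <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  path
}

read_panel_files <- function(cfg, outdir) {
  groups_file <- require_file(fixture_path(outdir, "groups.tsv"))
  gdf <- utils::read.table(groups_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  groups <- stats::setNames(gdf$group, gdf$sample)
  samples <- sort(gdf$sample)
  marks <- c("H3K27ac", "H3K4me3")
  out <- list()
  for (mk in marks) {
    peaks <- lapply(samples, function(s)
      read_bed(require_file(fixture_path(outdir, paste0(s, "_", mk, ".bed")))))
    tracks <- lapply(samples, function(s)
      read_bedgraph(require_file(fixture_path(outdir, paste0(s, "_", mk, ".bedGraph")))))
    names(peaks) <- names(tracks) <- samples
    out[[mk]] <- list(peaks = peaks, tracks = tracks)
  }
  list(marks = out, groups = groups[samples])
}

stage_simulate <- function(cfg, outdir) {
  sc <- cfg$simulate
  panel <- simulate_panel(
    n_high = sc$n_high, n_low = sc$n_low, n_common = sc$n_common,
    n_hgu = sc$n_hgu, n_lgu = sc$n_lgu, n_background = sc$n_background,
    n_shared = c(common = sc$shared_common, HGU = sc$shared_hgu,
                 LGU = sc$shared_lgu),
    genome = unlist(sc$genome), signal_contrast = sc$signal_contrast,
    noise_sd = sc$noise_sd, stitch_gap = cfg$domains$stitch_gap,
    seed = cfg$seed
  )
  write_panel(panel, fixture_path(outdir))
  tc <- cfg$tads
  sim <- simulate_contact_matrix(
    tad_sizes = tc$tad_sizes, contrast = tc$contrast, noise_sd = tc$noise_sd,
    bin_size = tc$bin_size, seed = cfg$seed + 1L
  )
  utils::write.table(sim$cm$matrix, fixture_path(outdir, "contacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_tsv(data.frame(boundary_bin = sim$true_boundaries),
            fixture_path(outdir, "true_boundaries.tsv"))
  log_line(outdir, "simulate: fixture written (seed ", cfg$seed, ")")
}

call_panel_domains <- function(cfg, outdir) {
  panel <- read_panel_files(cfg, outdir)
  samples <- names(panel$marks$H3K27ac$peaks)
  se_sets <- list()
  rrs_list <- list()
  for (s in samples) {
    rrs <- call_super_enhancers(panel$marks$H3K27ac$peaks[[s]],
                                panel$marks$H3K27ac$tracks[[s]],
                                stitch_gap = cfg$domains$stitch_gap)
    rrs_list[[s]] <- rrs
    se_sets[[s]] <- rrs$regions[S4Vectors::mcols(rrs$regions)$is_super]
  }
  broad_sets <- lapply(samples, function(s)
    call_broad_domains(panel$marks$H3K4me3$peaks[[s]],
                       top_fraction = cfg$domains$top_fraction)$domains)
  names(broad_sets) <- samples
  list(panel = panel, se_sets = se_sets, broad_sets = broad_sets,
       rrs_list = rrs_list)
}

stage_call_se <- function(cfg, outdir) {
  d <- call_panel_domains(cfg, outdir)
  dir.create(file.path(outdir, "se"), showWarnings = FALSE)
  for (s in names(d$rrs_list)) {
    rrs <- d$rrs_list[[s]]
    write_tsv(ranked_table(rrs), file.path(outdir, "se", paste0(s, "_ranked.tsv")))
    write_bed(rrs$regions[S4Vectors::mcols(rrs$regions)$is_super],
              file.path(outdir, "se", paste0(s, "_super.bed")))
    write_bed(rrs$regions[!S4Vectors::mcols(rrs$regions)$is_super],
              file.path(outdir, "se", paste0(s, "_typical.bed")))
    log_line(outdir, "call-se: ", s, " cutoff ",
             format(rrs$cutoff_score, digits = 8), ", ",
             sum(S4Vectors::mcols(rrs$regions)$is_super), " super-enhancers")
  }
}

stage_call_broad <- function(cfg, outdir) {
  panel <- read_panel_files(cfg, outdir)
  dir.create(file.path(outdir, "broad"), showWarnings = FALSE)
  for (s in names(panel$marks$H3K4me3$peaks)) {
    bd <- call_broad_domains(panel$marks$H3K4me3$peaks[[s]],
                             top_fraction = cfg$domains$top_fraction)
    write_bed(bd$domains, file.path(outdir, "broad", paste0(s, "_broad.bed")))
    log_line(outdir, "call-broad: ", s, " kept ", length(bd$domains),
             " domains (width threshold ", bd$width_threshold, " bp)")
  }
}

stage_classify <- function(cfg, outdir) {
  d <- call_panel_domains(cfg, outdir)
  cc <- cfg$classify
  dir.create(file.path(outdir, "classify"), showWarnings = FALSE)
  results <- list()
  for (type in c("SE", "broadK4")) {
    sets <- if (type == "SE") d$se_sets else d$broad_sets
    pan <- sample_panel(sets, d$panel$groups)
    mm <- build_membership(pan, merge_gap = cc$merge_gap)
    labels <- classify_regions(mm, min_in_group = cc$min_in_group,
                               max_in_other = cc$max_in_other)
    write_tsv(cbind(data.frame(region = rownames(mm$occupancy)),
                    as.data.frame(mm$occupancy),
                    data.frame(label = as.character(labels))),
              file.path(outdir, "classify", paste0(type, "_membership.tsv")))
    for (cat in c("common", "HGU", "LGU")) {
      write_bed(mm$union_regions[labels == cat],
                file.path(outdir, "classify", paste0(type, "_", cat, ".bed")))
    }
    results[[type]] <- list(mm = mm, labels = labels)
  }
  counts <- do.call(rbind, lapply(names(results), function(type) {
    tab <- table(results[[type]]$labels)
    data.frame(domain_type = type, category = names(tab),
               n = as.integer(tab))
  }))
  write_tsv(counts, file.path(outdir, "classify", "category_counts.tsv"))
  ov <- overlap_domain_types(results$SE$mm$union_regions, results$SE$labels,
                             results$broadK4$mm$union_regions,
                             results$broadK4$labels)
  write_tsv(do.call(rbind, lapply(names(ov), function(cat) {
    data.frame(category = cat, n_broad = ov[[cat]]$n_b, n_se = ov[[cat]]$n_s,
               n_broad_overlap = ov[[cat]]$n_b_overlap,
               n_se_overlap = ov[[cat]]$n_s_overlap)
  })), file.path(outdir, "classify", "bs_overlap.tsv"))
  log_line(outdir, "classify: category counts written")
}

stage_differential <- function(cfg, outdir) {
  dc <- cfg$differential
  sim <- simulate_treatment(
    n_regions = dc$n_regions, frac_increased = dc$frac_increased,
    frac_decreased = dc$frac_decreased, effect_fold = dc$effect_fold,
    poisson_mean = dc$poisson_mean, n_reps = dc$n_reps, seed = cfg$seed + 2L
  )
  res <- differential_regions(sim$rc, fdr_threshold = dc$fdr_threshold,
                              normalization = dc$normalization)
  res$truth <- as.character(sim$truth)
  dir.create(file.path(outdir, "differential"), showWarnings = FALSE)
  write_tsv(res, file.path(outdir, "differential", "differential_regions.tsv"))
  tab <- table(res$direction)
  write_tsv(data.frame(direction = names(tab), n = as.integer(tab)),
            file.path(outdir, "differential", "direction_counts.tsv"))
  log_line(outdir, "differential: ", sum(res$direction != "unchanged"),
           " regions changed at FDR < ", dc$fdr_threshold)
}

read_tads_from_fixture <- function(cfg, outdir) {
  tc <- cfg$tads
  cm <- read_contact_matrix(require_file(fixture_path(outdir, "contacts.tsv")),
                            format = "dense", bin_size = tc$bin_size)
  call_tads(cm, w = tc$w, min_domain_bins = tc$min_domain_bins,
            flank = tc$flank)
}

stage_tads <- function(cfg, outdir) {
  tads <- read_tads_from_fixture(cfg, outdir)
  dir.create(file.path(outdir, "tads"), showWarnings = FALSE)
  write_bed(tads$domains, file.path(outdir, "tads", "tads.bed"))
  write_bed(tads$boundary_regions, file.path(outdir, "tads", "boundaries.bed"))
  write_tsv(data.frame(gap = seq_along(tads$bin_signal),
                       bin_signal = tads$bin_signal),
            file.path(outdir, "tads", "bin_signal.tsv"))
  log_line(outdir, "tads: ", length(tads$domains), " domains, ",
           length(tads$boundary_bins), " boundaries")
}

stage_enrich <- function(cfg, outdir) {
  tads <- read_tads_from_fixture(cfg, outdir)
  ec <- cfg$enrich
  n <- tads$n_bins
  bsz <- tads$bin_size
  feats <- with_seed(cfg$seed + 3L, {
    at_bounds <- sample(tads$boundary_bins,
                        ec$n_boundary_features, replace = TRUE)
    unif <- sample.int(n, ec$n_uniform_features, replace = TRUE) - 1L
    list(
      boundary_planted = bed0_to_granges(tads$chrom, at_bounds * bsz + 1000,
                                         at_bounds * bsz + 3000),
      uniform = bed0_to_granges(tads$chrom, unif * bsz + 1000,
                                unif * bsz + 3000)
    )
  })
  rows <- lapply(names(feats), function(nm) {
    er <- boundary_enrichment(feats[[nm]], tads, flank = cfg$tads$flank,
                              n_perm = ec$n_perm,
                              n_bins_drawn = ec$n_bins_drawn,
                              seed = cfg$seed + 4L)
    data.frame(features = nm, observed = er$observed,
               expected_mean = er$expected_mean, expected_sd = er$expected_sd,
               z_score = er$z_score, empirical_p = er$empirical_p,
               n_perm = er$n_perm, n_bins_drawn = er$n_bins_drawn,
               seed = er$seed)
  })
  dir.create(file.path(outdir, "enrich"), showWarnings = FALSE)
  write_tsv(do.call(rbind, rows), file.path(outdir, "enrich", "enrichment.tsv"))
  log_line(outdir, "enrich: enrichment table written")
}

#' Run pipeline stages on the synthetic fixture
#'
#' Runs one stage, or all of them in order, writing deterministic outputs
#' with stable filenames under `outdir`. The resolved configuration is
#' written to `outdir/config_resolved.yaml` and a plain-text log (no
#' timestamps, so reruns are byte-identical) to `outdir/run.log`. Rerunning
#' with the same config and seed reproduces every output byte for byte.
#'
#' @param stage one of `"simulate"`, `"call-se"`, `"call-broad"`,
#'   `"classify"`, `"differential"`, `"tads"`, `"enrich"`, `"all"`.
#' @param config `NULL` (defaults), a YAML file path, or a nested list
#'   overriding [default_config()]; unknown keys are rejected.
#' @param outdir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return the resolved config, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "call-se", "call-broad",
                                   "classify", "differential", "tads",
                                   "enrich"),
                         config = NULL, outdir = "pipeline_out", seed = NULL) {
  stage <- match.arg(stage)
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "run.log"))
  yaml::write_yaml(cfg, file.path(outdir, "config_resolved.yaml"))
  log_line(outdir, "broadomains ", as.character(utils::packageVersion("broadomains")),
           " stage=", stage, " seed=", cfg$seed)
  stages <- if (stage == "all") {
    c("simulate", "call-se", "call-broad", "classify", "differential",
      "tads", "enrich")
  } else stage
  fns <- list(`simulate` = stage_simulate, `call-se` = stage_call_se,
              `call-broad` = stage_call_broad, `classify` = stage_classify,
              `differential` = stage_differential, `tads` = stage_tads,
              `enrich` = stage_enrich)
  for (s in stages) fns[[s]](cfg, outdir)
  invisible(cfg)
}
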