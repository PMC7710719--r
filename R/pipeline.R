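#' Load and validate a pipeline configuration
#'
#' Configs are YAML files (or equivalent lists) with condition matrix paths,
#' per-stage resolutions, method parameters and an output directory.  Every
#' referenced file must exist at load time; missing fields fall back to the
#' package defaults.
#'
#' @param x path to a YAML file, or a list.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  def <- list(
    conditions = list(control = NULL, treated = NULL),
    loops = NULL, anchor = NULL, outdir = "irhic_out", seed = 1L,
    resolutions = list(reproducibility = NULL, scaling = NULL,
                       compartments = NULL, tads = NULL),
    params = list(total = 1e6, balance_tol = 1e-5, balance_max_iter = 200,
                  filter_frac = 0.02, square_bp = 500000,
                  delta_span_bp = 120000, min_strength = 0.1,
                  d_bp = 400000, hicratio_threshold = 1,
                  pileup_window_bp = 500000, diag_exclusion_bp = 30000,
                  pileup_min_strength = 1, loop_window_bins = 10,
                  saddle_quantiles = 10, loess_span = 0.3,
                  direction = "treated_greater", max_offset_bins = 1))
  cfg <- utils::modifyList(def, cfg)
  for (cond in names(cfg$conditions)) {
    p <- cfg$conditions[[cond]]
    if (is.null(p)) stop("config is missing a matrix for condition '", cond, "'")
    if (!file.exists(p)) stop("config references a missing file: ", p)
  }
  for (p in c(cfg$loops, cfg$anchor))
    if (!is.null(p) && !file.exists(p))
      stop("config references a missing file: ", p)
  structure(cfg, class = "pipeline_config")
}

# map a bedGraph reference track onto a bin table (mean of interval
# midpoints per bin)
anchor_from_bedgraph <- function(bins, df) {
  mid <- (df$start + df$end) / 2
  at <- locate_bins(bins, df$chrom, mid)
  out <- rep(NA_real_, nrow(bins))
  ok <- !is.na(at)
  agg <- tapply(df$score[ok], at[ok], mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full control-vs-treated analysis
#'
#' Executes balance, fixed-total scaling, reproducibility, log2 ratio map,
#' scaling curves, compartments and saddle, insulation and Hicratio boundary
#' calling, boundary/loop pileups, and the matched signed-rank comparison;
#' writes every intermediate artifact plus a machine-readable JSON summary
#' and a log into the output directory.
#'
#' @param config a [pipeline_config()], YAML path, or list.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  pp <- cfg$params
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  summary <- list(parameters = pp[order(names(pp))], seed = cfg$seed)

  mats <- run_stage("load+balance+scale", {
    lapply(cfg$conditions, function(p) {
      m <- read_matrix(p)
      m <- ice_balance(m, tol = pp$balance_tol, max_iter = pp$balance_max_iter,
                       filter_frac = pp$filter_frac)
      scale_to_total(m, pp$total)
    })
  })
  for (cond in names(mats))
    write_matrix(mats[[cond]], file.path(out, paste0(cond, "_balanced.tsv")))
  base_res <- mats[[1]]$resolution
  at_res <- function(m, r) if (is.null(r) || r == base_res) m else rebin(m, r)

  summary$reproducibility <- run_stage("reproducibility", {
    rm_ <- lapply(mats, at_res, r = cfg$resolutions$reproducibility)
    rep_ <- reproducibility_report(rm_)
    utils::write.table(rep_$scores, file.path(out, "reproducibility.tsv"),
                       sep = "\t", quote = FALSE)
    list(score = rep_$scores["control", "treated"],
         resolution = rm_[[1]]$resolution)
  })

  summary$ratio_map <- run_stage("ratio map", {
    rm_ <- lapply(mats, at_res, r = cfg$resolutions$reproducibility)
    rat <- log2_ratio_map(rm_$treated, rm_$control)
    utils::write.table(rat$values, file.path(out, "log2_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    list(min = min(rat$values, na.rm = TRUE),
         max = max(rat$values, na.rm = TRUE))
  })

  summary$scaling <- run_stage("scaling curves", {
    sm <- lapply(mats, at_res, r = cfg$resolutions$scaling)
    curves <- lapply(sm, loess_scaling_curve, span = pp$loess_span)
    for (cond in names(curves))
      utils::write.table(curves[[cond]], file.path(out, paste0("scaling_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    rat <- scaling_ratio(curves$treated, curves$control)
    utils::write.table(rat, file.path(out, "scaling_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(slope_control = scaling_slope(curves$control),
         slope_treated = scaling_slope(curves$treated))
  })

  summary$compartments <- run_stage("compartments", {
    cmm <- lapply(mats, at_res, r = cfg$resolutions$compartments)
    anchor <- NULL
    if (!is.null(cfg$anchor))
      anchor <- anchor_from_bedgraph(cmm[[1]]$bins, read_bedgraph(cfg$anchor))
    tracks <- lapply(cmm, compartment_eigenvector, anchor = anchor)
    for (cond in names(tracks))
      write_bedgraph(tracks[[cond]], tracks[[cond]]$pc1,
                     file.path(out, paste0("pc1_", cond, ".bedgraph")))
    sads <- mapply(function(m, tr) saddle(m, tr, Q = pp$saddle_quantiles),
                   cmm, tracks, SIMPLIFY = FALSE)
    list(switch_fraction = switch_fraction(tracks$control, tracks$treated),
         strength_control = sads$control$strength,
         strength_treated = sads$treated$strength)
  })

  tads <- run_stage("boundaries", {
    tm <- lapply(mats, at_res, r = cfg$resolutions$tads)
    res <- list()
    for (cond in names(tm)) {
      ins <- insulation_track(tm[[cond]], square_bp = pp$square_bp)
      write_bedgraph(ins, ins$score,
                     file.path(out, paste0("insulation_", cond, ".bedgraph")))
      bi <- call_boundaries_insulation(ins, delta_span_bp = pp$delta_span_bp,
                                       min_strength = pp$min_strength)
      hr <- hicratio_track(tm[[cond]], d_bp = pp$d_bp)
      bh <- call_boundaries_hicratio(hr, threshold = pp$hicratio_threshold)
      write_bed(data.frame(chrom = bi$chrom, start = bi$pos - 1, end = bi$pos,
                           name = "ins", score = bi$strength),
                file.path(out, paste0("boundaries_insulation_", cond, ".bed")))
      write_bed(data.frame(chrom = bh$chrom, start = bh$pos - 1, end = bh$pos,
                           name = "hicratio", score = bh$strength),
                file.path(out, paste0("boundaries_hicratio_", cond, ".bed")))
      res[[cond]] <- list(matrix = tm[[cond]], insulation = bi, hicratio = bh)
    }
    res
  })
  summary$boundaries <- lapply(tads, function(x)
    list(n_insulation = nrow(x$insulation),
         median_strength_insulation = stats::median(x$insulation$strength),
         n_hicratio = nrow(x$hicratio),
         median_strength_hicratio =
           stats::median(filter_boundary_strengths(x$hicratio)$strength)))

  summary$pileups <- run_stage("pileups", {
    piles <- lapply(tads, function(x)
      boundary_pileup(x$matrix, x$insulation,
                      min_strength = pp$pileup_min_strength,
                      window_bp = pp$pileup_window_bp,
                      diag_exclusion_bp = pp$diag_exclusion_bp))
    rat <- pileup_log2_ratio(piles$treated, piles$control)
    utils::write.table(rat, file.path(out, "boundary_pileup_log2_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    Wc <- (nrow(rat) + 1) / 2
    cross <- row(rat) < Wc & col(rat) > Wc
    res <- list(boundary_n_control = piles$control$n_aggregated,
                boundary_n_treated = piles$treated$n_aggregated,
                boundary_cross_log2_ratio = mean(rat[cross], na.rm = TRUE))
    if (!is.null(cfg$loops)) {
      loops <- read_bedpe(cfg$loops)
      lp <- lapply(tads, function(x)
        loop_pileup(x$matrix, loops, window_bins = pp$loop_window_bins))
      sub <- pileup_subtract(lp$treated, lp$control)
      utils::write.table(sub, file.path(out, "loop_pileup_subtract.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      res$loop_enrichment_control <- pileup_loop_enrichment(lp$control)
      res$loop_enrichment_treated <- pileup_loop_enrichment(lp$treated)
    }
    res
  })

  summary$comparison <- run_stage("comparison", {
    res <- list()
    for (method in c("insulation", "hicratio")) {
      ctl <- tads$control[[method]]
      trt <- tads$treated[[method]]
      if (method == "hicratio") {
        ctl <- filter_boundary_strengths(ctl)
        trt <- filter_boundary_strengths(trt)
      }
      pairs <- match_boundaries(ctl, trt, max_offset_bins = pp$max_offset_bins)
      utils::write.table(pairs, file.path(out, paste0("matched_", method, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(pairs) >= 6) {
        tst <- boundary_strength_test(pairs, direction = pp$direction)
        sm <- strength_change_summary(pairs)
        res[[method]] <- list(n_matched = tst$n_matched, p_value = tst$p_value,
                              statistic = tst$statistic,
                              median_change = sm$median)
      } else {
        res[[method]] <- list(n_matched = nrow(pairs), p_value = NA,
                              statistic = NA, median_change = NA)
      }
    }
    res
  })

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  writeLines(c(paste("irhic", as.character(utils::packageVersion("irhic"))),
               R.version.string,
               paste("seed:", cfg$seed),
               paste("outdir:", normalizePath(out)),
               paste("conditions:", paste(unlist(cfg$conditions), collapse = ", "))),
             file.path(out, "pipeline.log"))
  invisible(summary)
}

#' Generate a ready-to-run demo bundle
#'
#' Writes a small control/treated synthetic pair (two chromosomes, 320 bins
#' at 40 kb), the ground-truth boundary BED, compartment bedGraph and loop
#' BEDPE, plus a config YAML wired to run the full pipeline on them.  The
#' treated condition has all boundary permeabilities multiplied by 0.75
#' (stronger boundaries), the direction of the radiation effect.
#'
#' @param outdir writable output directory.
#' @param seed integer seed; the bundle is identical across runs for a fixed
#'   seed.
#' @return the config path, invisibly.
#' @export
make_demo <- function(outdir, seed = 7L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- 40000
  lens <- c(chrA = 200 * res, chrB = 120 * res)
  tb <- list(chrA = seq(20, 180, by = 20) * res,
             chrB = seq(20, 100, by = 20) * res)
  nbin <- 320
  comp <- rep(rep(c(1, -1), each = 50), length.out = nbin)
  set.seed(as.integer(seed))
  bias <- exp(stats::rnorm(nbin, 0, 0.2))
  loops <- data.frame(bin1 = c(30, 70, 110, 150),
                      bin2 = c(55, 95, 135, 175),
                      enrichment = 3, footprint = 3)
  control <- genome_spec(lens, res, decay_exponent = 1, decay_floor = 1e-4,
                         tad_boundaries = tb, boundary_permeability = 0.6,
                         within_tad_enrichment = 1.5,
                         compartment_vector = comp,
                         compartment_amplitude = 0.35,
                         loops = loops, bin_bias = bias, seed = seed)
  treated <- perturb_boundaries(control, 0.75)
  depth <- 4e6
  mc <- sample_counts(expected_matrix(control), depth, seed = seed)
  mt <- sample_counts(expected_matrix(treated), depth, seed = seed + 1L)
  fc <- file.path(outdir, "control.tsv")
  ft <- file.path(outdir, "treated.tsv")
  write_matrix(mc, fc)
  write_matrix(mt, ft)
  truth <- true_boundaries(control)
  write_bed(data.frame(chrom = truth$chrom, start = truth$pos - 1,
                       end = truth$pos, name = "truth", score = 0),
            file.path(outdir, "truth_boundaries.bed"))
  bins <- spec_bins(control)
  write_bedgraph(bins, comp, file.path(outdir, "truth_compartments.bedgraph"))
  anchors <- data.frame(
    chrom1 = bins$chrom[loops$bin1], start1 = bins$start[loops$bin1],
    end1 = bins$end[loops$bin1],
    chrom2 = bins$chrom[loops$bin2], start2 = bins$start[loops$bin2],
    end2 = bins$end[loops$bin2])
  write_bedpe(anchors, file.path(outdir, "loops.bedpe"))
  cfg <- list(conditions = list(control = fc, treated = ft),
              loops = file.path(outdir, "loops.bedpe"),
              anchor = file.path(outdir, "truth_compartments.bedgraph"),
              outdir = file.path(outdir, "results"), seed = as.integer(seed),
              resolutions = list(reproducibility = 200000, scaling = 40000,
                                 compartments = 160000, tads = 40000))
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
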