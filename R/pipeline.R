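# End-to-end orchestration: simulate genotype datasets and run the
# map-normalization / subtraction / virtual-4C workflow on them, with a
# plain-text log of every scale factor so subtraction-map provenance is
# auditable.

pipeline_log <- function(log_path, ...) {
  line <- sprintf(...)
  if (!is.null(log_path)) cat(line, "\n", sep = "", file = log_path,
                              append = TRUE)
  invisible(line)
}

#' Simulate a genotype dataset to disk
#'
#' Runs [simulate_contacts()] for one named genotype and writes the
#' reference-projected pairs file plus a JSON truth sidecar recording
#' every parameter, the segment map, the per-bin copy-number track and a
#' checksum (sum / sum of squares / dimensions) of the bin-level
#' expected contact matrix, so any downstream result can be traced to
#' its generating configuration.
#'
#' @param config Run configuration ([default_run_config()] /
#'   [read_run_config()]).
#' @param sv_name `"wildtype"` or an SV name configured in `config$svs`.
#' @param seed RNG seed for contact sampling.
#' @param out_dir Output directory (created if needed).
#' @param locus Optional pre-built [model_locus()] (avoids re-digesting
#'   the reference when simulating several genotypes).
#' @return List with `pairs_path`, `sidecar_path` and the in-memory
#'   simulation result.
#' @export
simulate_dataset <- function(config, sv_name = "wildtype", seed,
                             out_dir = ".", locus = NULL) {
  if (!identical(sv_name, "wildtype") && is.null(config$svs[[sv_name]]))
    stop("unknown sv_name: ", sv_name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(locus)) locus <- config_locus(config)
  params <- config_params(config, seed = seed)
  sim <- simulate_contacts(locus, sv_name, params, seed = seed)
  pairs_path <- file.path(out_dir, sprintf("%s_seed%d.pairs.tsv", sv_name, seed))
  write_pairs(sim$pairs, pairs_path)
  E <- expected_matrix(locus, params, config$bin_size)
  cn <- copy_number_bins(sim$segment_map,
                         n_bins = ceiling(gi_width(locus$region) / config$bin_size),
                         bin_size = config$bin_size,
                         base_cn = config$base_copy_number)
  sidecar <- list(
    sv = sv_name, seed = seed,
    region = format_region(locus$region),
    bin_size = config$bin_size,
    locus_seed = locus$seed,
    params = unclass(params[c("alpha", "tad_boost", "leakiness", "n_pairs",
                              "loop_strength", "loop_width", "p_highq",
                              "mapq_high", "mapq_low")]),
    segment_map = sim$segment_map$segments,
    rearranged_length = sim$segment_map$rearranged_length,
    n_pairs_written = nrow(sim$pairs$pairs),
    n_dropped_payload = sim$n_dropped,
    copy_number_bins = cn,
    expected_map_checksum = list(sum = sum(E), sum_sq = sum(E^2),
                                 dim = dim(E)))
  sidecar_path <- file.path(out_dir, sprintf("%s_seed%d.truth.json", sv_name, seed))
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  list(pairs_path = pairs_path, sidecar_path = sidecar_path, sim = sim,
       locus = locus)
}

#' Run the mutant-versus-wild-type comparison pipeline
#'
#' Bins both pair sets, normalizes (KR for both; additionally LOIC with
#' the configured copy-number track for the mutant when
#' `norm = "LOIC"`), jointly scales the KR maps across sub-diagonals
#' with the rearranged regions excluded from factor computation,
#' subtracts (mutant minus wild-type), and computes virtual-4C profiles
#' and windowed integrated signals for every configured viewpoint.  All
#' outputs are plain text and byte-deterministic for fixed inputs.
#'
#' @param config Run configuration.
#' @param mutant,wildtype `contact_pairs` objects or paths to pairs
#'   files.
#' @param sv_name SV name of the mutant (defines exclusion regions and
#'   the copy-number track); `"wildtype"` for a null comparison.
#' @param out_dir Output directory.
#' @param norm `"KR"` or `"LOIC"` for the mutant's normalized map
#'   (subtraction always uses the KR maps, as in the reference
#'   workflow).
#' @param locus Optional pre-built locus model.
#' @return List of file paths plus the in-memory subtraction map and
#'   integrated-signal table.
#' @export
run_pipeline <- function(config, mutant, wildtype, sv_name = "wildtype",
                         out_dir = ".", norm = c("KR", "LOIC"),
                         locus = NULL) {
  norm <- match.arg(norm)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  if (file.exists(log_path)) file.remove(log_path)
  if (is.null(locus)) locus <- config_locus(config)
  region <- locus$region
  if (is.character(mutant)) mutant <- read_pairs(mutant)
  if (is.character(wildtype)) wildtype <- read_pairs(wildtype)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  m_raw <- stage("bin", bin_pairs(mutant, region, config$bin_size, config$mapq_min))
  w_raw <- stage("bin", bin_pairs(wildtype, region, config$bin_size, config$mapq_min))
  pipeline_log(log_path, "bin: mutant=%d wildtype=%d qualifying pairs",
               m_raw$metadata$pairs_used, w_raw$metadata$pairs_used)

  m_kr <- stage("balance", kr_balance(m_raw))
  w_kr <- stage("balance", kr_balance(w_raw))
  pipeline_log(log_path, "kr: residual mutant=%.3g wildtype=%.3g",
               m_kr$bias$convergence_error, w_kr$bias$convergence_error)

  paths <- list()
  write_map <- function(m, tag) {
    p <- file.path(out_dir, paste0(tag, ".coo.tsv"))
    write_contact_map(m, p, "coo")
    paths[[tag]] <<- p
  }
  write_map(m_raw, "mutant_raw"); write_map(w_raw, "wildtype_raw")
  write_map(m_kr$map, "mutant_kr"); write_map(w_kr$map, "wildtype_kr")

  if (norm == "LOIC") {
    sm <- locus_segment_map(locus, sv_name)
    cn <- copy_number_bins(sm, n_bins(m_raw), config$bin_size,
                           config$base_copy_number)
    m_loic <- stage("balance", loic_normalize(m_raw, cn))
    write_map(m_loic$map, "mutant_loic")
    pipeline_log(log_path, "loic: residual=%.3g", m_loic$bias$convergence_error)
  }

  exclude <- config_exclude(config, sv_name)
  scaled <- stage("joint_scale",
                  joint_distance_scale(m_kr$map, w_kr$map, exclude,
                                       total = config$map_scale))
  pipeline_log(log_path, "joint_scale: global factors mutant=%.6g wildtype=%.6g",
               scaled$a$metadata$global_factor, scaled$b$metadata$global_factor)
  sub <- stage("subtract", subtract_maps(scaled$a, scaled$b, excluded = exclude))
  sub_path <- file.path(out_dir, "subtraction.tsv")
  write_contact_map(sub, sub_path, "tsv")
  paths$subtraction <- sub_path

  rows <- list()
  for (vp_name in names(config$viewpoints)) {
    vp <- locus_interval(locus, config$viewpoints[[vp_name]])
    for (samp in c("mutant", "wildtype")) {
      pp <- if (samp == "mutant") mutant else wildtype
      prof <- stage("v4c", virtual4c(pp, vp, locus$rm,
                                     mapq_min = config$mapq_min,
                                     grid_size = config$grid_size,
                                     window = config$smooth_window,
                                     margin = config$margin,
                                     scale_total = config$profile_scale))
      bg <- file.path(out_dir, sprintf("v4c_%s_%s.bedgraph", vp_name, samp))
      write_profile_bedgraph(prof, bg)
      paths[[paste0("v4c_", vp_name, "_", samp)]] <- bg
      pipeline_log(log_path, "v4c %s %s: scale_factor=%.6g qualifying=%d",
                   vp_name, samp, prof$scale_factor, prof$total_qualifying)
      for (w_name in names(config$windows)) {
        win <- locus_interval(locus, config$windows[[w_name]])
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samp, viewpoint = vp_name, window = w_name,
          integrated_signal = integrate_signal(prof, win))
      }
    }
  }
  integ <- do.call(rbind, rows)
  integ_path <- file.path(out_dir, "integrated_signal.tsv")
  utils::write.table(format(integ, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     integ_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$integrated <- integ_path
  list(paths = paths, subtraction = sub, integrated = integ,
       scaled = scaled, log = log_path)
}
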