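# Run configuration: a flat textual (YAML) key-value file with sections
# per structural variant.  Defaults mirror the printed analysis
# parameters: 5 kb map bins, MAPQ >= 30, 1 kb virtual-4C grid, 5 kb
# smoothing window, +-5 kb viewpoint margin, profile scale 1e3, map
# scale 1e6, copy number 4 over the duplication and 2 elsewhere.

#' Default run configuration
#'
#' @return Nested list of parameters; see the fields of the returned
#'   object and the package vignette for meanings and units.
#' @export
default_run_config <- function() {
  list(
    region = "chr19:44,440,001-46,400,000",
    bin_size = 5000,
    grid_size = 1000,
    smooth_window = 5000,
    margin = 5000,
    mapq_min = 30,
    motif = "GATC",
    profile_scale = 1000,
    map_scale = 1e6,
    base_copy_number = 2,
    locus_seed = 1903,
    boundaries = c(44700000, 45400000, 46100000),
    ctcf = list(pos = c(44698000, 44702000, 45396000,
                        45404000, 46098000, 46102000),
                strand = c("-", "+", "-", "+", "-", "+")),
    genes = list(start = c(45100000, 45200000, 45380000,
                           45406000, 45460000, 46000000),
                 end = c(45105000, 45260000, 45392000,
                         45418000, 45545000, 46006000),
                 name = c("Lbx1", "Btrc", "Poll", "Dpcd", "Fbxw4", "Fgf8")),
    enhancers = list(start = c(45480000, 45492000, 45504000,
                               45516000, 45990000),
                     end = c(45482000, 45494000, 45506000,
                             45518000, 45992000),
                     name = c("CE58", "CE59", "CE61", "CE66", "CE80")),
    model = list(alpha = 1.0, tad_boost = 3.0, leakiness = 0.3,
                 n_pairs = 5e5, loop_strength = 1.0, loop_width = 10000,
                 p_highq = 0.9, mapq_high = 60, mapq_low = 10),
    svs = list(
      dup = list(kind = "tandem_duplication",
                 breakpoints = c(45020000, 45560000)),
      inv1 = list(kind = "inversion", breakpoints = c(45300000, 45900000)),
      inv2 = list(kind = "inversion", breakpoints = c(45150000, 45900000)),
      ki = list(kind = "insertion", breakpoints = 45110000,
                payload_length = 6993)),
    viewpoints = list(Lbx1 = c(45100000, 45105000),
                      Fgf8 = c(46000000, 46006000),
                      Btrc = c(45200000, 45205000)),
    windows = list(enhancer_region = c(45455000, 45580000))
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read / write a run configuration
#'
#' Reads a YAML config file and merges it over [default_run_config()],
#' so a config needs to state only what differs from the defaults.
#'
#' @param path Config file path.
#' @return `read_run_config` returns the merged config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config Config list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  num_fields <- c("bin_size", "grid_size", "smooth_window", "margin",
                  "mapq_min", "profile_scale", "map_scale",
                  "base_copy_number")
  for (f in num_fields)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field ", f, " must be a positive number")
  if (anyDuplicated(names(cfg$svs))) stop("duplicate SV names in config")
  invisible(cfg)
}

# construct the locus model and contact params described by a config
config_locus <- function(cfg) {
  model_locus(region = parse_region(cfg$region),
              seed = as.integer(cfg$locus_seed),
              motif = cfg$motif,
              boundaries = unlist(cfg$boundaries),
              ctcf = as.data.frame(cfg$ctcf),
              genes = as.data.frame(cfg$genes),
              enhancers = as.data.frame(cfg$enhancers),
              svs = lapply(cfg$svs, function(s)
                rearrangement(s$kind, s$breakpoints,
                              payload_length = s$payload_length)),
              viewpoints = cfg$viewpoints,
              windows = cfg$windows)
}

config_params <- function(cfg, n_pairs = NULL, seed = NULL) {
  m <- cfg$model
  contact_params(alpha = m$alpha, tad_boost = m$tad_boost,
                 leakiness = m$leakiness,
                 n_pairs = if (is.null(n_pairs)) m$n_pairs else n_pairs,
                 loop_strength = m$loop_strength, loop_width = m$loop_width,
                 p_highq = m$p_highq, mapq_high = m$mapq_high,
                 mapq_low = m$mapq_low, seed = seed)
}

# exclusion intervals for a genotype comparison: the rearranged span(s)
config_exclude <- function(cfg, sv) {
  if (identical(sv, "wildtype")) return(NULL)
  s <- cfg$svs[[sv]]
  if (is.null(s)) stop("unknown sv_name: ", sv)
  chrom <- parse_region(cfg$region)$chrom
  if (s$kind == "insertion") return(NULL)
  list(gi(chrom, s$breakpoints[1], s$breakpoints[2]))
}
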