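#' Pipeline configuration
#'
#' Collects and validates every stage parameter of a full run. Defaults
#' are the study conditions the pipeline targets: 1950-read rarefaction,
#' 20-read (1%) minimum prey count, 95% assignment identity, 2-edit OTU
#' radius, 99,999 permutation iterations, a 0.001 availability floor,
#' and the conventional 0.6 substantial-overlap threshold.
#'
#' @param depth rarefaction depth (reads).
#' @param min_prey_reads minimum prey reads per retained sample.
#' @param min_identity minimum reference identity for ESU assignment.
#' @param max_diff OTU clustering radius (edits).
#' @param n_perm permutation iterations for the overlap-change test.
#' @param zero_floor availability floor fraction.
#' @param overlap_threshold substantial-overlap flag level.
#' @param seed integer seed for all stochastic stages.
#' @param community optional [community_config()] used when the run
#'   simulates its inputs; defaults to `community_config(seed = seed)`.
#' @param out_dir optional output directory; when set, stage outputs and
#'   the manifest are written there as TSV/JSON.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(depth = 1950, min_prey_reads = 20,
                            min_identity = 0.95, max_diff = 2,
                            n_perm = 99999, zero_floor = 0.001,
                            overlap_threshold = 0.6, seed = 1,
                            community = NULL, out_dir = NULL) {
  cfg <- list(depth = depth, min_prey_reads = min_prey_reads,
              min_identity = min_identity, max_diff = max_diff,
              n_perm = n_perm, zero_floor = zero_floor,
              overlap_threshold = overlap_threshold, seed = as.integer(seed),
              community = community %||% community_config(seed = seed),
              out_dir = out_dir)
  pos <- c("depth", "min_prey_reads", "min_identity", "max_diff", "n_perm",
           "zero_floor", "overlap_threshold")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("config error: `", f, "` must be a positive scalar", call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override the [pipeline_config()] defaults; a nested
#' `community:` block overrides [community_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  comm <- NULL
  if (!is.null(y$community)) {
    comm <- do.call(community_config, y$community)
    y$community <- NULL
  }
  do.call(pipeline_config, c(y, list(community = comm)))
}

#' Run the full diet-analysis pipeline on a synthetic community
#'
#' Executes all stages on generated data: simulate (reference database,
#' GI samples, mock homogenate, drift survey), process samples to a diet
#' matrix, estimate amplification bias, convert the drift survey to
#' availability, and compute overlap and selectivity statistics. Reruns
#' with an identical configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return object of class `diet_pipeline`: `config`, `manifest`,
#'   `refdb`, `diet` (a `diet_matrix`), `processing_report`, `rcf` (an
#'   `rcf_table`), `bias_correlation`, `drift` (nightly ESU biomass),
#'   `period_biomass`, `overlap` (an `overlap_result`), `overlap_test`
#'   (a `sign_flip_test`), `selectivity` (a `selectivity_table`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  comm <- config$community

  refdb <- generate_reference_db(comm)
  synth <- simulate_diet_samples(comm, refdb)
  proc <- process_samples(synth$counts, synth$sequences, synth$metadata,
                          refdb, depth = config$depth,
                          min_prey_reads = config$min_prey_reads,
                          max_diff = config$max_diff,
                          min_identity = config$min_identity,
                          seed = config$seed)

  # mock homogenate: equal-biomass mixture of the bilaterian ESUs,
  # sequenced with the community's own bias factors
  bil <- refdb$esus$esu[refdb$esus$is_bilaterian]
  bias <- stats::setNames(comm$bias_factors, refdb$esus$esu)[bil]
  mock <- simulate_mock_homogenate(
    stats::setNames(rep(1 / length(bil), length(bil)), bil),
    bias, depth = 9450, seed = config$seed)
  rcf <- compute_rcf(mock)
  bias_cor <- biomass_sequence_correlation(mock)

  drift <- simulate_drift_survey(synthetic_drift_families(bil, config$seed),
                                 seed = config$seed)
  nightly <- aggregate_biomass_to_esu(drift)
  period_biomass <- period_average_biomass(nightly)

  overlap <- overlap_matrices(proc$diet, threshold = config$overlap_threshold)
  overlap_test <- NULL
  if (!is.null(overlap$pairs) && !is.null(overlap$pairs$delta) &&
      sum(!is.na(overlap$pairs$delta)) >= 2) {
    ok <- !is.na(overlap$pairs$delta)
    overlap_test <- paired_sign_flip_test(delta = overlap$pairs$delta[ok],
                                          n_perm = config$n_perm,
                                          seed = config$seed)
  }

  # synthetic diets use the synthetic survey's ESU space only where the
  # two overlap; selectivity is computed over that shared index
  surveyed <- intersect(unique(nightly$esu), colnames(proc$diet$proportions))
  selectivity <- NULL
  if (length(surveyed) >= 2) {
    has_night <- proc$diet$metadata$night %in% nightly$night
    d2 <- proc$diet
    d2$proportions <- d2$proportions[has_night, , drop = FALSE]
    d2$prey_reads <- d2$prey_reads[has_night]
    d2$metadata <- d2$metadata[has_night, , drop = FALSE]
    if (nrow(d2$proportions) > 0) {
      selectivity <- selectivity_by_day(d2, nightly, surveyed_esus = surveyed,
                                        zero_floor = config$zero_floor)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("driftdiet")),
    seed = config$seed,
    parameters = unclass(config)[c("depth", "min_prey_reads", "min_identity",
                                   "max_diff", "n_perm", "zero_floor",
                                   "overlap_threshold")],
    community = unclass(comm),
    stage_counts = list(
      n_samples_simulated = nrow(synth$counts),
      n_sequences = ncol(synth$counts),
      filter = as.list(proc$report$filter),
      n_otus = proc$report$n_otus,
      n_unassigned_otus = proc$report$n_unassigned,
      n_discarded_low_depth = proc$report$discarded_low_depth,
      n_samples_retained = nrow(proc$diet$proportions),
      n_excluded = nrow(proc$diet$exclusions),
      n_drift_nights = length(unique(nightly$night)),
      n_overlap_pairs = if (is.null(overlap$pairs)) 0L else nrow(overlap$pairs)
    ))

  res <- structure(list(config = config, manifest = manifest, refdb = refdb,
                        truth = synth$truth, diet = proc$diet,
                        processing_report = proc$report,
                        mock = mock, rcf = rcf, bias_correlation = bias_cor,
                        drift = nightly, period_biomass = period_biomass,
                        overlap = overlap, overlap_test = overlap_test,
                        selectivity = selectivity),
                   class = "diet_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(data.frame(sample_id = rownames(res$diet$proportions),
                res$diet$proportions, check.names = FALSE),
     "diet_proportions.tsv")
  wt(res$diet$exclusions, "exclusions.tsv")
  wt(as.data.frame(res$rcf), "rcf.tsv")
  wt(res$drift, "nightly_esu_biomass.tsv")
  wt(res$period_biomass, "period_biomass.tsv")
  if (!is.null(res$overlap$pairs)) wt(res$overlap$pairs, "overlap_pairs.tsv")
  if (!is.null(res$selectivity)) wt(as.data.frame(res$selectivity),
                                    "selectivity.tsv")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$overlap_test)) {
    jsonlite::write_json(unclass(res$overlap_test),
                         file.path(dir, "overlap_test.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(render_report(res), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render a human-readable run summary
#'
#' @param res a `diet_pipeline` result.
#' @return character vector of report lines.
#' @export
render_report <- function(res) {
  stopifnot(inherits(res, "diet_pipeline"))
  sc <- res$manifest$stage_counts
  lines <- c(
    "Diet metabarcoding pipeline report",
    "==================================",
    sprintf("seed %d | rarefaction depth %d | min prey reads %d",
            res$manifest$seed, res$config$depth, res$config$min_prey_reads),
    "",
    sprintf("Samples: %d simulated, %d retained, %d excluded",
            sc$n_samples_simulated, sc$n_samples_retained, sc$n_excluded),
    sprintf("Filter removals: too_long %d, homopolymer %d, singleton %d",
            sc$filter$too_long, sc$filter$homopolymer, sc$filter$singleton),
    sprintf("OTUs: %d (%d unassigned); low-depth discards: %d",
            sc$n_otus, sc$n_unassigned_otus, sc$n_discarded_low_depth),
    "",
    "Relative correction factors (amplification bias):")
  r <- res$rcf
  lines <- c(lines, sprintf("  %-24s RCF %7.3f %s", r$family, r$rcf,
                            ifelse(r$overrepresented, "(overrepresented)", "")))
  for (pd in names(res$overlap$alpha)) {
    m <- res$overlap$alpha[[pd]]
    if (nrow(m) < 2) {
      lines <- c(lines, "", sprintf("Overlap (%s): fewer than 2 species", pd))
      next
    }
    lines <- c(lines, "", sprintf("Schoener's alpha, %s period:", pd))
    ut <- which(upper.tri(m), arr.ind = TRUE)
    lines <- c(lines, sprintf("  %s - %s: %.2f%s",
                              rownames(m)[ut[, 1]], colnames(m)[ut[, 2]],
                              m[ut],
                              ifelse(m[ut] > res$overlap$threshold,
                                     "  [substantial]", "")))
  }
  if (!is.null(res$overlap_test)) {
    lines <- c(lines, "",
               sprintf("Overlap change (postdrift - drift): mean delta = %.3f, p = %.4g (%d iterations)",
                       res$overlap_test$statistic, res$overlap_test$p,
                       res$overlap_test$n_perm))
  }
  if (!is.null(res$selectivity) && nrow(res$selectivity) > 0) {
    s <- res$selectivity
    top <- s[order(-abs(s$chesson_epsilon)), ][seq_len(min(5, nrow(s))), ]
    lines <- c(lines, "", "Strongest selectivity (Chesson's epsilon):",
               sprintf("  %s %s %s: %+.2f", top$species, top$date, top$esu,
                       top$chesson_epsilon))
  }
  lines
}

#' @export
print.diet_pipeline <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
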