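#' Configuration for the synthetic diet-study generator
#'
#' Bundles and validates every knob of the synthetic community used to
#' exercise the pipeline end-to-end: how many predator species and prey
#' ESUs (ecologically significant units) exist, how deep samples are
#' sequenced, how strongly amplification favours each ESU, and how much
#' of each gut sample is the predator's own DNA.
#'
#' The defaults emulate the field conditions the pipeline targets: GI
#' samples rarefied to 1950 reads, predator self-reads at 43.05% of the
#' total, per-ESU amplification bias spanning roughly 0.1-3.5x (the range
#' implied by mock-homogenate correction factors), and a small admixture
#' of junk sequences that each quality filter must catch.
#'
#' @param n_predator_species number of predator fish species.
#' @param n_esus total number of ESUs, including one self ESU per
#'   predator species and `n_decoy_esus` non-bilaterian decoys.
#' @param n_samples_per_species_period GI samples per species per period.
#' @param rarefaction_depth target read depth per sample (reads).
#' @param read_length integer range (min, max) of reference sequence
#'   lengths in bp after primer trimming.
#' @param bias_factors positive per-ESU amplification multipliers, length
#'   `n_esus`; `NULL` uses a log-spaced ladder from 0.1 to 3.5.
#' @param self_read_fraction expected share of a sample's reads coming
#'   from the predator's own tissue, in [0, 1).
#' @param junk_otu_rate expected share of reads in junk sequences
#'   (overlong, homopolymer, singleton, unassignable), in [0, 1).
#' @param decoy_read_fraction expected share of reads in non-bilaterian
#'   decoy ESUs (parasites, incidental microbes), in [0, 1).
#' @param dirichlet_concentration concentration of the per-sample
#'   Dirichlet draw around the species-by-period diet profile; larger
#'   values mean less among-fish variation.
#' @param n_decoy_esus number of non-bilaterian decoy ESUs.
#' @param variants_per_esu reference sequence variants per ESU (each
#'   within 2 bp of the ESU centroid).
#' @param n_shallow number of samples generated with total depth below
#'   `rarefaction_depth` (exercises the low-depth discard rule).
#' @param n_empty number of near-empty-stomach samples dominated by
#'   self-reads (exercises the minimum-prey-reads exclusion).
#' @param seed integer seed; all generator stages derive independent
#'   substreams from it.
#'
#' @return a validated list of class `community_config`.
#' @export
community_config <- function(n_predator_species = 3,
                             n_esus = 12,
                             n_samples_per_species_period = 5,
                             rarefaction_depth = 1950,
                             read_length = c(150L, 170L),
                             bias_factors = NULL,
                             self_read_fraction = 0.4305,
                             junk_otu_rate = 0.05,
                             decoy_read_fraction = 0.02,
                             dirichlet_concentration = 5,
                             n_decoy_esus = 2,
                             variants_per_esu = 2,
                             n_shallow = 2,
                             n_empty = 2,
                             seed = 1) {
  cfg <- list(n_predator_species = as.integer(n_predator_species),
              n_esus = as.integer(n_esus),
              n_samples_per_species_period = as.integer(n_samples_per_species_period),
              rarefaction_depth = as.integer(rarefaction_depth),
              read_length = as.integer(read_length),
              bias_factors = bias_factors,
              self_read_fraction = self_read_fraction,
              junk_otu_rate = junk_otu_rate,
              decoy_read_fraction = decoy_read_fraction,
              dirichlet_concentration = dirichlet_concentration,
              n_decoy_esus = as.integer(n_decoy_esus),
              variants_per_esu = as.integer(variants_per_esu),
              n_shallow = as.integer(n_shallow),
              n_empty = as.integer(n_empty),
              seed = as.integer(seed))
  counts <- c("n_predator_species", "n_samples_per_species_period",
              "rarefaction_depth", "variants_per_esu")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("invalid config: `", f, "` must be a count >= 1", call. = FALSE)
    }
  }
  if (is.na(cfg$n_esus) || cfg$n_esus < 2L) {
    stop("invalid config: `n_esus` must be >= 2", call. = FALSE)
  }
  min_esus <- max(2L, cfg$n_predator_species + cfg$n_decoy_esus)
  if (cfg$n_esus < min_esus) {
    stop("invalid config: need n_esus >= ", min_esus,
         " (one self ESU per predator plus ", cfg$n_decoy_esus,
         " decoys)", call. = FALSE)
  }
  if (is.null(cfg$bias_factors)) {
    cfg$bias_factors <- exp(seq(log(0.1), log(3.5), length.out = cfg$n_esus))
  }
  if (length(cfg$bias_factors) != cfg$n_esus || any(cfg$bias_factors <= 0)) {
    stop("invalid config: `bias_factors` must be ", cfg$n_esus,
         " positive multipliers", call. = FALSE)
  }
  for (f in c("self_read_fraction", "junk_otu_rate", "decoy_read_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop("invalid config: `", f, "` must be in [0, 1)", call. = FALSE)
    }
  }
  if (cfg$self_read_fraction + cfg$junk_otu_rate + cfg$decoy_read_fraction >= 1) {
    stop("invalid config: self + junk + decoy read fractions must leave ",
         "room for prey reads", call. = FALSE)
  }
  if (length(cfg$read_length) != 2L || cfg$read_length[1] > cfg$read_length[2] ||
      cfg$read_length[1] < 50L) {
    stop("invalid config: `read_length` must be an increasing (min, max) pair",
         call. = FALSE)
  }
  structure(cfg, class = "community_config")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

has_homopolymer <- function(seq, min_run = 8L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", min_run, min_run, min_run, min_run),
        seq)
}

# Random sequence free of homopolymer runs that would trip the quality
# filter (generated sequences model already-clean marker regions).
clean_random_dna <- function(len, min_run = 8L) {
  for (i in 1:100) {
    s <- random_dna(len)
    if (!has_homopolymer(s, min_run)) return(s)
  }
  stop("could not generate a homopolymer-free sequence", call. = FALSE)
}

mutate_sequence <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

pairwise_identity <- function(a, b) {
  1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

#' Generate a synthetic reference database and ESU taxonomy
#'
#' Creates one centroid sequence per ESU (pairwise identity between ESUs
#' below 95%, so reference assignment is unambiguous) plus within-ESU
#' variants at most 2 bp from the centroid. The taxonomy marks
#' non-bilaterian decoy ESUs (not counted as prey) and assigns each
#' predator species a "self" ESU whose reads are removed from that
#' predator's own samples but kept as prey in other predators' samples.
#'
#' @param config a [community_config()].
#' @return list of class `reference_db` with elements `sequences` (named
#'   character vector of reference sequences), `refs` (data.frame
#'   `ref_id`, `esu`), and `esus` (data.frame `esu`, `family`,
#'   `is_bilaterian`, `self_of_species`).
#' @export
generate_reference_db <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(substream_seed(config$seed, "reference"))
  n <- config$n_esus
  esu_ids <- sprintf("ESU_%02d", seq_len(n))
  predators <- sprintf("predator_%02d", seq_len(config$n_predator_species))

  self_of <- rep(NA_character_, n)
  self_of[seq_len(config$n_predator_species)] <- predators
  is_bil <- rep(TRUE, n)
  if (config$n_decoy_esus > 0) {
    is_bil[(n - config$n_decoy_esus + 1L):n] <- FALSE
  }

  centroids <- character(n)
  for (i in seq_len(n)) {
    len <- sample(config$read_length[1]:config$read_length[2], 1)
    repeat {
      cand <- clean_random_dna(len)
      ok <- i == 1L ||
        all(vapply(centroids[seq_len(i - 1L)], pairwise_identity,
                   numeric(1), b = cand) < 0.95)
      if (ok) break
    }
    centroids[i] <- cand
  }

  seqs <- character(0)
  ref_id <- character(0)
  ref_esu <- character(0)
  for (i in seq_len(n)) {
    for (v in seq_len(config$variants_per_esu)) {
      s <- if (v == 1L) centroids[i] else mutate_sequence(centroids[i], sample(1:2, 1))
      id <- sprintf("%s_v%d", esu_ids[i], v)
      seqs <- c(seqs, s)
      ref_id <- c(ref_id, id)
      ref_esu <- c(ref_esu, esu_ids[i])
    }
  }
  names(seqs) <- ref_id

  structure(list(
    sequences = seqs,
    refs = data.frame(ref_id = ref_id, esu = ref_esu,
                      stringsAsFactors = FALSE),
    esus = data.frame(esu = esu_ids, family = esu_ids,
                      is_bilaterian = is_bil, self_of_species = self_of,
                      stringsAsFactors = FALSE)
  ), class = "reference_db")
}

#' Simulate predator GI-tract diet samples with known true diets
#'
#' For each predator species and sampling period, draws a latent diet
#' profile and then per-fish true diets from a Dirichlet around it. Reads
#' are allocated by a multinomial over the predator's self ESU (expected
#' share `self_read_fraction`), prey ESUs (proportional to true diet
#' times per-ESU amplification bias), non-bilaterian decoy ESUs, and junk
#' sequences. The junk pool plants one sequence for each quality-filter
#' rule (overlong, dataset-wide singleton, >= 8 bp homopolymer) plus
#' unassignable clean sequences. `n_shallow` samples are generated below
#' the rarefaction depth and `n_empty` samples are dominated by
#' self-reads, so the downstream exclusion rules always have positive
#' test cases.
#'
#' @param config a [community_config()].
#' @param refdb a [generate_reference_db()] result.
#' @return list of class `synthetic_diet_set`: `counts` (samples x
#'   features integer matrix), `sequences` (feature id -> sequence),
#'   `features` (data.frame with feature kind), `metadata` (sample_id,
#'   species, period, date, night, substrate, site), and
#'   `truth` (samples x ESUs matrix of true prey proportions).
#' @export
simulate_diet_samples <- function(config, refdb) {
  stopifnot(inherits(config, "community_config"), inherits(refdb, "reference_db"))
  set.seed(substream_seed(config$seed, "diets"))

  esus <- refdb$esus
  n_esus <- nrow(esus)
  bias <- stats::setNames(config$bias_factors, esus$esu)
  predators <- stats::setNames(esus$self_of_species[!is.na(esus$self_of_species)],
                               esus$esu[!is.na(esus$self_of_species)])
  species <- unname(predators)
  decoy_esus <- esus$esu[!esus$is_bilaterian]

  # junk feature pool; the homopolymer read carries an embedded 8 bp run
  # and the overlong read exceeds the post-trim target size
  len0 <- config$read_length[1]
  junk_seqs <- c(
    junk_overlong = clean_random_dna(181L),
    junk_homopolymer = {
      s <- clean_random_dna(len0)
      paste0(substr(s, 1, 40), strrep("A", 8), substr(s, 49, len0))
    },
    junk_singleton = clean_random_dna(len0),
    junk_unassigned1 = clean_random_dna(len0),
    junk_unassigned2 = clean_random_dna(len0)
  )

  features <- c(names(refdb$sequences), names(junk_seqs))
  sequences <- c(refdb$sequences, junk_seqs)
  feature_kind <- c(rep("reference", length(refdb$sequences)),
                    "junk_overlong", "junk_homopolymer", "junk_singleton",
                    "junk_unassigned", "junk_unassigned")
  feature_esu <- c(refdb$refs$esu, rep(NA_character_, length(junk_seqs)))

  periods <- c("drift", "postdrift")
  nights <- list(drift = c("2015-05-23", "2015-06-04", "2015-06-05",
                           "2015-06-06", "2015-06-07"),
                 postdrift = c("2015-07-03", "2015-07-05"))

  # latent species-by-period diet profiles over that species' prey ESUs
  profile <- list()
  for (sp in species) {
    prey <- esus$esu[esus$is_bilaterian & (is.na(esus$self_of_species) |
                                             esus$self_of_species != sp)]
    if (length(prey) < 2) {
      stop("simplex profile invalid: species ", sp, " has fewer than 2 ",
           "prey ESUs; increase `n_esus`", call. = FALSE)
    }
    for (pd in periods) {
      profile[[paste(sp, pd)]] <- stats::setNames(rdirichlet1(rep(0.8, length(prey))),
                                                  prey)
    }
  }

  n_samples <- config$n_predator_species * length(periods) *
    config$n_samples_per_species_period
  shallow_idx <- if (config$n_shallow > 0 && n_samples > 1) {
    sample(n_samples, min(config$n_shallow, n_samples))
  } else integer(0)
  empty_pool <- setdiff(seq_len(n_samples), shallow_idx)
  empty_idx <- if (config$n_empty > 0 && length(empty_pool) > 0) {
    sample(empty_pool, min(config$n_empty, length(empty_pool)))
  } else integer(0)

  counts <- matrix(0L, nrow = n_samples, ncol = length(features),
                   dimnames = list(NULL, features))
  truth <- matrix(0, nrow = n_samples, ncol = n_esus,
                  dimnames = list(NULL, esus$esu))
  meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
                     species = NA_character_, period = NA_character_,
                     date = NA_character_, night = NA_character_,
                     substrate = NA_character_, site = NA_character_,
                     stringsAsFactors = FALSE)
  rownames(counts) <- rownames(truth) <- meta$sample_id

  k <- 0L
  for (sp in species) {
    self_esu <- names(predators)[predators == sp]
    for (pd in periods) {
      prof <- profile[[paste(sp, pd)]]
      for (j in seq_len(config$n_samples_per_species_period)) {
        k <- k + 1L
        night <- nights[[pd]][1L + (k - 1L) %% length(nights[[pd]])]
        substrate <- if (k %% 2L == 0L) "sand" else "gravel"
        meta$species[k] <- sp
        meta$period[k] <- pd
        meta$night[k] <- night
        meta$date[k] <- as.character(as.Date(night) + 1L)
        meta$substrate[k] <- substrate
        meta$site[k] <- if (substrate == "sand") "PD4" else "PD1"

        true_diet <- rdirichlet1(config$dirichlet_concentration * prof)
        names(true_diet) <- names(prof)
        truth[k, names(true_diet)] <- true_diet

        self_frac <- config$self_read_fraction
        junk_frac <- config$junk_otu_rate
        decoy_frac <- config$decoy_read_fraction
        if (k %in% empty_idx) {
          self_frac <- 0.995
          junk_frac <- 0
          decoy_frac <- 0
        }
        prey_frac <- 1 - self_frac - junk_frac - decoy_frac

        w <- stats::setNames(numeric(length(features)), features)
        # prey reads: truth x bias, renormalized
        pw <- true_diet * bias[names(true_diet)]
        pw <- pw / sum(pw) * prey_frac
        for (e in names(pw)) {
          vids <- refdb$refs$ref_id[refdb$refs$esu == e]
          w[vids] <- w[vids] + pw[e] / length(vids)
        }
        # self reads
        vids <- refdb$refs$ref_id[refdb$refs$esu == self_esu]
        w[vids] <- w[vids] + self_frac / length(vids)
        # decoy reads
        if (decoy_frac > 0 && length(decoy_esus) > 0) {
          for (e in decoy_esus) {
            vids <- refdb$refs$ref_id[refdb$refs$esu == e]
            w[vids] <- w[vids] + decoy_frac / length(decoy_esus) / length(vids)
          }
        }
        # junk reads (the planted singleton is added separately below)
        if (junk_frac > 0) {
          w["junk_overlong"] <- junk_frac * 0.3
          w["junk_homopolymer"] <- junk_frac * 0.3
          w[c("junk_unassigned1", "junk_unassigned2")] <- junk_frac * 0.2
        }

        depth <- if (k %in% shallow_idx) {
          sample(seq(20L, config$rarefaction_depth - 1L), 1)
        } else {
          round(stats::runif(1, 1.2, 2.5) * config$rarefaction_depth)
        }
        counts[k, ] <- as.integer(stats::rmultinom(1, depth, w))
      }
    }
  }
  # dataset-wide singleton: exactly one read, in the first sample
  if (config$junk_otu_rate > 0) counts[1, "junk_singleton"] <- 1L

  structure(list(counts = counts,
                 sequences = sequences,
                 features = data.frame(feature_id = features,
                                       kind = feature_kind, esu = feature_esu,
                                       stringsAsFactors = FALSE),
                 metadata = meta,
                 truth = truth),
            class = "synthetic_diet_set")
}

#' Simulate a sequenced mock tissue homogenate
#'
#' Given known biomass proportions and per-family amplification bias,
#' draws sequence counts from a multinomial over the bias-distorted
#' biomass composition, emulating a rarefied mock-community library.
#'
#' @param biomass_proportions named nonnegative vector summing to 1.
#' @param bias_factors positive per-family multipliers (same names).
#' @param depth total rarefied read count (the study's homogenates were
#'   rarefied to 9,450 reads).
#' @param seed integer seed.
#' @return data.frame with `family`, `biomass_pct`, `sequence_count`,
#'   `sequence_pct`.
#' @export
simulate_mock_homogenate <- function(biomass_proportions, bias_factors,
                                     depth = 9450, seed = 1) {
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  assert_simplex(biomass_proportions, "biomass_proportions")
  if (length(bias_factors) != length(biomass_proportions) || any(bias_factors <= 0)) {
    stop("`bias_factors` must be positive and match `biomass_proportions`",
         call. = FALSE)
  }
  if (!is.null(names(bias_factors)) && !is.null(names(biomass_proportions))) {
    bias_factors <- bias_factors[names(biomass_proportions)]
  }
  set.seed(substream_seed(seed, "mock"))
  w <- biomass_proportions * bias_factors
  w <- w / sum(w)
  cnt <- as.integer(stats::rmultinom(1, depth, w))
  data.frame(family = names(biomass_proportions) %||%
               sprintf("family_%02d", seq_along(w)),
             biomass_pct = 100 * as.numeric(biomass_proportions),
             sequence_count = cnt,
             sequence_pct = 100 * cnt / depth,
             stringsAsFactors = FALSE)
}

default_drift_families <- function() {
  data.frame(
    family = c("Catostomidae", "Acipenseridae", "Heptageniidae", "Baetidae",
               "Ephemerellidae", "Isonychiidae", "Siphlonuridae",
               "Ephemeridae", "Brachycentridae", "Glossosomatidae",
               "Helicopsychidae"),
    esu = c("Catostomidae", "Acipenseridae", "Other Ephemeroptera", "Baetidae",
            "Ephemerelloidea", "Other Ephemeroptera", "Other Ephemeroptera",
            "Other Ephemeroptera", "Trichoptera", "Trichoptera", "Trichoptera"),
    individual_dry_mass_mg = c(1.193, 8.5, 1.768, 0.366, 1.255, 4.145, 6.829,
                               5.578, 1.458, 6.948, 0.914),
    # mean subsample counts per night, chosen so expected nightly catch
    # biomass matches the magnitudes seen in the motivating drift survey
    drift_mean = c(490, 0.22, 19, 2.7, 5.6, 16.6, 0.37, 0.18, 0.34, 0.58, 6),
    postdrift_mean = c(31.6, 0, 9.9, 13.7, 0.6, 5.5, 0, 0, 6.5, 0, 0),
    subsample_fraction = c(0.05, 1, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                           0.05, 0.05, 0.05),
    pulse = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Drift-family table for a synthetic community
#'
#' Builds a [simulate_drift_survey()] family table over a set of ESUs
#' (one family per ESU): log-spaced nightly mean counts, lognormal-ish
#' individual dry masses, and the first two ESUs designated as pulse
#' taxa whose postdrift means drop to zero (emulating the larval-fish
#' dispersal pulse); non-pulse taxa keep comparable means across
#' periods.
#'
#' @param esus character vector of ESU names to survey.
#' @param seed integer seed.
#' @return data.frame in the format of [default_drift_families()].
#' @export
synthetic_drift_families <- function(esus, seed = 1) {
  stopifnot(length(esus) >= 2)
  set.seed(substream_seed(seed, "drift_families"))
  n <- length(esus)
  drift_mean <- exp(seq(log(400), log(4), length.out = n))
  pulse <- seq_len(n) <= 2
  post_factor <- stats::runif(n, 0.4, 1.2)
  post_factor[pulse] <- 0
  data.frame(family = esus, esu = esus,
             individual_dry_mass_mg = round(exp(stats::rnorm(n, log(2), 0.8)), 3),
             drift_mean = drift_mean,
             postdrift_mean = drift_mean * post_factor,
             subsample_fraction = 0.05,
             pulse = pulse,
             stringsAsFactors = FALSE)
}

#' Simulate a nightly drift-net survey
#'
#' Draws nightly per-family subsample counts from period-specific Poisson
#' means. Designated "pulse" families (larval fishes dispersing during
#' the drift period) have drift-period means at least as large as their
#' postdrift means; sturgeon are counted on site (subsample fraction 1)
#' while other taxa are counted from 5% subsamples of the cod-end
#' contents.
#'
#' @param families data.frame like [default_drift_families()]: columns
#'   `family`, `esu`, `individual_dry_mass_mg`, `drift_mean`,
#'   `postdrift_mean`, `subsample_fraction`, `pulse`.
#' @param n_drift_nights,n_postdrift_nights nights per period (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `drift_survey`: `night`, `period`,
#'   `family`, `esu`, `count`, `individual_dry_mass_mg`,
#'   `subsample_fraction`.
#' @export
simulate_drift_survey <- function(families = default_drift_families(),
                                  n_drift_nights = 5, n_postdrift_nights = 2,
                                  seed = 1) {
  if (n_drift_nights < 1 || n_postdrift_nights < 1) {
    stop("need at least one night per period", call. = FALSE)
  }
  if (any(families$pulse & families$postdrift_mean > families$drift_mean)) {
    stop("pulse families must have drift means >= postdrift means",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "drift"))
  nights <- c(as.character(as.Date("2015-05-23") + c(0, 12:15))[seq_len(min(5, n_drift_nights))],
              if (n_drift_nights > 5)
                as.character(as.Date("2015-06-08") + seq_len(n_drift_nights - 5)))
  pnights <- as.character(as.Date("2015-07-03") + 2 * (seq_len(n_postdrift_nights) - 1))
  all_nights <- c(nights, pnights)
  period <- c(rep("drift", n_drift_nights), rep("postdrift", n_postdrift_nights))

  out <- do.call(rbind, lapply(seq_along(all_nights), function(i) {
    mu <- if (period[i] == "drift") families$drift_mean else families$postdrift_mean
    data.frame(night = all_nights[i], period = period[i],
               family = families$family, esu = families$esu,
               count = stats::rpois(nrow(families), mu),
               individual_dry_mass_mg = families$individual_dry_mass_mg,
               subsample_fraction = families$subsample_fraction,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("drift_survey", "data.frame")
  out
}

#' Write a complete synthetic run to disk
#'
#' Writes the reference FASTA, taxonomy, sample count table, sample
#' metadata, truth records, and drift survey as plain-text files under
#' `dir`, plus a `manifest.json` recording the configuration and seed.
#'
#' @param config a [community_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
write_synthetic_run <- function(config, dir) {
  stopifnot(inherits(config, "community_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refdb <- generate_reference_db(config)
  diet <- simulate_diet_samples(config, refdb)
  drift <- simulate_drift_survey(
    synthetic_drift_families(refdb$esus$esu[refdb$esus$is_bilaterian],
                             config$seed),
    seed = config$seed)

  write_fasta(refdb$sequences, file.path(dir, "reference.fasta"))
  utils::write.table(merge(refdb$refs, refdb$esus, by = "esu")[,
    c("ref_id", "esu", "family", "is_bilaterian", "self_of_species")],
    file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(diet$counts),
                                diet$counts, check.names = FALSE),
                     file.path(dir, "sample_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(diet$metadata, file.path(dir, "sample_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(diet$truth), diet$truth,
                                check.names = FALSE),
                     file.path(dir, "truth_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(drift, file.path(dir, "drift_survey.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(config = unclass(config),
                            generated = c("reference.fasta", "taxonomy.tsv",
                                          "sample_counts.tsv",
                                          "sample_metadata.tsv",
                                          "truth_proportions.tsv",
                                          "drift_survey.tsv")),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(refdb = refdb, diet = diet, drift = drift))
}

# FASTA I/O goes through Biostrings when available (the standard route);
# the fallback writes the same two-line records.
write_fasta <- function(seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  invisible(path)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    ids <- sub("^>", "", lines[idx])
    ends <- c(idx[-1] - 1L, length(lines))
    stats::setNames(vapply(seq_along(idx), function(i) {
      paste(lines[(idx[i] + 1L):ends[i]], collapse = "")
    }, character(1)), ids)
  }
}
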