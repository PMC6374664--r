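#' Quality-screen trimmed marker sequences
#'
#' Applies the three post-trim screening rules used for 18S V9 amplicon
#' data: drop sequences longer than the post-trim target size, sequences
#' containing any single-base run at least `homopolymer_min` long, and
#' (optionally) sequences whose dataset-wide abundance is exactly one.
#'
#' @param sequences character vector of unique sequences (may be named).
#' @param abundances dataset-wide counts per sequence (default all 1;
#'   with all-1 abundances and `drop_singletons = TRUE` everything would
#'   be a singleton, so pass real totals when screening a study).
#' @param max_trimmed_length maximum retained length in bp (175).
#' @param homopolymer_min minimum homopolymer run length that triggers
#'   removal (8).
#' @param drop_singletons drop sequences seen exactly once dataset-wide.
#' @return list with `retained` (logical vector aligned to input),
#'   `rejected` (data.frame `sequence`, `rule`), and `counts_per_rule`
#'   (named integer vector `too_long`, `homopolymer`, `singleton`).
#'   A sequence failing several rules is counted once, in the order
#'   length, homopolymer, singleton.
#' @export
filter_sequences <- function(sequences, abundances = NULL,
                             max_trimmed_length = 175,
                             homopolymer_min = 8,
                             drop_singletons = TRUE) {
  if (length(sequences) == 0) {
    return(list(retained = logical(0),
                rejected = data.frame(sequence = character(0),
                                      rule = character(0)),
                counts_per_rule = c(too_long = 0L, homopolymer = 0L,
                                    singleton = 0L)))
  }
  abundances <- abundances %||% rep(1L, length(sequences))
  stopifnot(length(abundances) == length(sequences))

  rule <- rep(NA_character_, length(sequences))
  rule[nchar(sequences) > max_trimmed_length] <- "too_long"
  homo <- is.na(rule) & has_homopolymer(sequences, homopolymer_min)
  rule[homo] <- "homopolymer"
  if (drop_singletons) {
    rule[is.na(rule) & abundances == 1] <- "singleton"
  }
  retained <- is.na(rule)
  rejected <- data.frame(sequence = sequences[!retained],
                         rule = rule[!retained],
                         stringsAsFactors = FALSE)
  list(retained = retained,
       rejected = rejected,
       counts_per_rule = c(too_long = sum(rule == "too_long", na.rm = TRUE),
                           homopolymer = sum(rule == "homopolymer", na.rm = TRUE),
                           singleton = sum(rule == "singleton", na.rm = TRUE)))
}

#' Cluster sequences into OTUs by greedy centroid clustering
#'
#' Iterates sequences in order of decreasing dataset-wide abundance (ties
#' broken lexicographically by sequence) and joins each to the first
#' existing OTU centroid within `max_diff` edits (Levenshtein distance);
#' otherwise the sequence founds a new OTU with itself as centroid. The
#' assignment is fully deterministic.
#'
#' @param sequences character vector of unique, quality-screened
#'   sequences.
#' @param abundances dataset-wide counts per sequence (default all 1).
#' @param max_diff maximum edit distance to a centroid (2).
#' @return data.frame with `sequence`, `abundance`, `otu` (e.g.
#'   "OTU_001"), and `is_centroid`; OTU ids are numbered in centroid
#'   founding order.
#' @export
cluster_otus <- function(sequences, abundances = NULL, max_diff = 2) {
  abundances <- abundances %||% rep(1L, length(sequences))
  stopifnot(length(abundances) == length(sequences))
  if (length(sequences) == 0) {
    return(data.frame(sequence = character(0), abundance = integer(0),
                      otu = character(0), is_centroid = logical(0)))
  }
  ord <- order(-abundances, sequences)
  centroids <- character(0)
  assign <- integer(length(sequences))
  for (i in ord) {
    hit <- 0L
    if (length(centroids) > 0) {
      d <- utils::adist(sequences[i], centroids)[1, ]
      ok <- which(d <= max_diff)
      if (length(ok) > 0) hit <- ok[1]
    }
    if (hit == 0L) {
      centroids <- c(centroids, sequences[i])
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  data.frame(sequence = sequences,
             abundance = abundances,
             otu = sprintf("OTU_%03d", assign),
             is_centroid = sequences %in% centroids,
             stringsAsFactors = FALSE)
}

#' Assign OTU representatives to ESUs by reference identity
#'
#' Each OTU representative is compared to every reference sequence by
#' global edit distance; identity is 1 minus distance over the longer of
#' the two lengths. The OTU takes the ESU of its best-identity reference
#' when that identity is at least `min_identity`; otherwise it is left
#' unassigned. With `require_full_coverage`, references shorter than the
#' OTU are not eligible (the full OTU length must be covered by the
#' alignment). Identity ties go to the ESU with the larger total
#' reference weight, then lexicographically.
#'
#' @param otu_sequences named character vector (names = OTU ids) of
#'   representative (centroid) sequences.
#' @param reference_db a `reference_db` (see [generate_reference_db()] or
#'   [read_reference_db()]).
#' @param min_identity minimum identity for assignment (0.95).
#' @param require_full_coverage require reference length >= OTU length.
#' @param ref_weights optional named abundance weights per `ref_id` used
#'   for tie-breaking.
#' @return data.frame with `otu`, `esu` (NA when unassigned), `identity`,
#'   and `is_prey` (assigned to a bilaterian ESU).
#' @export
assign_esu <- function(otu_sequences, reference_db, min_identity = 0.95,
                       require_full_coverage = TRUE, ref_weights = NULL) {
  stopifnot(length(reference_db$sequences) > 0)
  refs <- reference_db$sequences
  ref_esu <- stats::setNames(reference_db$refs$esu, reference_db$refs$ref_id)
  w <- ref_weights %||% stats::setNames(rep(1, length(refs)), names(refs))

  out <- data.frame(otu = names(otu_sequences) %||%
                      sprintf("OTU_%03d", seq_along(otu_sequences)),
                    esu = NA_character_, identity = NA_real_,
                    is_prey = FALSE, stringsAsFactors = FALSE)
  if (length(otu_sequences) == 0) return(out)

  d <- utils::adist(otu_sequences, refs)
  len_o <- nchar(otu_sequences)
  len_r <- nchar(refs)
  for (i in seq_along(otu_sequences)) {
    eligible <- if (require_full_coverage) len_r >= len_o[i] else rep(TRUE, length(refs))
    if (!any(eligible)) next
    ident <- 1 - d[i, ] / pmax(len_o[i], len_r)
    ident[!eligible] <- -Inf
    best <- max(ident)
    if (best < min_identity) next
    cand <- which(ident >= best - 1e-12)
    if (length(cand) > 1) {
      esu_w <- tapply(w[names(refs)[cand]], ref_esu[names(refs)[cand]], sum)
      esu_pick <- names(esu_w)[order(-esu_w, names(esu_w))][1]
    } else {
      esu_pick <- ref_esu[names(refs)[cand]]
    }
    out$esu[i] <- unname(esu_pick)
    out$identity[i] <- best
  }
  bil <- stats::setNames(reference_db$esus$is_bilaterian, reference_db$esus$esu)
  out$is_prey <- !is.na(out$esu) & bil[out$esu]
  out$is_prey[is.na(out$is_prey)] <- FALSE
  out
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are discarded and logged, mirroring the discard rule for
#' samples with insufficient sequence numbers.
#'
#' @param counts integer matrix (samples x features) or a single count
#'   vector.
#' @param depth target depth in reads (1950 for GI samples).
#' @param seed integer seed; the subsampling is reproducible for a fixed
#'   seed and input ordering.
#' @return list with `counts` (rarefied matrix of retained samples) and
#'   `discarded` (data.frame `sample_id`, `total`, `reason` = "LOW_DEPTH").
#' @export
rarefy <- function(counts, depth = 1950, seed = 1) {
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1,
                     dimnames = list("sample_1", names(counts)))
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  set.seed(substream_seed(seed, "rarefy"))
  totals <- rowSums(counts)
  keep <- totals >= depth
  ids <- rownames(counts) %||% sprintf("sample_%d", seq_len(nrow(counts)))
  out <- matrix(0L, nrow = sum(keep), ncol = ncol(counts),
                dimnames = list(ids[keep], colnames(counts)))
  j <- 0L
  for (i in which(keep)) {
    j <- j + 1L
    out[j, ] <- if (totals[i] == depth) as.integer(counts[i, ])
                else as.integer(rmvhyper(counts[i, ], depth))
  }
  list(counts = out,
       discarded = data.frame(sample_id = ids[!keep],
                              total = unname(totals[!keep]),
                              reason = rep("LOW_DEPTH", sum(!keep)),
                              stringsAsFactors = FALSE))
}

#' Rarefaction curve for one sample
#'
#' Mean observed feature richness over `reps` random subsamples at each
#' depth; used to check that the chosen rarefaction depth does not
#' artificially reduce the number of observed OTUs.
#'
#' @param sample_counts nonnegative integer count vector for one sample.
#' @param depths ascending vector of subsampling depths.
#' @param reps Monte-Carlo replicates per depth.
#' @param seed integer seed.
#' @return data.frame with `depth` and `mean_richness`.
#' @export
rarefaction_curve <- function(sample_counts, depths, reps = 10, seed = 1) {
  stopifnot(all(diff(depths) >= 0), all(sample_counts >= 0))
  set.seed(substream_seed(seed, "rarefaction_curve"))
  total <- sum(sample_counts)
  mean_rich <- vapply(depths, function(d) {
    if (d > total) return(NA_real_)
    if (d == total) return(sum(sample_counts > 0))
    mean(vapply(seq_len(reps), function(r) {
      sum(rmvhyper(sample_counts, d) > 0)
    }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_richness = mean_rich)
}

#' Aggregate OTU counts to ESU counts
#'
#' Sums OTU columns mapping to the same ESU; unassigned OTUs are dropped
#' and reported.
#'
#' @param otu_counts samples x OTUs integer matrix.
#' @param assignment data.frame from [assign_esu()].
#' @return list with `counts` (samples x ESUs), `esu_info` (assignment
#'   rows used), and `unassigned_otus` (character vector).
#' @export
aggregate_otus_to_esu <- function(otu_counts, assignment) {
  assignment <- assignment[match(colnames(otu_counts), assignment$otu), ]
  keep <- !is.na(assignment$esu)
  esus <- sort(unique(assignment$esu[keep]))
  out <- matrix(0L, nrow = nrow(otu_counts), ncol = length(esus),
                dimnames = list(rownames(otu_counts), esus))
  for (e in esus) {
    cols <- assignment$otu[keep & assignment$esu == e]
    out[, e] <- as.integer(rowSums(otu_counts[, cols, drop = FALSE]))
  }
  list(counts = out,
       esu_info = assignment[keep, ],
       unassigned_otus = assignment$otu[!keep])
}

#' Build the per-sample prey-proportion matrix
#'
#' For each rarefied sample: remove the sampled predator's own ("self")
#' ESUs and all non-bilaterian (non-prey) ESUs, exclude the sample if
#' fewer than `min_prey_reads` prey reads remain (near-empty stomachs),
#' and otherwise convert the remaining prey counts to proportions of all
#' prey reads in the sample.
#'
#' @param esu_counts samples x ESUs integer matrix, all rarefied to a
#'   common depth.
#' @param metadata data.frame with `sample_id` and `species` (plus any
#'   other per-sample columns, carried through).
#' @param taxonomy data.frame with `esu`, `is_bilaterian`,
#'   `self_of_species` (NA for non-predator ESUs). Every species in
#'   `metadata` must appear in `self_of_species`.
#' @param min_prey_reads minimum prey reads to keep a sample (20, i.e.
#'   1% of a 1950-read sample).
#' @return object of class `diet_matrix`: list with `proportions`
#'   (samples x prey ESUs, rows summing to 1), `prey_reads` (per-sample
#'   denominators), `metadata` (retained samples), and `exclusions`
#'   (data.frame `sample_id`, `prey_reads`, `reason` in
#'   `ALL_SELF`/`LOW_PREY`).
#' @export
make_diet_matrix <- function(esu_counts, metadata, taxonomy,
                             min_prey_reads = 20) {
  stopifnot(is.matrix(esu_counts), !is.null(rownames(esu_counts)))
  metadata <- metadata[match(rownames(esu_counts), metadata$sample_id), ]
  if (any(is.na(metadata$sample_id))) {
    stop("every sample in `esu_counts` needs a metadata row", call. = FALSE)
  }
  known <- unique(stats::na.omit(taxonomy$self_of_species))
  missing_sp <- setdiff(unique(metadata$species), known)
  if (length(missing_sp) > 0) {
    stop("no self-ESU entry in taxonomy for predator species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  tax <- taxonomy[match(colnames(esu_counts), taxonomy$esu), ]
  prey_cols <- !is.na(tax$esu) & tax$is_bilaterian

  keep <- logical(nrow(esu_counts))
  reasons <- character(nrow(esu_counts))
  prey_reads <- numeric(nrow(esu_counts))
  prey_mat <- matrix(0, nrow = nrow(esu_counts), ncol = sum(prey_cols),
                     dimnames = list(rownames(esu_counts),
                                     colnames(esu_counts)[prey_cols]))
  for (i in seq_len(nrow(esu_counts))) {
    self_esus <- taxonomy$esu[!is.na(taxonomy$self_of_species) &
                                taxonomy$self_of_species == metadata$species[i]]
    ok_cols <- prey_cols & !(colnames(esu_counts) %in% self_esus)
    x <- esu_counts[i, ok_cols]
    tot <- sum(x)
    prey_reads[i] <- tot
    if (tot == 0) {
      reasons[i] <- "ALL_SELF"
    } else if (tot < min_prey_reads) {
      reasons[i] <- "LOW_PREY"
    } else {
      keep[i] <- TRUE
      prey_mat[i, names(x)] <- x / tot
    }
  }
  # prey ESU columns that are self ESUs for some species stay in the
  # matrix (they are prey for the other predators); rows for the species
  # itself simply carry zero there
  structure(list(
    proportions = prey_mat[keep, , drop = FALSE],
    prey_reads = stats::setNames(prey_reads[keep], rownames(esu_counts)[keep]),
    metadata = metadata[keep, , drop = FALSE],
    exclusions = data.frame(sample_id = rownames(esu_counts)[!keep],
                            prey_reads = prey_reads[!keep],
                            reason = reasons[!keep],
                            stringsAsFactors = FALSE)
  ), class = "diet_matrix")
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("Diet matrix:", nrow(x$proportions), "samples x",
      ncol(x$proportions), "prey ESUs\n")
  cat("Excluded samples:", nrow(x$exclusions))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Run the full sample-processing pipeline on a sequence-level table
#'
#' Chains the fixed processing order: quality filter, greedy OTU
#' clustering, reference assignment, per-sample rarefaction, ESU
#' aggregation, self-read removal and the minimum-prey-reads exclusion,
#' and proportion standardization.
#'
#' @param counts samples x sequences integer matrix (columns named by
#'   feature id).
#' @param sequences named character vector mapping feature id to
#'   sequence.
#' @param metadata per-sample metadata (`sample_id`, `species`, ...).
#' @param reference_db a `reference_db`.
#' @param depth rarefaction depth (1950).
#' @param min_prey_reads minimum prey reads per retained sample (20).
#' @param max_diff OTU clustering radius in edits (2).
#' @param min_identity minimum reference identity (0.95).
#' @param max_trimmed_length,homopolymer_min,drop_singletons quality
#'   screening parameters, see [filter_sequences()].
#' @param seed integer seed for the rarefaction subsampling.
#' @return list of class `processed_samples`: the final `diet_matrix`
#'   plus a `report` of per-stage counts (`filter`, `n_otus`,
#'   `n_unassigned`, `discarded_low_depth`).
#' @export
process_samples <- function(counts, sequences, metadata, reference_db,
                            depth = 1950, min_prey_reads = 20,
                            max_diff = 2, min_identity = 0.95,
                            max_trimmed_length = 175, homopolymer_min = 8,
                            drop_singletons = TRUE, seed = 1) {
  sequences <- sequences[colnames(counts)]
  abund <- colSums(counts)
  flt <- filter_sequences(unname(sequences), abundances = unname(abund),
                          max_trimmed_length = max_trimmed_length,
                          homopolymer_min = homopolymer_min,
                          drop_singletons = drop_singletons)
  keep_feat <- names(sequences)[flt$retained]
  counts <- counts[, keep_feat, drop = FALSE]

  clu <- cluster_otus(unname(sequences[keep_feat]),
                      abundances = unname(abund[keep_feat]),
                      max_diff = max_diff)
  otus <- sort(unique(clu$otu))
  otu_counts <- matrix(0L, nrow = nrow(counts), ncol = length(otus),
                       dimnames = list(rownames(counts), otus))
  for (o in otus) {
    cols <- keep_feat[clu$otu == o]
    otu_counts[, o] <- as.integer(rowSums(counts[, cols, drop = FALSE]))
  }
  reps <- stats::setNames(clu$sequence[clu$is_centroid][
    match(otus, clu$otu[clu$is_centroid])], otus)
  otu_weights <- colSums(otu_counts)

  asg <- assign_esu(reps, reference_db, min_identity = min_identity)

  rar <- rarefy(otu_counts, depth = depth, seed = seed)
  agg <- aggregate_otus_to_esu(rar$counts, asg)
  diet <- make_diet_matrix(agg$counts, metadata, reference_db$esus,
                           min_prey_reads = min_prey_reads)
  lowd <- rar$discarded
  lowd$prey_reads <- NA_real_
  diet$exclusions <- rbind(lowd[, c("sample_id", "prey_reads", "reason")],
                           diet$exclusions[, c("sample_id", "prey_reads",
                                               "reason")])
  structure(list(diet = diet,
                 report = list(filter = flt$counts_per_rule,
                               n_otus = length(otus),
                               n_unassigned = sum(is.na(asg$esu)),
                               discarded_low_depth = nrow(rar$discarded)),
                 assignment = asg),
            class = "processed_samples")
}
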