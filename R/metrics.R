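#' Schoener's index of dietary overlap
#'
#' \deqn{\alpha = 1 - 0.5 \sum_i |p_{xi} - p_{yi}|}
#' for two proportional resource-use vectors on the same prey index;
#' 0 means disjoint diets, 1 identical diets, and values above 0.6 are
#' conventionally read as substantial biologically relevant overlap.
#'
#' @param p_x,p_y proportion vectors on the simplex over the same ESU
#'   index (matched by name when named).
#' @return Schoener's alpha in [0, 1].
#' @export
schoener_alpha <- function(p_x, p_y) {
  al <- align_index(p_x, p_y)
  assert_simplex(al$px, "p_x")
  assert_simplex(al$py, "p_y")
  1 - 0.5 * sum(abs(al$px - al$py))
}

#' Bray-Curtis distance between proportion vectors
#'
#' For vectors on the simplex this is \eqn{0.5 \sum_i |p_{xi} - p_{yi}|},
#' the complement of Schoener's overlap: d = 1 - alpha.
#'
#' @inheritParams schoener_alpha
#' @return distance in [0, 1].
#' @export
bray_curtis <- function(p_x, p_y) {
  1 - schoener_alpha(p_x, p_y)
}

#' Pool diets of one species in one period
#'
#' Sums prey read counts across all qualifying samples (each rarefied to
#' the same depth, so each fish carries near-equal weight) and
#' normalizes to proportions. Alternatively averages the per-fish
#' proportion vectors (`method = "mean"`), for sensitivity analysis.
#'
#' @param diet a `diet_matrix` (see [make_diet_matrix()]).
#' @param species,period values matched against the diet metadata.
#' @param method "sum_counts" (default) or "mean" of per-fish
#'   proportions.
#' @return list of class `pooled_diet`: `species`, `period`, `p` (named
#'   proportion vector), `n_fish`. `NULL` (with a message attribute) is
#'   never returned; zero qualifying samples is an error so empty
#'   species-by-period cells are flagged by the caller.
#' @export
pool_diets <- function(diet, species, period,
                       method = c("sum_counts", "mean")) {
  method <- match.arg(method)
  sel <- diet$metadata$species == species & diet$metadata$period == period
  if (!any(sel)) {
    stop("no qualifying samples for ", species, " in period ", period,
         call. = FALSE)
  }
  props <- diet$proportions[sel, , drop = FALSE]
  if (method == "sum_counts") {
    counts <- props * diet$prey_reads[sel]
    p <- colSums(counts) / sum(counts)
  } else {
    p <- colMeans(props)
  }
  structure(list(species = species, period = period, p = p,
                 n_fish = sum(sel)),
            class = "pooled_diet")
}

#' Pairwise Schoener overlap matrices per period
#'
#' Pools diets by species within each period and computes Schoener's
#' alpha for every species pair present in that period. Pairs with
#' alpha above `threshold` are flagged as substantial overlap.
#'
#' @param diet a `diet_matrix`.
#' @param threshold substantial-overlap flag level (0.6).
#' @param method pooling method, see [pool_diets()].
#' @return object of class `overlap_result`: `alpha` (named list of
#'   symmetric unit-diagonal matrices, one per period), `pairs`
#'   (data.frame `species_a`, `species_b`, one `alpha_<period>` column
#'   per period, `delta` = postdrift - drift when both exist, and
#'   `substantial_<period>` flags), `threshold`.
#' @export
overlap_matrices <- function(diet, threshold = 0.6,
                             method = c("sum_counts", "mean")) {
  method <- match.arg(method)
  periods <- unique(diet$metadata$period)
  alpha <- list()
  for (pd in periods) {
    sp <- sort(unique(diet$metadata$species[diet$metadata$period == pd]))
    m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
    pooled <- lapply(sp, function(s) pool_diets(diet, s, pd, method)$p)
    names(pooled) <- sp
    for (i in seq_along(sp)) {
      m[i, i] <- 1
      if (i < length(sp)) for (j in (i + 1):length(sp)) {
        a <- schoener_alpha(pooled[[i]], pooled[[j]])
        m[i, j] <- m[j, i] <- a
      }
    }
    alpha[[pd]] <- m
  }
  shared <- Reduce(intersect, lapply(alpha, rownames))
  pairs <- NULL
  if (length(shared) >= 2) {
    cmb <- utils::combn(sort(shared), 2)
    pairs <- data.frame(species_a = cmb[1, ], species_b = cmb[2, ],
                        stringsAsFactors = FALSE)
    for (pd in periods) {
      pairs[[paste0("alpha_", pd)]] <- alpha[[pd]][cbind(pairs$species_a,
                                                         pairs$species_b)]
      pairs[[paste0("substantial_", pd)]] <-
        pairs[[paste0("alpha_", pd)]] > threshold
    }
    if (all(c("alpha_drift", "alpha_postdrift") %in% names(pairs))) {
      pairs$delta <- pairs$alpha_postdrift - pairs$alpha_drift
    }
  }
  structure(list(alpha = alpha, pairs = pairs, threshold = threshold),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, digits = 2, ...) {
  for (pd in names(x$alpha)) {
    cat("Schoener's alpha,", pd, "period (", nrow(x$alpha[[pd]]),
        "species ):\n")
    print(round(x$alpha[[pd]], digits))
    cat("\n")
  }
  if (!is.null(x$pairs)) {
    n_sub <- colSums(x$pairs[grep("^substantial_", names(x$pairs))],
                     na.rm = TRUE)
    cat("Pairs above threshold", x$threshold, ":",
        paste(sub("substantial_", "", names(n_sub)), n_sub,
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired sign-flip permutation test for a change in overlap
#'
#' Tests whether dietary overlap differs between two periods. The
#' observed statistic is the mean over species pairs of
#' (postdrift alpha - drift alpha). The null distribution is built by
#' randomly inverting the period assignment of each pair independently
#' (each pair keeps or swaps its two values with probability 1/2 per
#' iteration, i.e. its difference flips sign) and recomputing the mean.
#' The p-value uses the add-one rule
#' p = (1 + #\{|mean_perm| >= |mean_obs|\}) / (n_perm + 1) for the
#' two-sided test.
#'
#' @param alpha_drift,alpha_postdrift aligned numeric vectors of
#'   per-pair overlap values (>= 2 pairs); alternatively pass the
#'   differences directly via `delta`.
#' @param delta optional vector of paired differences
#'   (postdrift - drift); overrides the first two arguments.
#' @param n_perm number of permutation iterations (the study used
#'   99,999).
#' @param seed integer seed.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list of class `sign_flip_test`: `statistic` (observed mean
#'   difference), `p`, `n_pairs`, `n_perm`, `alternative`, `seed`.
#' @export
paired_sign_flip_test <- function(alpha_drift = NULL, alpha_postdrift = NULL,
                                  delta = NULL, n_perm = 99999, seed = 1,
                                  alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(delta)) {
    stopifnot(length(alpha_drift) == length(alpha_postdrift))
    delta <- alpha_postdrift - alpha_drift
  }
  delta <- as.numeric(delta)
  if (length(delta) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  obs <- mean(delta)
  # the flips are i.i.d. across pairs, so sorting the differences first
  # makes a fixed-seed result exactly invariant to pair ordering
  delta <- sort(delta)

  set.seed(substream_seed(seed, "sign_flip"))
  n <- length(delta)
  exceed <- 0L
  done <- 0L
  chunk <- max(1L, min(20000L, n_perm))
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    signs <- matrix(sample(c(-1, 1), b * n, replace = TRUE), nrow = b)
    perm <- as.numeric(signs %*% delta) / n
    exceed <- exceed + switch(alternative,
      two.sided = sum(abs(perm) >= abs(obs) - 1e-15),
      less = sum(perm <= obs + 1e-15),
      greater = sum(perm >= obs - 1e-15))
    done <- done + b
  }
  structure(list(statistic = obs, p = (1 + exceed) / (n_perm + 1),
                 n_pairs = n, n_perm = n_perm,
                 alternative = alternative, seed = seed),
            class = "sign_flip_test")
}

#' @export
print.sign_flip_test <- function(x, ...) {
  cat("Paired sign-flip permutation test (", x$alternative, ")\n", sep = "")
  cat("  mean paired difference:", format(x$statistic, digits = 4), "\n")
  cat("  p =", format(x$p, digits = 3), "over", x$n_perm, "iterations,",
      x$n_pairs, "pairs\n")
  invisible(x)
}

#' Manly's selection index
#'
#' \deqn{\alpha_i = (r_i / n_i) / \sum_j (r_j / n_j)}
#' where r is the diet proportion and n the environmental availability
#' proportion of each prey type. The result sums to 1; 1/m (m prey
#' types) is neutral selection.
#'
#' @param r diet proportion vector on the simplex over the surveyed
#'   ESUs.
#' @param n availability proportions, strictly positive (floor zeros
#'   upstream with [availability_proportions()]).
#' @return named vector of Manly's alpha summing to 1.
#' @export
manly_alpha <- function(r, n) {
  al <- align_index(r, n)
  assert_simplex(al$px, "r")
  if (any(al$py <= 0)) {
    stop("all availability proportions must be positive; apply the ",
         "zero floor upstream", call. = FALSE)
  }
  ratio <- al$px / al$py
  ratio / sum(ratio)
}

#' Chesson's selectivity index
#'
#' Rescales Manly's alpha to [-1, 1]:
#' \deqn{\epsilon_i = (m \alpha_i - 1) / ((m - 2) \alpha_i + 1)}
#' with m prey types; 0 is neutral selection (alpha = 1/m), 1 complete
#' positive and -1 complete negative selection. Strictly increasing in
#' alpha for fixed m.
#'
#' @param alpha_i Manly's alpha values in [0, 1] (vectorized).
#' @param m number of prey types in the environment (>= 2).
#' @return Chesson's epsilon values in [-1, 1].
#' @export
chesson_epsilon <- function(alpha_i, m) {
  if (m < 2) stop("`m` must be >= 2", call. = FALSE)
  if (any(alpha_i < -1e-12 | alpha_i > 1 + 1e-12)) {
    stop("`alpha_i` must lie in [0, 1]", call. = FALSE)
  }
  (m * alpha_i - 1) / ((m - 2) * alpha_i + 1)
}

#' Per species-day prey selectivity against nightly availability
#'
#' For each (species, sampling day): the diet vector r is the mean of
#' that day's per-sample prey proportions restricted to the surveyed
#' ESUs and renormalized; availability n comes from the drift survey of
#' the previous night (fish were electrofished the day after each drift
#' night), floored and normalized by [availability_proportions()];
#' Manly's alpha and Chesson's epsilon follow with m = number of
#' surveyed ESUs.
#'
#' @param diet a `diet_matrix` whose metadata has `species`, `date`, and
#'   `night` (the drift night each sampling day is linked to; defaults
#'   to the day before `date` when absent).
#' @param nightly_biomass data.frame from [aggregate_biomass_to_esu()]
#'   (`night`, `esu`, `biomass_g`).
#' @param surveyed_esus ESUs with availability estimates (the index over
#'   which r is renormalized); default: all ESUs in `nightly_biomass`.
#' @param zero_floor floor for zero availability, see
#'   [availability_proportions()].
#' @return data.frame of class `selectivity_table`: `species`, `date`,
#'   `night`, `esu`, `r_i`, `n_i`, `manly_alpha`, `chesson_epsilon`,
#'   `m`, `n_fish`. Species-days with no surveyed-ESU reads are skipped
#'   and listed in attribute `skipped`.
#' @export
selectivity_by_day <- function(diet, nightly_biomass, surveyed_esus = NULL,
                               zero_floor = 0.001) {
  surveyed_esus <- surveyed_esus %||% sort(unique(nightly_biomass$esu))
  m <- length(surveyed_esus)
  if (m < 2) stop("need at least 2 surveyed ESUs", call. = FALSE)
  meta <- diet$metadata
  if (!"night" %in% names(meta)) {
    meta$night <- as.character(as.Date(meta$date) - 1L)
  }
  avail_night <- function(night) {
    sel <- nightly_biomass$night == night
    if (!any(sel)) stop("no drift survey for night ", night, call. = FALSE)
    b <- stats::setNames(rep(0, m), surveyed_esus)
    hit <- nightly_biomass[sel & nightly_biomass$esu %in% surveyed_esus, ]
    b[hit$esu] <- hit$biomass_g
    availability_proportions(b, zero_floor)
  }

  keys <- unique(meta[, c("species", "date", "night")])
  rows <- list()
  skipped <- character(0)
  for (k in seq_len(nrow(keys))) {
    sel <- meta$species == keys$species[k] & meta$date == keys$date[k]
    props <- diet$proportions[sel, intersect(colnames(diet$proportions),
                                             surveyed_esus), drop = FALSE]
    r_full <- stats::setNames(rep(0, m), surveyed_esus)
    if (ncol(props) > 0) r_full[colnames(props)] <- colMeans(props)
    if (sum(r_full) == 0) {
      skipped <- c(skipped, paste(keys$species[k], keys$date[k]))
      next
    }
    r <- r_full / sum(r_full)
    n <- avail_night(keys$night[k])
    a <- manly_alpha(r, n)
    rows[[length(rows) + 1L]] <- data.frame(
      species = keys$species[k], date = keys$date[k], night = keys$night[k],
      esu = surveyed_esus, r_i = unname(r[surveyed_esus]),
      n_i = unname(n[surveyed_esus]),
      manly_alpha = unname(a[surveyed_esus]),
      chesson_epsilon = unname(chesson_epsilon(a[surveyed_esus], m)),
      m = m, n_fish = sum(sel), stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(species = character(0), date = character(0),
               night = character(0), esu = character(0), r_i = numeric(0),
               n_i = numeric(0), manly_alpha = numeric(0),
               chesson_epsilon = numeric(0), m = integer(0),
               n_fish = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("selectivity_table", "data.frame")
  out
}
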