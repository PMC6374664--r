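test_that("quality screening applies each rule at its boundary", {
  seqs <- c(at_limit = strrep("ACGT", 43) %+% "ACG",     # 175 bp
            over_limit = strrep("ACGT", 44),             # 176 bp
            homop = paste0(strrep("ACGT", 30), strrep("A", 8), "CGT"),
            homop7 = paste0(strrep("ACGT", 30), strrep("A", 7), "CGT"),
            common = strrep("ACGTT", 30),
            lone = strrep("GTCA", 30))
  ab <- c(2, 5, 5, 5, 2, 1)
  res <- filter_sequences(unname(seqs), abundances = ab)
  names(res$retained) <- names(seqs)
  expect_true(res$retained[["at_limit"]])
  expect_false(res$retained[["over_limit"]])
  expect_false(res$retained[["homop"]])
  expect_true(res$retained[["homop7"]])
  expect_true(res$retained[["common"]])   # abundance 2: not a singleton
  expect_false(res$retained[["lone"]])
  expect_identical(unname(res$counts_per_rule),
                   c(1L, 1L, 1L))

  empty <- filter_sequences(character(0))
  expect_identical(sum(empty$counts_per_rule), 0L)
  expect_identical(nrow(empty$rejected), 0L)
})

test_that("greedy clustering joins at <= 2 edits and splits beyond", {
  base <- strrep("ACGT", 30)
  s2 <- seq_with_diffs(base, c(5, 17))
  s3 <- seq_with_diffs(base, c(5, 17, 44))
  cl <- cluster_otus(c(base, base2 = base, s2, s3), abundances = c(5, 5, 3, 2))
  expect_identical(cl$otu[1], cl$otu[2])  # identical sequences share an OTU
  expect_identical(cl$otu[1], cl$otu[3])  # 2 edits: same OTU
  expect_false(cl$otu[1] == cl$otu[4])    # 3 edits: new OTU
})

test_that("clustering recovers planted groups, matching a single-linkage oracle", {
  set.seed(81)
  n_groups <- 8
  seqs <- character(0)
  truth <- integer(0)
  centroids <- character(0)
  for (g in seq_len(n_groups)) {
    repeat {  # group centroids > 5 edits apart
      cand <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                    collapse = "")
      if (length(centroids) == 0 ||
          all(utils::adist(cand, centroids) > 5)) break
    }
    centroids <- c(centroids, cand)
    k <- sample(2:6, 1)
    for (v in seq_len(k)) {
      s <- if (v == 1) cand else seq_with_diffs(cand, sample(120, sample(1:2, 1)))
      seqs <- c(seqs, s)
      truth <- c(truth, g)
    }
  }
  keep <- !duplicated(seqs)
  seqs <- seqs[keep]
  truth <- truth[keep]
  ab <- ifelse(seqs %in% centroids, 50, sample(2:10, length(seqs), replace = TRUE))

  cl <- cluster_otus(seqs, abundances = ab)
  oracle <- single_linkage_oracle(seqs, max_diff = 2)
  same_partition <- function(a, b) {
    identical(outer(a, a, "=="), outer(b, b, "=="))
  }
  expect_true(same_partition(cl$otu, oracle))       # matches the oracle
  expect_true(same_partition(cl$otu, truth))        # recovers planted groups
  expect_identical(length(unique(cl$otu)), as.integer(n_groups))
})

test_that("ESU assignment enforces the 95% identity threshold", {
  base <- strrep("ACGT", 25)  # 100 bp
  ref <- structure(list(
    sequences = c(ESU_A_v1 = base, ESU_B_v1 = strrep("GGCA", 25),
                  Decoy_v1 = strrep("TTGA", 25)),
    refs = data.frame(ref_id = c("ESU_A_v1", "ESU_B_v1", "Decoy_v1"),
                      esu = c("ESU_A", "ESU_B", "Decoy")),
    esus = data.frame(esu = c("ESU_A", "ESU_B", "Decoy"),
                      family = c("ESU_A", "ESU_B", "Decoy"),
                      is_bilaterian = c(TRUE, TRUE, FALSE),
                      self_of_species = c(NA, NA, NA))),
    class = "reference_db")

  # substitutions spaced so the edit distance equals their count
  otus <- c(OTU_001 = base,                                        # exact
            OTU_002 = seq_with_diffs(base, c(3, 17, 31, 59, 83)),  # 0.95
            OTU_003 = seq_with_diffs(base, c(3, 17, 31, 59, 83, 97)), # 0.94
            OTU_004 = strrep("TTGA", 25))                          # decoy
  asg <- assign_esu(otus, ref)
  expect_identical(asg$esu, c("ESU_A", "ESU_A", NA, "Decoy"))
  expect_identical(asg$identity[1], 1)
  expect_equal(asg$identity[2], 0.95)
  expect_identical(asg$is_prey, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("rarefaction discards shallow samples and hits depth exactly", {
  m <- rbind(deep = c(a = 3000, b = 1500, c = 500),
             exact = c(a = 1000, b = 700, c = 250),
             shallow = c(a = 1000, b = 900, c = 49))
  r <- rarefy(m, depth = 1950, seed = 4)
  expect_identical(rownames(r$counts), c("deep", "exact"))
  expect_true(all(rowSums(r$counts) == 1950))
  expect_identical(unname(r$counts["exact", ]), c(1000L, 700L, 250L))
  expect_true(all(r$counts["deep", ] <= m["deep", ]))
  expect_identical(r$discarded$sample_id, "shallow")
  expect_identical(r$discarded$reason, "LOW_DEPTH")

  one <- rarefy(c(only = 5000), depth = 1950, seed = 1)
  expect_identical(unname(one$counts[1, ]), 1950L)

  expect_identical(rarefy(m, depth = 1950, seed = 4)$counts, r$counts)
  expect_error(rarefy(-m, depth = 10), "nonnegative")
})

test_that("rarefied proportions are unbiased across seeds", {
  x <- c(a = 6000, b = 3000, c = 1000)
  props <- t(vapply(1:200, function(s) {
    rarefy(x, depth = 1000, seed = s)$counts[1, ] / 1000
  }, numeric(3)))
  p0 <- x / sum(x)
  se <- sqrt(p0 * (1 - p0) / 1000 / 200)
  expect_true(all(abs(colMeans(props) - p0) < 4 * se + 1e-12))
})

test_that("rarefaction curves match the hypergeometric closed form", {
  cnt <- rep(20L, 100)  # uniform 100-feature sample
  cur <- rarefaction_curve(cnt, depths = c(1, 50, sum(cnt)), reps = 300,
                           seed = 2)
  expect_identical(cur$mean_richness[1], 1)
  expect_identical(cur$mean_richness[3], 100)
  exp50 <- expected_richness(cnt, 50)
  expect_equal(cur$mean_richness[2], exp50, tolerance = 0.02)

  skewed <- c(500L, 10L, 5L, 1L)
  cur2 <- rarefaction_curve(skewed, depths = c(5, 50, 200, 516), reps = 300,
                            seed = 3)
  expect_true(all(diff(cur2$mean_richness) >= -0.2))  # nondecreasing (MC tol)
  expect_identical(cur2$mean_richness[4], 4)
})

test_that("diet matrix removes self reads and applies the prey-read floor", {
  tax <- data.frame(esu = c("Perciformes", "Otomorpha", "Baetidae", "Rotifer"),
                    is_bilaterian = c(TRUE, TRUE, TRUE, FALSE),
                    self_of_species = c("rock_bass", "white_sucker", NA, NA))
  counts <- rbind(
    ok = c(Perciformes = 1900, Otomorpha = 30, Baetidae = 10, Rotifer = 10),
    low = c(Perciformes = 1921, Otomorpha = 9, Baetidae = 10, Rotifer = 10),
    self_only = c(Perciformes = 1950, Otomorpha = 0, Baetidae = 0, Rotifer = 0))
  md <- data.frame(sample_id = rownames(counts),
                   species = c("rock_bass", "rock_bass", "rock_bass"))
  dm <- make_diet_matrix(counts, md, tax, min_prey_reads = 20)

  expect_identical(rownames(dm$proportions), "ok")
  expect_equal(unname(dm$proportions["ok", c("Otomorpha", "Baetidae")]),
               c(0.75, 0.25))
  expect_identical(unname(dm$proportions["ok", "Perciformes"]), 0)
  expect_identical(dm$exclusions$reason[dm$exclusions$sample_id == "low"],
                   "LOW_PREY")
  expect_identical(dm$exclusions$reason[dm$exclusions$sample_id == "self_only"],
                   "ALL_SELF")
  expect_true(all(abs(rowSums(dm$proportions) - 1) < 1e-9))

  # a sample with exactly 19 prey reads is excluded, 20 is kept
  c19 <- rbind(s = c(Perciformes = 1931, Otomorpha = 19, Baetidae = 0,
                     Rotifer = 0))
  c20 <- rbind(s = c(Perciformes = 1930, Otomorpha = 20, Baetidae = 0,
                     Rotifer = 0))
  md1 <- data.frame(sample_id = "s", species = "rock_bass")
  expect_identical(nrow(make_diet_matrix(c19, md1, tax)$proportions), 0L)
  expect_identical(nrow(make_diet_matrix(c20, md1, tax)$proportions), 1L)

  expect_error(make_diet_matrix(counts,
                                transform(md, species = "burbot"), tax),
               "burbot")
})

test_that("the full processing chain recovers bias-distorted true diets", {
  cfg <- community_config(n_predator_species = 2, n_esus = 8,
                          n_decoy_esus = 1, n_samples_per_species_period = 4,
                          n_shallow = 1, n_empty = 1, seed = 12)
  r <- generate_reference_db(cfg)
  s <- simulate_diet_samples(cfg, r)
  pr <- process_samples(s$counts, s$sequences, s$metadata, r, seed = 12)

  # every planted junk class is caught
  expect_true(all(pr$report$filter >= 1))
  expect_identical(pr$report$discarded_low_depth, 1L)
  expect_true("LOW_PREY" %in% pr$diet$exclusions$reason)
  expect_true(all(abs(rowSums(pr$diet$proportions) - 1) < 1e-9))

  # retained per-sample proportions track normalize(truth x bias)
  bias <- stats::setNames(cfg$bias_factors, r$esus$esu)
  kept <- rownames(pr$diet$proportions)
  errs <- vapply(kept, function(id) {
    sp <- s$metadata$species[s$metadata$sample_id == id]
    self <- r$esus$esu[!is.na(r$esus$self_of_species) &
                         r$esus$self_of_species == sp]
    tru <- s$truth[id, ]
    expd <- tru * bias[names(tru)]
    expd[self] <- 0
    expd <- expd[colnames(pr$diet$proportions)]
    expd <- expd / sum(expd)
    sum(abs(pr$diet$proportions[id, ] - expd))
  }, numeric(1))
  expect_lt(mean(errs), 0.15)  # ~1000 prey reads per sample
})
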