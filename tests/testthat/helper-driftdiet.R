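# Shared fixtures and independent oracles for the test suite.

small_config <- function(seed = 42, ...) {
  community_config(n_predator_species = 2, n_esus = 8, n_decoy_esus = 1,
                   n_samples_per_species_period = 3, n_shallow = 1,
                   n_empty = 1, seed = seed, ...)
}

# Random simplex vector (uniform via exponential spacings).
random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Independent single-linkage clustering oracle: connected components of
# the graph joining sequences at edit distance <= max_diff, found by
# exhaustive BFS on the full distance matrix.
single_linkage_oracle <- function(sequences, max_diff = 2) {
  n <- length(sequences)
  d <- utils::adist(sequences)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(d[v, ] <= max_diff & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Exact sign-flip null: enumerate all 2^n sign assignments.
exact_sign_flip_p <- function(delta, alternative = "two.sided") {
  n <- length(delta)
  obs <- mean(delta)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- as.numeric(signs %*% delta) / n
  switch(alternative,
         two.sided = mean(abs(perm) >= abs(obs) - 1e-15),
         less = mean(perm <= obs + 1e-15),
         greater = mean(perm >= obs - 1e-15))
}

# Closed-form expected richness of a hypergeometric subsample of size d.
expected_richness <- function(counts, d) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}

# Sequences built from blocks, guaranteeing controlled edit distances.
seq_with_diffs <- function(base, positions, to = "A") {
  chars <- strsplit(base, "")[[1]]
  for (p in positions) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[
      if (to == "A") 1 else 2]
  }
  paste(chars, collapse = "")
}

# Minimal diet_matrix built directly from a proportion matrix (rows on
# the simplex) for metric-level tests.
manual_diet_matrix <- function(props, species, period, prey_reads = NULL,
                               date = NULL, night = NULL) {
  if (is.null(rownames(props))) {
    rownames(props) <- sprintf("S%03d", seq_len(nrow(props)))
  }
  md <- data.frame(sample_id = rownames(props), species = species,
                   period = period, stringsAsFactors = FALSE)
  if (!is.null(date)) md$date <- date
  if (!is.null(night)) md$night <- night
  structure(list(proportions = props,
                 prey_reads = stats::setNames(prey_reads %||%
                                                rep(1950, nrow(props)),
                                              rownames(props)),
                 metadata = md,
                 exclusions = data.frame(sample_id = character(0),
                                         prey_reads = numeric(0),
                                         reason = character(0))),
            class = "diet_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%+%` <- function(a, b) paste0(a, b)
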