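#' Relative correction factors from a mock-community mixture
#'
#' For each family t in a mock homogenate of known composition, the
#' relative correction factor is the odds ratio of sequence
#' representation to biomass representation,
#' \deqn{RCF_t = (S_t / S_m) \times (B_m / B_t)}
#' where \eqn{S_t} and \eqn{B_t} are the family's sequence and biomass
#' proportions and \eqn{S_m = 1 - S_t}, \eqn{B_m = 1 - B_t} are the
#' proportions of all other families. RCF > 1 means the family is
#' overrepresented by sequence abundance (amplification bias in its
#' favour); RCF < 1 means under-representation.
#'
#' A family with zero biomass but positive sequence proportion has an
#' undefined RCF and is returned as `NA` with `undefined = TRUE`.
#'
#' @param mixture data.frame with columns `family`, `biomass_pct`,
#'   `sequence_pct` (percent scale, as such tables are printed), or
#'   proportions if `percent = FALSE`.
#' @param percent are the columns on the 0-100 scale?
#' @return data.frame of class `rcf_table`: `family`, `biomass_pct`,
#'   `sequence_pct`, `rcf`, `overrepresented`, `undefined`.
#' @export
compute_rcf <- function(mixture, percent = TRUE) {
  req <- c("family", "biomass_pct", "sequence_pct")
  if (!all(req %in% names(mixture))) {
    stop("`mixture` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  scale <- if (percent) 100 else 1
  B <- mixture$biomass_pct / scale
  S <- mixture$sequence_pct / scale
  if (any(B < 0 | B > 1 | S < 0 | S > 1)) {
    stop("biomass and sequence proportions must lie in [0, 1] ",
         "(check the `percent` flag)", call. = FALSE)
  }
  undefined <- (B == 0 & S > 0) | B == 1 | S == 1
  rcf <- ifelse(undefined, NA_real_, (S / (1 - S)) * ((1 - B) / B))
  out <- data.frame(family = mixture$family,
                    biomass_pct = B * 100,
                    sequence_pct = S * 100,
                    rcf = rcf,
                    overrepresented = !undefined & S > B,
                    undefined = undefined,
                    stringsAsFactors = FALSE)
  class(out) <- c("rcf_table", "data.frame")
  out
}

#' @export
print.rcf_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$rcf <- round(y$rcf, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Average RCFs over replicate mock mixtures
#'
#' Computes an RCF table per replicate and averages per family. The
#' arithmetic mean is the default (matching how mean percentages are
#' usually reported); a geometric mean is available since RCFs are odds
#' ratios.
#'
#' @param mixtures data.frame with `replicate`, `family`, `biomass_pct`,
#'   `sequence_pct`.
#' @param average "arithmetic" or "geometric".
#' @param percent see [compute_rcf()].
#' @return an `rcf_table` with per-family mean percentages and mean RCF.
#' @export
rcf_from_replicates <- function(mixtures, average = c("arithmetic", "geometric"),
                                percent = TRUE) {
  average <- match.arg(average)
  stopifnot("replicate" %in% names(mixtures))
  per_rep <- lapply(split(mixtures, mixtures$replicate), compute_rcf,
                    percent = percent)
  all <- do.call(rbind, per_rep)
  agg <- function(v) if (average == "arithmetic") mean(v) else exp(mean(log(v)))
  fams <- unique(all$family)
  out <- data.frame(
    family = fams,
    biomass_pct = vapply(fams, function(f) mean(all$biomass_pct[all$family == f]),
                         numeric(1)),
    sequence_pct = vapply(fams, function(f) mean(all$sequence_pct[all$family == f]),
                          numeric(1)),
    rcf = vapply(fams, function(f) agg(all$rcf[all$family == f]), numeric(1)),
    stringsAsFactors = FALSE)
  out$overrepresented <- out$rcf > 1
  out$undefined <- is.na(out$rcf)
  rownames(out) <- NULL
  class(out) <- c("rcf_table", "data.frame")
  out
}

#' Merge sequence-indistinguishable families before RCF computation
#'
#' Some families cannot be told apart at the marker (for 18S V9 e.g.
#' several mayfly families); their biomass and sequence percentages are
#' summed into one merged row.
#'
#' @param mixture data.frame with `family`, `biomass_pct`,
#'   `sequence_pct` (and optionally other columns, dropped).
#' @param merge_map named list: merged-name -> character vector of member
#'   families.
#' @return data.frame with merged rows appended in place of members.
#' @export
merge_families <- function(mixture, merge_map) {
  out <- mixture[, c("family", "biomass_pct", "sequence_pct")]
  for (nm in names(merge_map)) {
    members <- merge_map[[nm]]
    sel <- out$family %in% members
    if (!any(sel)) next
    merged <- data.frame(family = nm,
                         biomass_pct = sum(out$biomass_pct[sel]),
                         sequence_pct = sum(out$sequence_pct[sel]),
                         stringsAsFactors = FALSE)
    out <- rbind(out[!sel, ], merged)
  }
  rownames(out) <- NULL
  out
}

#' Correlation between biomass and sequence representation
#'
#' Pearson correlation of paired (biomass %, sequence %) values across
#' families and replicates of mock mixtures; the standard check that
#' read abundance tracks biomass at all despite amplification bias.
#'
#' @param mixtures data.frame with `biomass_pct` and `sequence_pct`
#'   (one row per family x replicate; needs >= 3 rows).
#' @return list with `r`, `r_squared`, `p`, `n`, and `undefined` (TRUE
#'   when either variable has zero variance).
#' @export
biomass_sequence_correlation <- function(mixtures) {
  x <- mixtures$biomass_pct
  y <- mixtures$sequence_pct
  if (length(x) < 3) stop("need at least 3 (family, replicate) pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(x), undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x), undefined = FALSE)
}

#' Correct diet proportions by relative correction factors
#'
#' Optional bias correction: each proportion is divided by its ESU's RCF
#' and the vector renormalized to the simplex. ESUs without an RCF use
#' 1 (no correction).
#'
#' @param proportions named proportion vector or samples x ESUs matrix
#'   (rows on the simplex).
#' @param rcf named RCF vector or an `rcf_table` (names/`family` matched
#'   against proportion names).
#' @return corrected proportions, same shape as the input.
#' @export
apply_rcf <- function(proportions, rcf) {
  if (inherits(rcf, "rcf_table") || is.data.frame(rcf)) {
    rcf <- stats::setNames(rcf$rcf, rcf$family)
  }
  rcf <- rcf[!is.na(rcf)]
  if (any(rcf <= 0)) stop("RCF values must be positive", call. = FALSE)
  fix_row <- function(p) {
    f <- rep(1, length(p))
    names(f) <- names(p)
    hit <- intersect(names(p), names(rcf))
    f[hit] <- rcf[hit]
    q <- p / f
    q / sum(q)
  }
  if (is.matrix(proportions)) {
    out <- t(apply(proportions, 1, fix_row))
    dimnames(out) <- dimnames(proportions)
    out
  } else {
    fix_row(proportions)
  }
}
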