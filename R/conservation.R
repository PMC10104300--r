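# Per-site entropy, conserved-site reports, and Kullback-Leibler divergence
# between subfamily groups over a shared projected alignment.
#
# Entropy is Shannon entropy with a base-20 logarithm, so S = 0 for a fully
# conserved site and S = 1 for a site uniform over the 20 amino-acid types.
# Gaps and ambiguity codes (B, Z, X, U, O, J) are missing data: they enter
# neither the frequency numerator nor its denominator, but do count against
# the non-gap fraction. KL divergence uses the natural logarithm on
# pseudocount-smoothed frequencies; the two bases are deliberately not
# harmonised.

#' Amino-acid frequency distribution at one alignment site
#'
#' @param proj A \code{proj_aln} from \code{\link{project_to_reference}}.
#' @param site_number 1-based reference site number.
#' @param rows Optional row subset: vector of row ids, or a single group
#'   label present in \code{proj$row_groups}.
#' @return A \code{site_dist}: list with \code{site_number}, \code{counts}
#'   (named length-20 integer vector), \code{freqs} (sums to 1 when any
#'   residue observed), \code{n_observed}, \code{n_rows} and
#'   \code{nongap_fraction}.
#' @export
column_frequencies <- function(proj, site_number, rows = NULL) {
  stopifnot(inherits(proj, "proj_aln"))
  idx <- match(site_number, proj$site_numbers)
  if (is.na(idx)) stop("site ", site_number, " not present in projection")
  ids <- resolve_rows(proj, rows)
  if (length(ids) == 0) stop("empty row subset")
  col <- proj$ali[ids, idx]
  counts <- table(factor(col, levels = AA20))
  counts <- stats::setNames(as.integer(counts), AA20)
  n_obs <- sum(counts)
  freqs <- if (n_obs > 0) counts / n_obs else stats::setNames(rep(NA_real_, 20), AA20)
  structure(list(site_number = site_number,
                 counts = counts,
                 freqs = freqs,
                 n_observed = n_obs,
                 n_rows = length(ids),
                 nongap_fraction = n_obs / length(ids)),
            class = "site_dist")
}

#' Base-20 Shannon entropy of a site distribution
#'
#' S = -sum_j p_j log20 p_j over the 20 amino-acid types, with 0 log 0 := 0.
#' Ranges from 0 (single residue type) to 1 (uniform over all 20).
#'
#' @param dist A \code{site_dist}, or a numeric frequency vector summing to 1.
#' @return Entropy in [0, 1]; \code{NA} if no residues were observed.
#' @export
site_entropy <- function(dist) {
  p <- if (inherits(dist, "site_dist")) {
    if (dist$n_observed == 0) return(NA_real_)
    dist$freqs
  } else {
    as.numeric(dist)
  }
  p <- p[!is.na(p) & p > 0]
  if (length(p) == 0) return(NA_real_)
  -sum(p * log(p, base = 20)) + 0  # + 0 normalises IEEE negative zero
}

#' Per-site conservation profile
#'
#' Applies \code{\link{site_entropy}} across all projected sites for a row
#' subset. The consensus residue is the most frequent amino acid; ties are
#' broken alphabetically by one-letter code.
#'
#' @inheritParams column_frequencies
#' @return Data frame of class \code{conservation_profile} with columns
#'   \code{site}, \code{entropy}, \code{nongap_fraction}, \code{consensus},
#'   \code{n_observed}. Sites with no observed residues have \code{NA}
#'   entropy and consensus (undefined, not zero).
#' @export
entropy_profile <- function(proj, rows = NULL) {
  stopifnot(inherits(proj, "proj_aln"))
  ids <- resolve_rows(proj, rows)
  if (length(ids) == 0) stop("empty row subset")
  sub <- proj$ali[ids, , drop = FALSE]
  n <- length(ids)
  res <- lapply(seq_along(proj$site_numbers), function(i) {
    counts <- table(factor(sub[, i], levels = AA20))
    counts <- as.integer(counts)
    n_obs <- sum(counts)
    if (n_obs == 0) {
      list(S = NA_real_, frac = 0, cons = NA_character_, n_obs = 0L)
    } else {
      p <- counts / n_obs
      cons <- AA20[which.max(counts)]  # which.max takes first => alphabetical tie-break
      pp <- p[p > 0]
      list(S = -sum(pp * log(pp, base = 20)), frac = n_obs / n,
           cons = cons, n_obs = n_obs)
    }
  })
  out <- data.frame(site = proj$site_numbers,
                    entropy = vapply(res, `[[`, numeric(1), "S"),
                    nongap_fraction = vapply(res, `[[`, numeric(1), "frac"),
                    consensus = vapply(res, `[[`, character(1), "cons"),
                    n_observed = vapply(res, function(r) as.integer(r$n_obs), integer(1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Filter a conservation profile to conserved sites
#'
#' Keeps sites with entropy <= \code{s_max} and non-gap fraction >
#' \code{frac_min}, sorted by site number — the report format used for
#' highly conserved sites (defaults: S <= 0.1, fraction > 0.7).
#'
#' @param profile A \code{conservation_profile}.
#' @param s_max Entropy ceiling, in (0, 1].
#' @param frac_min Non-gap fraction floor (exclusive), in [0, 1).
#' @return Data frame with columns \code{residue}, \code{entropy},
#'   \code{frac}, \code{amino_acid}.
#' @export
conserved_sites <- function(profile, s_max = 0.1, frac_min = 0.7) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (s_max <= 0 || s_max > 1) stop("s_max must be in (0, 1]")
  if (frac_min < 0 || frac_min >= 1) stop("frac_min must be in [0, 1)")
  keep <- !is.na(profile$entropy) & profile$entropy <= s_max &
    profile$nongap_fraction > frac_min
  out <- profile[keep, , drop = FALSE]
  out <- out[order(out$site), ]
  data.frame(residue = out$site,
             entropy = out$entropy,
             frac = out$nongap_fraction,
             amino_acid = out$consensus,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Smooth counts with an additive pseudocount and renormalise.
smooth_freqs <- function(counts, pseudocount) {
  tot <- sum(counts) + 20 * pseudocount
  (counts + pseudocount) / tot
}

#' Kullback-Leibler divergence between two site distributions
#'
#' D = sum_j p_j ln(p_j / q_j) over the 20 amino-acid types, computed on
#' pseudocount-smoothed frequencies (add \code{pseudocount} to each of the
#' 20 counts, renormalise). Terms with p_j = 0 contribute 0. With
#' \code{pseudocount = 0} the value is finite only when the support of p is
#' contained in the support of q.
#'
#' @param p,q \code{site_dist} objects (p is the reference distribution).
#' @param pseudocount Non-negative additive count (default 0.5, Jeffreys-style).
#' @return Divergence >= 0 (Gibbs' inequality); \code{NA} if either
#'   distribution has no observed residues.
#' @export
kl_divergence <- function(p, q, pseudocount = 0.5) {
  stopifnot(inherits(p, "site_dist"), inherits(q, "site_dist"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (p$n_observed == 0 || q$n_observed == 0) return(NA_real_)
  ps <- smooth_freqs(p$counts, pseudocount)
  qs <- smooth_freqs(q$counts, pseudocount)
  nz <- ps > 0
  sum(ps[nz] * log(ps[nz] / qs[nz]))
}

#' Bidirectional per-site divergence profile between two groups
#'
#' For each projected site, computes the KL divergence in both directions
#' (kl_1 with group 1 as reference distribution, kl_2 with group 2), the
#' within-group base-20 entropies (s_1, s_2) and modal residues. Sites are
#' ranked by max(kl_1, kl_2) descending, which surfaces positions conserved
#' in at least one subfamily but different in the other.
#'
#' @param proj A \code{proj_aln}.
#' @param group_1,group_2 Disjoint row subsets (id vectors or group labels).
#' @param pseudocount Smoothing pseudocount passed to \code{\link{kl_divergence}}.
#' @param s_conserved Entropy threshold used for the conserved-and-divergent
#'   flag (default 0.2).
#' @return Data frame of class \code{divergence_profile} with columns
#'   \code{site}, \code{kl_1}, \code{kl_2}, \code{s_1}, \code{s_2},
#'   \code{modal_1}, \code{modal_2}, \code{frac_1}, \code{frac_2},
#'   \code{conserved_divergent}, sorted by \code{pmax(kl_1, kl_2)} descending.
#' @export
divergence_profile <- function(proj, group_1, group_2, pseudocount = 0.5,
                               s_conserved = 0.2) {
  stopifnot(inherits(proj, "proj_aln"))
  ids1 <- resolve_rows(proj, group_1)
  ids2 <- resolve_rows(proj, group_2)
  if (length(ids1) == 0 || length(ids2) == 0) stop("both groups must be non-empty")
  if (length(intersect(ids1, ids2)) > 0) stop("groups must be disjoint")

  prof1 <- entropy_profile(proj, ids1)
  prof2 <- entropy_profile(proj, ids2)
  n_sites <- length(proj$site_numbers)
  kl1 <- kl2 <- rep(NA_real_, n_sites)
  for (i in seq_len(n_sites)) {
    d1 <- column_frequencies(proj, proj$site_numbers[i], ids1)
    d2 <- column_frequencies(proj, proj$site_numbers[i], ids2)
    kl1[i] <- kl_divergence(d1, d2, pseudocount)
    kl2[i] <- kl_divergence(d2, d1, pseudocount)
  }
  out <- data.frame(site = proj$site_numbers,
                    kl_1 = kl1, kl_2 = kl2,
                    s_1 = prof1$entropy, s_2 = prof2$entropy,
                    modal_1 = prof1$consensus, modal_2 = prof2$consensus,
                    frac_1 = prof1$nongap_fraction, frac_2 = prof2$nongap_fraction,
                    stringsAsFactors = FALSE)
  out$conserved_divergent <-
    !is.na(out$s_1) & !is.na(out$s_2) &
    (out$s_1 < s_conserved | out$s_2 < s_conserved) &
    out$modal_1 != out$modal_2
  ord <- order(-pmax(out$kl_1, out$kl_2, na.rm = FALSE), out$site)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("divergence_profile", "data.frame")
  out
}

#' Write a conserved-site table as TSV
#'
#' Columns: residue, entropy, frac, amino acid.
#'
#' @param tab Output of \code{\link{conserved_sites}}.
#' @param path Output path.
#' @param digits Decimal places for numeric columns.
#' @return \code{path}, invisibly.
#' @export
write_conserved_tsv <- function(tab, path, digits = 2) {
  out <- data.frame(residue = tab$residue,
                    entropy = formatC(tab$entropy, format = "f", digits = digits),
                    frac = formatC(tab$frac, format = "f", digits = digits),
                    `amino acid` = tab$amino_acid,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a divergence profile as TSV
#'
#' Columns: res num, KL_1, KL_2, S_1, S_2, and the modal residue of each
#' group. A group's residue is rendered as '-' when the group is
#' gap-majority at the site (non-gap fraction <= 0.5).
#'
#' @param dp A \code{divergence_profile}.
#' @param path Output path.
#' @param group_names Length-2 character vector of column headers for the
#'   modal residues.
#' @param digits Decimal places.
#' @return \code{path}, invisibly.
#' @export
write_divergence_tsv <- function(dp, path, group_names = c("group1", "group2"),
                                 digits = 2) {
  stopifnot(inherits(dp, "divergence_profile"))
  res1 <- ifelse(dp$frac_1 <= 0.5 | is.na(dp$modal_1), "-", dp$modal_1)
  res2 <- ifelse(dp$frac_2 <= 0.5 | is.na(dp$modal_2), "-", dp$modal_2)
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
  out <- data.frame(`res num` = dp$site,
                    KL_1 = fmt(dp$kl_1), KL_2 = fmt(dp$kl_2),
                    S_1 = fmt(dp$s_1), S_2 = fmt(dp$s_2),
                    g1 = res1, g2 = res2, check.names = FALSE)
  names(out)[6:7] <- group_names
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
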