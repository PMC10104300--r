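# Representative-set reduction for phylogeny input: thin a sequence set to k
# members with the most even possible spread, using the pairwise distance
# matrix, then merge and deduplicate reduced sets.

#' Pairwise identity-based distance matrix from an alignment
#'
#' distance(a, b) = 1 - (matching positions) / (positions where both rows
#' are non-gap). Pairs with no mutually non-gap position get distance 1.
#'
#' @param aln Character matrix with row names, or aligned \code{seq_set}.
#' @return A \code{dist_matrix}: list with \code{ids} and symmetric numeric
#'   matrix \code{d} (zero diagonal, values in [0, 1]).
#' @export
pairwise_identity_matrix <- function(aln) {
  if (inherits(aln, "seq_set")) aln <- alignment_matrix(aln)
  stopifnot(is.matrix(aln), is.character(aln))
  if (nrow(aln) < 2) stop("need at least 2 sequences")
  n <- nrow(aln)
  nongap <- aln != GAP
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- nongap[i, ] & nongap[j, ]
      nc <- sum(both)
      dij <- if (nc == 0) 1 else 1 - sum(aln[i, both] == aln[j, both]) / nc
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(list(ids = rownames(aln), d = d), class = "dist_matrix")
}

#' Construct a distance matrix object from a precomputed matrix
#'
#' @param d Symmetric numeric matrix with zero diagonal, values in [0, 1].
#' @param ids Sequence ids; defaults to \code{rownames(d)}.
#' @return A \code{dist_matrix}.
#' @export
dist_matrix <- function(d, ids = rownames(d)) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(ids)) stop("ids required (or rownames on d)")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0 | d > 1)) stop("distances must lie in [0, 1]")
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "dist_matrix")
}

#' Select k evenly spread representatives from a distance matrix
#'
#' Iteratively finds the globally closest remaining pair and removes one of
#' its members until k sequences remain, keeping the spread as even as
#' possible. Within the closest pair, the member removed is the one whose
#' next-nearest remaining neighbour (excluding the partner) is closer —
#' i.e. the more redundant sequence — so isolated sequences are kept.
#' Ties are broken by lexicographic id; the procedure is deterministic.
#'
#' @param dm A \code{dist_matrix}.
#' @param k Number of representatives to retain, 1 <= k <= n.
#' @return Character vector of retained ids, in original order.
#' @export
select_representatives <- function(dm, k) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- length(dm$ids)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  d <- dm$d
  alive <- dm$ids
  while (length(alive) > k) {
    sub <- d[alive, alive, drop = FALSE]
    diag(sub) <- Inf
    # globally closest remaining pair; ties resolved to lexicographically
    # first (i, j) pair via ordered id scan
    min_d <- min(sub)
    hits <- which(sub == min_d, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_ids <- t(apply(hits, 1, function(h) sort(alive[h])))
    ord <- order(pair_ids[, 1], pair_ids[, 2])
    a <- pair_ids[ord[1], 1]
    b <- pair_ids[ord[1], 2]
    # next-nearest neighbour distance, excluding the partner
    nn <- function(x, partner) {
      others <- setdiff(alive, c(x, partner))
      if (length(others) == 0) return(Inf)
      min(d[x, others])
    }
    nn_a <- nn(a, b)
    nn_b <- nn(b, a)
    drop_id <- if (nn_a < nn_b) a
      else if (nn_b < nn_a) b
      else min(a, b)  # tie: lexicographic
    alive <- setdiff(alive, drop_id)
  }
  dm$ids[dm$ids %in% alive]
}

#' Merge sequence sets and remove duplicates
#'
#' Union preserving first occurrence. A record is a duplicate if its id OR
#' its residue string is identical to an earlier record. The removed
#' duplicates are attached as the \code{"duplicates"} attribute.
#'
#' @param ... \code{seq_set} objects (or a single list of them).
#' @return Merged \code{seq_set} with attribute \code{duplicates}
#'   (data frame: id, reason).
#' @export
merge_dedupe <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "seq_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "seq_set")))
  all <- do.call(rbind, lapply(sets, as.data.frame))
  dup_id <- duplicated(all$id)
  dup_seq <- duplicated(all$residues)
  dup <- dup_id | dup_seq
  reason <- ifelse(dup_id, "id", "residues")[dup]
  removed <- data.frame(id = all$id[dup], reason = reason,
                        stringsAsFactors = FALSE)
  kept <- all[!dup, , drop = FALSE]
  out <- seq_set(kept$id, kept$description, kept$residues)
  attr(out, "duplicates") <- removed
  out
}

#' Write a distance matrix as TSV (ids header + full matrix)
#'
#' @param dm A \code{dist_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dist_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  utils::write.table(cbind(id = dm$ids, as.data.frame(dm$d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
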