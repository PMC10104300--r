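# Shared fixture builders: tiny alignments and structures constructed in
# code, so no binary test data is needed.

# alignment matrix from residue strings
aln_from_strings <- function(strings) {
  m <- do.call(rbind, strsplit(unname(strings), ""))
  rownames(m) <- names(strings)
  m
}

# projected alignment straight from residue strings (sites 1..L)
proj_from_strings <- function(strings, row_groups = NULL) {
  m <- aln_from_strings(strings)
  structure(list(reference_id = "ref",
                 site_numbers = seq_len(ncol(m)),
                 source_columns = seq_len(ncol(m)),
                 ali = m,
                 row_groups = row_groups),
            class = "proj_aln")
}

# write a seq_set-like FASTA to a temp file
write_temp_fasta <- function(headers, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# one-letter -> explicit 20-vector site distribution
point_dist <- function(letter) {
  p <- setNames(rep(0, 20), famcons:::AA20)
  p[letter] <- 1
  p
}

mix_dist <- function(...) {
  w <- c(...)
  p <- setNames(rep(0, 20), famcons:::AA20)
  p[names(w)] <- w / sum(w)
  p
}

# distribution object for a hand-built column string (one row per character)
dist_from_column <- function(column) {
  chars <- strsplit(column, "")[[1]]
  strings <- setNames(chars, paste0("s", seq_along(chars)))
  proj <- proj_from_strings(strings)
  column_frequencies(proj, 1)
}

# independent brute-force KL on smoothed counts (oracle; loops over the
# 20 types explicitly, no shared code with the implementation)
brute_kl <- function(counts_p, counts_q, pc) {
  ps <- (counts_p + pc) / (sum(counts_p) + 20 * pc)
  qs <- (counts_q + pc) / (sum(counts_q) + 20 * pc)
  total <- 0
  for (j in 1:20) {
    if (ps[j] > 0) total <- total + as.numeric(ps[j] * log(ps[j] / qs[j]))
  }
  total
}

# exhaustive best min-pairwise-distance over all k-subsets (oracle, n small)
best_min_spread <- function(d, k) {
  ids <- rownames(d)
  best <- -Inf
  for (sub in utils::combn(ids, k, simplify = FALSE)) {
    m <- d[sub, sub]
    val <- min(m[upper.tri(m)])
    if (val > best) best <- val
  }
  best
}

min_spread <- function(d, ids) {
  m <- d[ids, ids]
  min(m[upper.tri(m)])
}

# single straight toy helix along z
toy_helix <- function(n = 10, origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  generate_toy_structure(toy_structure_spec(list(
    list(length = n, origin = origin, direction = direction))))
}
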