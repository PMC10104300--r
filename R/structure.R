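# Structure analysis: PDB parsing, Kabsch superposition, per-residue C-alpha
# deviation of variant vs wild-type structures, polar/ionic contact networks
# between annotated helices, conservation painting into the B-factor column,
# and disease-mutation overlap reports.

#' Construct a structure model from an atom table
#'
#' The atom table is the package's working representation of a (single
#' model) structure: one row per atom with author residue numbering.
#'
#' @param atoms Data frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{x}, \code{y}, \code{z},
#'   \code{b}, \code{o}, \code{het}.
#' @return A \code{structure_model}.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z", "b", "o", "het")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) stop("atom table missing column(s): ",
                                paste(missing, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty atom table")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' Read a PDB structure
#'
#' Reads the first model. Alternate locations are resolved to the highest
#' occupancy (ties to altloc 'A'). Waters and other heteroatoms are retained
#' with \code{het = TRUE}. Residues lacking a C-alpha are kept and listed in
#' the \code{"no_ca"} attribute.
#'
#' @param path Path to a PDB-format file.
#' @return A \code{structure_model}.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (file.size(path) == 0) stop("structure file is empty: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot read PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # resolve altlocs: within (chain, resno, insert, elety) keep top occupancy,
  # ties to the alphabetically first altloc ('A' before 'B')
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, b = at$b, o = at$o,
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  prot <- atoms[!atoms$het, ]
  rkey <- unique(paste(prot$chain, prot$resno, prot$insert, sep = "|"))
  has_ca <- unique(paste(prot$chain, prot$resno, prot$insert, sep = "|")[prot$elety == "CA"])
  attr(m, "no_ca") <- setdiff(rkey, has_ca)
  m
}

#' Write a structure model to PDB format
#'
#' @param model A \code{structure_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, insert = a$insert,
                   chain = a$chain, elety = a$elety, o = a$o,
                   b = pmin(pmax(a$b, -9.99), 999.99))
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  prot <- a[!a$het, ]
  cat("Structure model: ", nrow(a), " atoms, ",
      length(unique(paste(prot$chain, prot$resno, prot$insert))),
      " protein residues, chains ",
      paste(unique(a$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

# C-alpha coordinate table keyed by chain|resno|insert
ca_table <- function(model) {
  a <- model$atoms
  ca <- a[!a$het & a$elety == "CA", , drop = FALSE]
  ca$key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  ca[!duplicated(ca$key), c("key", "chain", "resno", "insert", "x", "y", "z")]
}

# residue selection -> key vector; `selection` is a vector of residue numbers
# (optionally restricted to `chain`), or NULL for all protein residues
selection_keys <- function(model, selection = NULL, chain = NULL) {
  a <- model$atoms[!model$atoms$het, ]
  keys <- unique(paste(a$chain, a$resno, a$insert, sep = "|"))
  if (!is.null(chain)) {
    keys <- keys[vapply(strsplit(keys, "|", fixed = TRUE), `[[`, "", 1) %in% chain]
  }
  if (!is.null(selection)) {
    resnos <- vapply(strsplit(keys, "|", fixed = TRUE),
                     function(p) as.integer(p[[2]]), integer(1))
    keys <- keys[resnos %in% selection]
  }
  keys
}

#' Least-squares (Kabsch) superposition of two structures
#'
#' Finds the proper rotation (determinant +1) and translation minimising the
#' RMSD between shared C-alpha atoms of the mobile and target models.
#'
#' @param mobile,target \code{structure_model} objects.
#' @param selection Optional residue numbers restricting the fit set.
#' @param chain Optional chain restriction applied to both models.
#' @return List with \code{R} (3x3 rotation), \code{t} (translation), the
#'   post-fit \code{rmsd} in Angstrom over the fit atoms, and \code{n} atoms
#'   fitted. Apply with \code{\link{apply_transform}}.
#' @export
superpose <- function(mobile, target, selection = NULL, chain = NULL) {
  stopifnot(inherits(mobile, "structure_model"), inherits(target, "structure_model"))
  ca_m <- ca_table(mobile)
  ca_t <- ca_table(target)
  keys <- intersect(ca_m$key, ca_t$key)
  keys <- intersect(keys, selection_keys(mobile, selection, chain))
  if (length(keys) < 3) stop("need at least 3 shared C-alpha atoms to superpose (have ",
                             length(keys), ")")
  X <- as.matrix(ca_m[match(keys, ca_m$key), c("x", "y", "z")])
  Y <- as.matrix(ca_t[match(keys, ca_t$key), c("x", "y", "z")])
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- t(Xc) %*% Yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- my - as.numeric(R %*% mx)
  fitted <- sweep(X %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(R = R, t = tr, rmsd = rmsd, n = length(keys))
}

#' Apply a rigid transform to a structure model
#'
#' @param model A \code{structure_model}.
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return Transformed \code{structure_model}.
#' @export
apply_transform <- function(model, R, t) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(R), 2, t, `+`)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}

#' Per-residue C-alpha deviation of a variant vs a wild-type structure
#'
#' Superposes the variant onto the wild type on the fit selection (default:
#' all shared C-alpha atoms), then reports the C-alpha/C-alpha distance for
#' every residue of the report selection present with C-alpha in both models.
#'
#' @param variant,wildtype \code{structure_model} objects.
#' @param fit_selection Residue numbers used for the superposition fit
#'   (NULL = all shared).
#' @param report_selection Residue numbers reported (NULL = all shared);
#'   restrict to network residues for a hydrogen-bond-network view.
#' @param chain Optional chain restriction.
#' @return Data frame (\code{deviation_profile}) with columns \code{chain},
#'   \code{resno}, \code{deviation} (Angstrom), sorted by residue number;
#'   post-fit RMSD over the fit set in attribute \code{"rmsd"}.
#' @export
ca_deviation_profile <- function(variant, wildtype, fit_selection = NULL,
                                 report_selection = NULL, chain = NULL) {
  fit <- superpose(variant, wildtype, fit_selection, chain)
  moved <- apply_transform(variant, fit$R, fit$t)
  ca_v <- ca_table(moved)
  ca_w <- ca_table(wildtype)
  keys <- intersect(ca_v$key, ca_w$key)
  keys <- intersect(keys, selection_keys(wildtype, report_selection, chain))
  if (length(keys) == 0) stop("empty report selection: no shared C-alpha atoms")
  V <- as.matrix(ca_v[match(keys, ca_v$key), c("x", "y", "z")])
  W <- as.matrix(ca_w[match(keys, ca_w$key), c("x", "y", "z")])
  dev <- sqrt(rowSums((V - W)^2))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[[`, "", 1),
                    resno = vapply(parts, function(p) as.integer(p[[2]]), integer(1)),
                    deviation = dev, stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  attr(out, "rmsd") <- fit$rmsd
  class(out) <- c("deviation_profile", "data.frame")
  out
}

# --- polar contact chemistry -------------------------------------------------
# Heavy-atom donor/acceptor definitions for the 20 standard residues.
# Crystal structures lack hydrogens, so hydrogen bonds are detected on a
# heavy-atom proxy: donor-acceptor distance plus the angle at the donor
# between its covalent antecedent and the acceptor.

.donor_table <- rbind(
  data.frame(resid = "*",   elety = "N",   antecedent = "CA"),
  data.frame(resid = "ARG", elety = c("NE", "NH1", "NH2"), antecedent = c("CD", "CZ", "CZ")),
  data.frame(resid = "LYS", elety = "NZ",  antecedent = "CE"),
  data.frame(resid = "HIS", elety = c("ND1", "NE2"), antecedent = c("CG", "CD2")),
  data.frame(resid = "TRP", elety = "NE1", antecedent = "CE2"),
  data.frame(resid = "ASN", elety = "ND2", antecedent = "CG"),
  data.frame(resid = "GLN", elety = "NE2", antecedent = "CD"),
  data.frame(resid = "SER", elety = "OG",  antecedent = "CB"),
  data.frame(resid = "THR", elety = "OG1", antecedent = "CB"),
  data.frame(resid = "TYR", elety = "OH",  antecedent = "CZ")
)

.acceptor_table <- rbind(
  data.frame(resid = "*",   elety = c("O", "OXT")),
  data.frame(resid = "ASP", elety = c("OD1", "OD2")),
  data.frame(resid = "GLU", elety = c("OE1", "OE2")),
  data.frame(resid = "ASN", elety = "OD1"),
  data.frame(resid = "GLN", elety = "OE1"),
  data.frame(resid = "HIS", elety = c("ND1", "NE2")),
  data.frame(resid = "SER", elety = "OG"),
  data.frame(resid = "THR", elety = "OG1"),
  data.frame(resid = "TYR", elety = "OH")
)

.ionic_pos <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"))
.ionic_neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Contact detection criteria
#'
#' @param h_max Maximum donor-acceptor heavy-atom distance for a hydrogen
#'   bond, Angstrom (default 3.5).
#' @param angle_min Minimum antecedent-donor-acceptor angle, degrees
#'   (default 90; heavy-atom proxy since hydrogens are absent).
#' @param i_max Maximum N-O distance for an ionic interaction (salt bridge),
#'   Angstrom (default 4.0).
#' @param dedupe If TRUE (default), keep only the closest atom pair per
#'   residue pair; FALSE reports all qualifying atom pairs.
#' @return List of criteria.
#' @export
contact_criteria <- function(h_max = 3.5, angle_min = 90, i_max = 4.0,
                             dedupe = TRUE) {
  stopifnot(h_max > 0, i_max > 0, angle_min >= 0, angle_min <= 180)
  list(h_max = h_max, angle_min = angle_min, i_max = i_max, dedupe = dedupe)
}

# annotate polar atoms of a model with donor/acceptor roles and antecedents
polar_atoms <- function(model) {
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  unknown <- setdiff(unique(a$resid), .aa3)
  if (length(unknown) > 0) {
    message("skipping side-chain chemistry of unknown residue type(s): ",
            paste(unknown, collapse = ", "))
    a <- a[a$resid %in% .aa3 | a$elety %in% c("N", "CA", "C", "O", "OXT"), ]
  }
  a$key <- paste(a$chain, a$resno, a$insert, sep = "|")
  don <- do.call(rbind, lapply(seq_len(nrow(.donor_table)), function(i) {
    row <- .donor_table[i, ]
    hit <- a[a$elety == row$elety & (row$resid == "*" | a$resid == row$resid), ]
    if (nrow(hit) == 0) return(NULL)
    hit$antecedent <- row$antecedent
    hit
  }))
  if (!is.null(don) && nrow(don) > 0) {
    # antecedent coordinates (same residue); missing antecedent -> NA (angle waived)
    akey <- paste(a$key, a$elety, sep = "@")
    m <- match(paste(don$key, don$antecedent, sep = "@"), akey)
    don$ax <- a$x[m]; don$ay <- a$y[m]; don$az <- a$z[m]
  }
  acc <- do.call(rbind, lapply(seq_len(nrow(.acceptor_table)), function(i) {
    row <- .acceptor_table[i, ]
    a[a$elety == row$elety & (row$resid == "*" | a$resid == row$resid), ]
  }))
  pos <- do.call(rbind, lapply(names(.ionic_pos), function(r) {
    a[a$resid == r & a$elety %in% .ionic_pos[[r]], ]
  }))
  neg <- do.call(rbind, lapply(names(.ionic_neg), function(r) {
    a[a$resid == r & a$elety %in% .ionic_neg[[r]], ]
  }))
  list(donors = don, acceptors = acc, pos = pos, neg = neg)
}

# pairwise distances between two atom tables
atom_dists <- function(A, B) {
  if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0) return(NULL)
  dx <- outer(A$x, B$x, `-`); dy <- outer(A$y, B$y, `-`); dz <- outer(A$z, B$z, `-`)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Detect hydrogen-bond and ionic contacts between two residue selections
#'
#' Hydrogen bond: donor heavy atom (N/O with hydrogen implied by residue
#' chemistry) to acceptor N/O distance <= \code{h_max}, with the
#' antecedent-donor-acceptor angle >= \code{angle_min}. Ionic: side-chain
#' charged-group nitrogen of Arg/Lys/His to side-chain carboxylate oxygen of
#' Asp/Glu at distance <= \code{i_max}; a pair qualifying as ionic is
#' labelled ionic. Each unordered atom pair is reported once; contacts
#' within a single residue are never reported.
#'
#' @param model A \code{structure_model}.
#' @param set_a,set_b Residue-number vectors (non-empty) defining the two
#'   selections.
#' @param criteria A \code{\link{contact_criteria}} list.
#' @param chain Optional chain restriction.
#' @return A \code{contact_network} data frame: \code{chain_a, resno_a,
#'   resid_a, atom_a, chain_b, resno_b, resid_b, atom_b, dist, type}.
#' @export
detect_polar_contacts <- function(model, set_a, set_b,
                                  criteria = contact_criteria(), chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (length(set_a) == 0 || length(set_b) == 0) stop("selections must be non-empty")
  keys_a <- selection_keys(model, set_a, chain)
  keys_b <- selection_keys(model, set_b, chain)
  pa <- polar_atoms(model)

  edge_rows <- list()
  hb_pairs <- function(don, acc) {
    if (is.null(don) || is.null(acc) || nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    D <- atom_dists(don, acc)
    hits <- which(D <= criteria$h_max, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    keep <- logical(nrow(hits))
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1]; j <- hits[k, 2]
      if (don$key[i] == acc$key[j]) next  # same residue
      if (!is.na(don$ax[i])) {
        u <- c(don$ax[i] - don$x[i], don$ay[i] - don$y[i], don$az[i] - don$z[i])
        v <- c(acc$x[j] - don$x[i], acc$y[j] - don$y[i], acc$z[j] - don$z[i])
        ang <- acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
        if (ang < criteria$angle_min) next
      }
      keep[k] <- TRUE
    }
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    data.frame(key_a = don$key[hits[, 1]], atom_a = don$elety[hits[, 1]],
               resid_a = don$resid[hits[, 1]],
               key_b = acc$key[hits[, 2]], atom_b = acc$elety[hits[, 2]],
               resid_b = acc$resid[hits[, 2]],
               dist = D[hits], type = "hydrogen-bond", stringsAsFactors = FALSE)
  }
  ion_pairs <- function(pos, neg) {
    if (is.null(pos) || is.null(neg) || nrow(pos) == 0 || nrow(neg) == 0) return(NULL)
    D <- atom_dists(pos, neg)
    hits <- which(D <= criteria$i_max, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    hits <- hits[pos$key[hits[, 1]] != neg$key[hits[, 2]], , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    data.frame(key_a = pos$key[hits[, 1]], atom_a = pos$elety[hits[, 1]],
               resid_a = pos$resid[hits[, 1]],
               key_b = neg$key[hits[, 2]], atom_b = neg$elety[hits[, 2]],
               resid_b = neg$resid[hits[, 2]],
               dist = D[hits], type = "ionic", stringsAsFactors = FALSE)
  }
  sub <- function(tab, keys) {
    if (is.null(tab)) return(NULL)
    tab[tab$key %in% keys, , drop = FALSE]
  }
  # both directions across the two selections
  edge_rows$h1 <- hb_pairs(sub(pa$donors, keys_a), sub(pa$acceptors, keys_b))
  edge_rows$h2 <- hb_pairs(sub(pa$donors, keys_b), sub(pa$acceptors, keys_a))
  edge_rows$i1 <- ion_pairs(sub(pa$pos, keys_a), sub(pa$neg, keys_b))
  edge_rows$i2 <- ion_pairs(sub(pa$pos, keys_b), sub(pa$neg, keys_a))
  edges <- do.call(rbind, edge_rows[!vapply(edge_rows, is.null, logical(1))])
  if (is.null(edges) || nrow(edges) == 0) return(empty_network())

  # exclude pairs where both residues fall in the intersection trivially:
  # keep only pairs bridging the two selections (one end in each)
  in_a <- edges$key_a %in% keys_a & edges$key_b %in% keys_b
  in_b <- edges$key_a %in% keys_b & edges$key_b %in% keys_a
  edges <- edges[in_a | in_b, , drop = FALSE]
  if (nrow(edges) == 0) return(empty_network())

  # canonical unordered atom-pair key; ionic labelling wins over hydrogen-bond
  ap <- paste(edges$key_a, edges$atom_a, sep = "@")
  bp <- paste(edges$key_b, edges$atom_b, sep = "@")
  lo <- pmin(ap, bp); hi <- pmax(ap, bp)
  edges$pair <- paste(lo, hi, sep = "::")
  edges <- edges[order(edges$pair, edges$type != "ionic"), ]
  edges <- edges[!duplicated(edges$pair), , drop = FALSE]

  if (criteria$dedupe) {
    rlo <- pmin(edges$key_a, edges$key_b); rhi <- pmax(edges$key_a, edges$key_b)
    edges$rpair <- paste(rlo, rhi, sep = "::")
    edges <- edges[order(edges$rpair, edges$dist), ]
    edges <- edges[!duplicated(edges$rpair), , drop = FALSE]
    edges$rpair <- NULL
  }
  edges$pair <- NULL
  split_key <- function(k, part) {
    vapply(strsplit(k, "|", fixed = TRUE),
           function(p) p[[part]], "")
  }
  out <- data.frame(chain_a = split_key(edges$key_a, 1),
                    resno_a = as.integer(split_key(edges$key_a, 2)),
                    resid_a = edges$resid_a, atom_a = edges$atom_a,
                    chain_b = split_key(edges$key_b, 1),
                    resno_b = as.integer(split_key(edges$key_b, 2)),
                    resid_b = edges$resid_b, atom_b = edges$atom_b,
                    dist = edges$dist, type = edges$type,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$resno_b), ]
  rownames(out) <- NULL
  class(out) <- c("contact_network", "data.frame")
  out
}

empty_network <- function() {
  out <- data.frame(chain_a = character(), resno_a = integer(),
                    resid_a = character(), atom_a = character(),
                    chain_b = character(), resno_b = integer(),
                    resid_b = character(), atom_b = character(),
                    dist = numeric(), type = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_network", "data.frame")
  out
}

#' Define helix annotations
#'
#' @param name Helix names (e.g. "a3", "a6", "a7", "a8").
#' @param chain Chain id per helix.
#' @param start,end First and last residue numbers (inclusive).
#' @return A \code{helix_annotation} data frame.
#' @export
helix_annotation <- function(name, chain, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  chain <- rep_len(chain, length(name))
  if (any(start > end)) stop("helix start must be <= end")
  out <- data.frame(name = name, chain = chain, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("helix_annotation", "data.frame")
  out
}

#' Inter-helix polar/ionic contact network report
#'
#' Detects polar and ionic contacts between every unordered pair of the
#' annotated helices (intra-helix contacts are never counted) and reports
#' both the residue-pair-level count (distinct residue pairs with at least
#' one contact) and the atom-pair-level count.
#'
#' @param model A \code{structure_model}.
#' @param helices A \code{\link{helix_annotation}} with >= 2 helices.
#' @param criteria A \code{\link{contact_criteria}} list.
#' @return List with \code{edges} (a \code{contact_network} plus
#'   \code{helix_pair}), \code{pair_counts} (per helix pair), and totals
#'   \code{n_residue_pairs}, \code{n_atom_pairs}.
#' @export
helix_network_report <- function(model, helices, criteria = contact_criteria()) {
  stopifnot(inherits(model, "structure_model"), inherits(helices, "helix_annotation"))
  if (nrow(helices) < 2) stop("need at least 2 helices")
  for (i in seq_len(nrow(helices) - 1)) {
    for (j in (i + 1):nrow(helices)) {
      if (helices$chain[i] == helices$chain[j] &&
          helices$start[i] <= helices$end[j] && helices$start[j] <= helices$end[i]) {
        stop("overlapping helix ranges: ", helices$name[i], " and ", helices$name[j])
      }
    }
  }
  all_edges <- list()
  counts <- list()
  for (i in seq_len(nrow(helices) - 1)) {
    for (j in (i + 1):nrow(helices)) {
      # per-pair atom-level detection (dedupe applied after pooling)
      crit_all <- criteria; crit_all$dedupe <- FALSE
      e <- detect_polar_contacts(model,
                                 set_a = helices$start[i]:helices$end[i],
                                 set_b = helices$start[j]:helices$end[j],
                                 criteria = crit_all,
                                 chain = unique(helices$chain[c(i, j)]))
      # drop edges not actually bridging the two helices (chain-aware)
      if (nrow(e) > 0) {
        a_in_i <- e$chain_a == helices$chain[i] &
          e$resno_a >= helices$start[i] & e$resno_a <= helices$end[i]
        b_in_j <- e$chain_b == helices$chain[j] &
          e$resno_b >= helices$start[j] & e$resno_b <= helices$end[j]
        a_in_j <- e$chain_a == helices$chain[j] &
          e$resno_a >= helices$start[j] & e$resno_a <= helices$end[j]
        b_in_i <- e$chain_b == helices$chain[i] &
          e$resno_b >= helices$start[i] & e$resno_b <= helices$end[i]
        e <- e[(a_in_i & b_in_j) | (a_in_j & b_in_i), , drop = FALSE]
      }
      pair_lab <- paste(helices$name[i], helices$name[j], sep = "-")
      n_atom <- nrow(e)
      if (n_atom > 0) {
        e$helix_pair <- pair_lab
        if (criteria$dedupe) {
          rlo <- pmin(paste(e$chain_a, e$resno_a), paste(e$chain_b, e$resno_b))
          rhi <- pmax(paste(e$chain_a, e$resno_a), paste(e$chain_b, e$resno_b))
          rp <- paste(rlo, rhi, sep = "::")
          e <- e[order(rp, e$dist), ]
          e <- e[!duplicated(paste(pmin(paste(e$chain_a, e$resno_a),
                                        paste(e$chain_b, e$resno_b)),
                                   pmax(paste(e$chain_a, e$resno_a),
                                        paste(e$chain_b, e$resno_b)))), ]
        }
        all_edges[[pair_lab]] <- e
      }
      rlo <- if (n_atom > 0) pmin(paste(e$chain_a, e$resno_a), paste(e$chain_b, e$resno_b))
      n_res <- if (n_atom == 0) 0L else
        length(unique(paste(pmin(paste(e$chain_a, e$resno_a), paste(e$chain_b, e$resno_b)),
                            pmax(paste(e$chain_a, e$resno_a), paste(e$chain_b, e$resno_b)))))
      counts[[pair_lab]] <- data.frame(helix_pair = pair_lab,
                                       n_residue_pairs = n_res,
                                       n_atom_pairs = n_atom,
                                       stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(all_edges) > 0) do.call(rbind, all_edges) else {
    e <- empty_network(); e$helix_pair <- character(0); e
  }
  rownames(edges) <- NULL
  pair_counts <- do.call(rbind, counts)
  rownames(pair_counts) <- NULL
  list(edges = edges,
       pair_counts = pair_counts,
       n_residue_pairs = sum(pair_counts$n_residue_pairs),
       n_atom_pairs = sum(pair_counts$n_atom_pairs))
}

#' Scan contact criteria over a cutoff grid
#'
#' Recomputes the inter-helix network at every combination of hydrogen-bond
#' and ionic distance cutoffs, reporting both count conventions. Useful when
#' a published contact count was obtained with unstated criteria.
#'
#' @param model A \code{structure_model}.
#' @param helices A \code{\link{helix_annotation}}.
#' @param h_grid,i_grid Numeric vectors of cutoffs (Angstrom).
#' @param angle_min Angle criterion held fixed across the grid.
#' @return Data frame: \code{h_max}, \code{i_max}, \code{n_residue_pairs},
#'   \code{n_atom_pairs}.
#' @export
contact_cutoff_grid <- function(model, helices,
                                h_grid = seq(3.0, 3.9, by = 0.3),
                                i_grid = seq(3.5, 4.5, by = 0.5),
                                angle_min = 90) {
  rows <- list()
  for (h in h_grid) for (i in i_grid) {
    rep <- helix_network_report(model, helices,
                                contact_criteria(h_max = h, i_max = i,
                                                 angle_min = angle_min))
    rows[[paste(h, i)]] <- data.frame(h_max = h, i_max = i,
                                      n_residue_pairs = rep$n_residue_pairs,
                                      n_atom_pairs = rep$n_atom_pairs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paint conservation scores into the B-factor column
#'
#' Sets the B-factor of every atom in residue r of the given chain to
#' \code{scale * S(r)}, clamped to [0, 999.99]; residues without a profile
#' value get the sentinel and are listed in the \code{"unpainted"} attribute.
#' Writing with \code{\link{write_structure}} then gives a structure
#' colourable by conservation in any molecular viewer.
#'
#' @param model A \code{structure_model}.
#' @param profile A \code{conservation_profile} whose site numbers are the
#'   chain's residue numbers.
#' @param chain Chain to paint.
#' @param scale Multiplier applied to entropy (default 100).
#' @param sentinel Value for residues lacking a defined score (default -1).
#' @return Annotated \code{structure_model}.
#' @export
map_scores_to_structure <- function(model, profile, chain, scale = 100,
                                    sentinel = -1) {
  stopifnot(inherits(model, "structure_model"),
            inherits(profile, "conservation_profile"))
  a <- model$atoms
  if (!chain %in% a$chain) stop("chain '", chain, "' not present in model")
  s <- profile$entropy[match(a$resno, profile$site)]
  on_chain <- a$chain == chain & !a$het
  b <- a$b
  b[on_chain] <- ifelse(is.na(s[on_chain]), sentinel,
                        pmin(pmax(scale * s[on_chain], 0), 999.99))
  model$atoms$b <- b
  unpainted <- sort(unique(a$resno[on_chain][is.na(s[on_chain])]))
  attr(model, "unpainted") <- unpainted
  model
}

#' Classify residues by mutation and conservation status
#'
#' Every residue appearing in the contact network, the disease-mutation
#' list, or the conserved set (entropy <= \code{s_max}) is classified as
#' \code{both}, \code{CMT-only}, \code{conserved-only} or \code{neither}.
#' For an optional focus segment (e.g. the a6-a7 loop), the residues
#' contacting it in the network are listed with their classes.
#'
#' @param network A \code{contact_network} (or the \code{edges} element of a
#'   \code{\link{helix_network_report}}).
#' @param profile A \code{conservation_profile} in the same residue numbering.
#' @param cmt_sites Integer vector of disease-mutation residue numbers.
#' @param s_max Entropy ceiling defining "highly conserved" (default 0.1).
#' @param focus Optional integer vector of focus-segment residue numbers.
#' @return List with \code{classes} (data frame: resno, in_network, class)
#'   and, when \code{focus} is given, \code{focus_contacts}.
#' @export
mutation_overlap_report <- function(network, profile, cmt_sites,
                                    s_max = 0.1, focus = NULL) {
  stopifnot(inherits(profile, "conservation_profile"))
  net_res <- integer(0)
  if (!is.null(network) && nrow(network) > 0) {
    net_res <- sort(unique(c(network$resno_a, network$resno_b)))
  }
  conserved <- profile$site[!is.na(profile$entropy) & profile$entropy <= s_max]
  residues <- sort(unique(c(net_res, cmt_sites, conserved)))
  cls <- ifelse(residues %in% cmt_sites & residues %in% conserved, "both",
         ifelse(residues %in% cmt_sites, "CMT-only",
         ifelse(residues %in% conserved, "conserved-only", "neither")))
  classes <- data.frame(resno = residues,
                        in_network = residues %in% net_res,
                        class = cls, stringsAsFactors = FALSE)
  out <- list(classes = classes)
  if (!is.null(focus) && !is.null(network) && nrow(network) > 0) {
    touches <- (network$resno_a %in% focus) | (network$resno_b %in% focus)
    partners <- unique(c(network$resno_a[network$resno_b %in% focus & touches],
                         network$resno_b[network$resno_a %in% focus & touches]))
    partners <- sort(setdiff(partners, focus))
    out$focus_contacts <- data.frame(
      resno = partners,
      class = classes$class[match(partners, classes$resno)],
      stringsAsFactors = FALSE)
    out$focus_contacts$class[is.na(out$focus_contacts$class)] <- "neither"
  }
  out
}

#' Write a contact network as TSV
#'
#' @param edges A \code{contact_network} (optionally with helix_pair).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_network_tsv <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
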