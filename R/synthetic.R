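# Synthetic alignments, grouped families, and toy helical structures with
# known ground truth, used to validate every estimator in the package
# without any external data. All generators are pure functions of their
# spec plus seed.

#' Specify a synthetic protein family
#'
#' Each site is described either by an explicit length-20 probability vector
#' over the amino-acid alphabet, or by a single positive number interpreted
#' as the concentration of a symmetric Dirichlet from which the site's
#' column distribution is drawn once (rows are then i.i.d. from it). Small
#' concentrations give near-conserved columns, large ones near-uniform.
#'
#' @param n_sequences Number of rows.
#' @param sites List of per-site specs (probability vector or concentration).
#' @param gap_rate Probability that a cell is masked to a gap, in [0, 1).
#' @param seed Integer seed.
#' @return A \code{family_spec}.
#' @export
family_spec <- function(n_sequences, sites, gap_rate = 0, seed = 1) {
  stopifnot(n_sequences >= 1, length(sites) >= 1)
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  for (s in sites) {
    if (length(s) == 1) {
      if (!is.numeric(s) || s <= 0) stop("concentration must be a positive number")
    } else {
      if (length(s) != 20) stop("explicit site distribution must have length 20")
      if (any(s < 0) || abs(sum(s) - 1) > 1e-8) stop("site probabilities must be >= 0 and sum to 1")
    }
  }
  structure(list(n_sequences = n_sequences, sites = sites,
                 gap_rate = gap_rate, seed = seed),
            class = "family_spec")
}

# symmetric Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha, k = 20) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(k, 1)] <- 1  # degenerate guard at tiny alpha
  g / sum(g)
}

# realize per-site distributions: 20 x L matrix of column probabilities
realize_site_dists <- function(sites) {
  L <- length(sites)
  P <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (i in seq_len(L)) {
    s <- sites[[i]]
    P[, i] <- if (length(s) == 1) rdirichlet1(s) else as.numeric(s)
  }
  P
}

# draw an alignment matrix from realized distributions
draw_rows <- function(P, n, gap_rate, prefix) {
  L <- ncol(P)
  ali <- matrix("", nrow = n, ncol = L)
  for (i in seq_len(L)) {
    ali[, i] <- sample(AA20, n, replace = TRUE, prob = P[, i])
  }
  if (gap_rate > 0) {
    mask <- matrix(stats::runif(n * L) < gap_rate, nrow = n)
    ali[mask] <- GAP
  }
  rownames(ali) <- sprintf("%s%04d", prefix, seq_len(n))
  ali
}

#' Generate a synthetic family alignment with known site distributions
#'
#' Rows are drawn independently per site from the site's column
#' distribution; gaps are injected independently at \code{gap_rate}. The
#' realized true distributions are returned for estimator-recovery tests.
#'
#' @param spec A \code{\link{family_spec}}.
#' @return List with \code{proj} (a \code{proj_aln} with sites numbered
#'   1..L), \code{true_dists} (20 x L matrix of column probabilities) and
#'   \code{true_entropy} (base-20 entropy of each true distribution).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  P <- realize_site_dists(spec$sites)
  ali <- draw_rows(P, spec$n_sequences, spec$gap_rate, "seq")
  proj <- structure(list(reference_id = "synthetic_reference",
                         site_numbers = seq_len(ncol(P)),
                         source_columns = seq_len(ncol(P)),
                         ali = ali, row_groups = NULL),
                    class = "proj_aln")
  list(proj = proj, true_dists = P,
       true_entropy = apply(P, 2, site_entropy))
}

#' Generate a two-group family with injected divergent sites
#'
#' Non-divergent sites share one realized distribution across both groups;
#' each divergent site uses \code{dist_1} for group 1 and \code{dist_2} for
#' group 2. The divergent-site key is returned for recovery testing.
#'
#' @param shared_spec A \code{\link{family_spec}}; \code{n_sequences} is the
#'   size of each group.
#' @param divergent_sites Named list mapping site number (as character or
#'   integer names) to a list of two length-20 probability vectors
#'   \code{list(dist_1, dist_2)}.
#' @return List with \code{proj} (row_groups set to "group1"/"group2"),
#'   \code{divergent_sites} (integer vector) and the realized per-group
#'   distributions \code{true_dists_1}, \code{true_dists_2}.
#' @export
generate_two_groups <- function(shared_spec, divergent_sites = list()) {
  stopifnot(inherits(shared_spec, "family_spec"))
  L <- length(shared_spec$sites)
  div_idx <- as.integer(names(divergent_sites))
  if (length(divergent_sites) > 0) {
    if (any(is.na(div_idx))) stop("divergent_sites must be named by site number")
    if (anyDuplicated(div_idx)) stop("duplicate divergent site indices")
    if (any(div_idx < 1 | div_idx > L)) stop("divergent site index outside 1..", L)
    for (d in divergent_sites) {
      if (length(d) != 2) stop("each divergent site needs exactly two distributions")
      for (v in d) {
        if (length(v) != 20 || any(v < 0) || abs(sum(v) - 1) > 1e-8) {
          stop("divergent-site distributions must be length-20 probability vectors")
        }
      }
    }
  }
  set.seed(shared_spec$seed)
  P1 <- realize_site_dists(shared_spec$sites)
  P2 <- P1
  for (k in seq_along(divergent_sites)) {
    P1[, div_idx[k]] <- as.numeric(divergent_sites[[k]][[1]])
    P2[, div_idx[k]] <- as.numeric(divergent_sites[[k]][[2]])
  }
  n <- shared_spec$n_sequences
  ali1 <- draw_rows(P1, n, shared_spec$gap_rate, "g1_")
  ali2 <- draw_rows(P2, n, shared_spec$gap_rate, "g2_")
  ali <- rbind(ali1, ali2)
  groups <- stats::setNames(rep(c("group1", "group2"), each = n), rownames(ali))
  proj <- structure(list(reference_id = "synthetic_reference",
                         site_numbers = seq_len(L),
                         source_columns = seq_len(L),
                         ali = ali, row_groups = groups),
                    class = "proj_aln")
  list(proj = proj, divergent_sites = sort(div_idx),
       true_dists_1 = P1, true_dists_2 = P2)
}

#' Specify a toy helical structure
#'
#' Ideal alpha-helical C-alpha traces: 1.5 Angstrom rise and 100 degree
#' rotation per residue about the helix axis, 2.3 Angstrom radius. Each
#' residue carries backbone N, CA, C, O (poly-alanine); side-chain
#' pseudo-atoms for contact fixtures are added by the caller.
#'
#' @param helices List of helices, each a list with \code{length} (>= 4
#'   residues), \code{origin} (length-3 numeric) and \code{direction}
#'   (length-3 numeric, non-zero).
#' @param chain Chain id (default "A").
#' @return A \code{toy_structure_spec}.
#' @export
toy_structure_spec <- function(helices, chain = "A") {
  for (h in helices) {
    if (is.null(h$length) || h$length < 4) stop("helix length must be >= 4")
    if (is.null(h$origin) || length(h$origin) != 3) stop("helix origin must be length-3")
    if (is.null(h$direction) || length(h$direction) != 3 ||
        sqrt(sum(h$direction^2)) == 0) stop("helix direction must be non-zero length-3")
  }
  structure(list(helices = helices, chain = chain), class = "toy_structure_spec")
}

# orthonormal frame with e3 = unit direction
axis_frame <- function(direction) {
  e3 <- direction / sqrt(sum(direction^2))
  ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Generate a toy poly-alanine helical structure
#'
#' Deterministic: the same spec always yields identical coordinates.
#' Residues are numbered consecutively along the chain across helices.
#'
#' @param spec A \code{\link{toy_structure_spec}}.
#' @return A \code{structure_model}.
#' @export
generate_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  rows <- list()
  resno <- 0
  for (h in spec$helices) {
    fr <- axis_frame(h$direction)
    n <- h$length
    ca <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      th <- (i - 1) * twist
      ca[i, ] <- h$origin + (i - 1) * rise * fr$e3 +
        radius * (cos(th) * fr$e1 + sin(th) * fr$e2)
    }
    for (i in seq_len(n)) {
      resno <- resno + 1
      # chord directions to neighbours give plausible backbone placements
      nxt <- if (i < n) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
      prv <- if (i > 1) ca[i - 1, ] - ca[i, ] else ca[i, ] - ca[i + 1, ]
      un <- nxt / sqrt(sum(nxt^2)); up <- prv / sqrt(sum(prv^2))
      Npos <- ca[i, ] + 1.46 * up * 0.9 + 0.3 * fr$e3
      Cpos <- ca[i, ] + 1.52 * un * 0.9 + 0.3 * fr$e3
      perp <- fr$e1 * sin((i - 1) * twist) - fr$e2 * cos((i - 1) * twist)
      Opos <- Cpos + 1.23 * perp
      rows[[resno]] <- data.frame(
        chain = spec$chain, resno = resno, insert = "", resid = "ALA",
        elety = c("N", "CA", "C", "O"),
        x = c(Npos[1], ca[i, 1], Cpos[1], Opos[1]),
        y = c(Npos[2], ca[i, 2], Cpos[2], Opos[2]),
        z = c(Npos[3], ca[i, 3], Cpos[3], Opos[3]),
        b = 0, o = 1, het = FALSE, stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows))
}

#' Add explicit atoms to a structure model
#'
#' Convenience for building contact-geometry fixtures: places side-chain
#' pseudo-atoms (e.g. a Ser OG donor or Asp OD1 acceptor) at exact
#' coordinates, optionally changing the residue type of the touched residue.
#'
#' @param model A \code{structure_model}.
#' @param resno Residue number receiving the atom.
#' @param elety Atom name.
#' @param xyz Length-3 coordinates.
#' @param resid Optional new residue type for the whole residue (e.g. "SER").
#' @param chain Chain id (default: the residue's existing chain).
#' @return Updated \code{structure_model}.
#' @export
add_atom <- function(model, resno, elety, xyz, resid = NULL, chain = NULL) {
  stopifnot(inherits(model, "structure_model"), length(xyz) == 3)
  a <- model$atoms
  sel <- a$resno == resno & !a$het
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("residue ", resno, " not found")
  use_chain <- if (is.null(chain)) a$chain[sel][1] else chain
  use_resid <- if (is.null(resid)) a$resid[sel][1] else resid
  if (!is.null(resid)) a$resid[sel] <- resid
  new <- data.frame(chain = use_chain, resno = resno, insert = "",
                    resid = use_resid, elety = elety,
                    x = xyz[1], y = xyz[2], z = xyz[3], b = 0, o = 1,
                    het = FALSE, stringsAsFactors = FALSE)
  model$atoms <- rbind(a, new)
  model$atoms <- model$atoms[order(model$atoms$chain, model$atoms$resno), ]
  rownames(model$atoms) <- NULL
  model
}

#' Perturb a structure with known per-residue displacements
#'
#' Translates the atoms of listed residues by their displacement vectors,
#' then optionally applies a global rigid motion. The ground-truth
#' displacement magnitudes are attached for recovery testing.
#'
#' @param model A \code{structure_model}.
#' @param displacements Named list: residue number -> length-3 vector (Angstrom).
#' @param rigid Optional list with \code{R} (3x3 rotation) and \code{t}
#'   (length-3 translation) applied after the displacements.
#' @return Perturbed \code{structure_model} with attribute
#'   \code{"true_displacements"} (named numeric vector of magnitudes).
#' @export
perturb_structure <- function(model, displacements = list(), rigid = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  mags <- numeric(0)
  for (nm in names(displacements)) {
    rn <- as.integer(nm)
    v <- displacements[[nm]]
    stopifnot(length(v) == 3)
    sel <- a$resno == rn & !a$het
    if (!any(sel)) stop("residue ", rn, " not found in model")
    a$x[sel] <- a$x[sel] + v[1]
    a$y[sel] <- a$y[sel] + v[2]
    a$z[sel] <- a$z[sel] + v[3]
    mags[nm] <- sqrt(sum(v^2))
  }
  model$atoms <- a
  if (!is.null(rigid)) {
    stopifnot(is.matrix(rigid$R), length(rigid$t) == 3)
    if (abs(det(rigid$R) - 1) > 1e-6) stop("rigid$R must be a proper rotation")
    model <- apply_transform(model, rigid$R, rigid$t)
  }
  attr(model, "true_displacements") <- mags
  model
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis "x", "y" or "z".
#' @param degrees Rotation angle.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis = c("z", "x", "y"), degrees) {
  axis <- match.arg(axis)
  th <- degrees * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
         z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE),
         x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
         y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE))
}
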