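# End-to-end orchestration from a single declarative config: group ->
# project -> entropy/KL -> representative reduction, and structures ->
# networks / deviations / conservation painting / mutation overlay.
# Outputs are deterministic given the config, and every run writes a
# manifest with input checksums so results are reproducible.

#' Read a run configuration from YAML
#'
#' Thresholds default to the conventions used throughout the package:
#' \code{s_conserved} 0.2, \code{s_highly} 0.1, \code{frac_min} 0.7,
#' \code{pseudocount} 0.5.
#'
#' @param path Path to a YAML config file.
#' @return A named list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' Validate and complete a run configuration
#'
#' @param cfg Named list of config entries (see \code{\link{run_sequence_pipeline}}
#'   and \code{\link{run_structure_pipeline}} for the keys each consumes).
#' @return The completed config, class \code{run_config}.
#' @export
run_config <- function(cfg) {
  defaults <- list(s_conserved = 0.2, s_highly = 0.1, frac_min = 0.7,
                   pseudocount = 0.5, k_representatives = 100,
                   scale = 100, seed = 1,
                   contact = list(h_max = 3.5, angle_min = 90, i_max = 4.0))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in c("s_conserved", "s_highly", "frac_min")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1) stop(nm, " must be in (0, 1]")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_manifest <- function(out_dir, cfg, inputs, outputs) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("famcons")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    outputs = unlist(outputs, use.names = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the sequence-analysis pipeline
#'
#' Reads an aligned FASTA, assigns subfamily groups from annotation rules,
#' projects onto the reference, writes per-group conserved-site tables, a
#' bidirectional divergence table for the two configured contrast groups,
#' and a reduced representative set.
#'
#' Config keys used: \code{msa} (aligned FASTA path), \code{reference_id},
#' \code{group_rules} (named list label -> patterns), \code{drop_patterns},
#' \code{contrast} (two group labels for the KL table), thresholds
#' (\code{s_conserved}, \code{s_highly}, \code{frac_min},
#' \code{pseudocount}), \code{k_representatives}, \code{out_dir}.
#'
#' @param cfg A \code{run_config} (or plain list passed through
#'   \code{\link{run_config}}).
#' @return Invisible list of result objects and output paths.
#' @export
run_sequence_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$msa)) stop("config error: 'msa' (aligned FASTA path) is required")
  if (is.null(cfg$reference_id)) stop("config error: 'reference_id' is required")
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  recs <- stage("read", read_fasta(cfg$msa))
  message("read ", nrow(recs), " aligned sequences from ", cfg$msa)

  grouping <- NULL
  row_groups <- NULL
  if (!is.null(cfg$group_rules)) {
    grouping <- stage("group", assign_groups(recs, cfg$group_rules,
                                             cfg$drop_patterns %||% character()))
    message("groups: ",
            paste(names(grouping$groups),
                  vapply(grouping$groups, length, integer(1)),
                  sep = "=", collapse = ", "),
            "; dropped ", length(grouping$dropped),
            ", unmatched ", length(grouping$unmatched))
    keep <- setdiff(recs$id, grouping$dropped)
    recs <- recs[recs$id %in% keep, ]
    class(recs) <- c("seq_set", "data.frame")
    row_groups <- unlist(lapply(names(grouping$groups), function(lab) {
      stats::setNames(rep(lab, length(grouping$groups[[lab]])),
                      grouping$groups[[lab]])
    }))
  }

  proj <- stage("project", project_to_reference(recs, cfg$reference_id, row_groups))
  outputs <- list()
  outputs$projection <- file.path(out_dir, "projection.fasta")
  write_projection(proj, outputs$projection,
                   map_path = file.path(out_dir, "site_map.tsv"))

  profiles <- list()
  group_labels <- if (!is.null(grouping)) names(grouping$groups) else list(NULL)
  for (lab in group_labels) {
    ids <- if (is.null(lab)) NULL else intersect(grouping$groups[[lab]], rownames(proj$ali))
    if (!is.null(ids) && length(ids) == 0) next
    prof <- stage("entropy", entropy_profile(proj, ids))
    tag <- if (is.null(lab)) "all" else lab
    profiles[[tag]] <- prof
    tab <- conserved_sites(prof, s_max = cfg$s_highly, frac_min = cfg$frac_min)
    outputs[[paste0("conserved_", tag)]] <-
      file.path(out_dir, paste0("conserved_", tag, ".tsv"))
    write_conserved_tsv(tab, outputs[[paste0("conserved_", tag)]])
    message("group ", tag, ": ", nrow(tab), " sites with S <= ", cfg$s_highly,
            " and frac > ", cfg$frac_min)
  }

  divergence <- NULL
  if (!is.null(cfg$contrast)) {
    if (length(cfg$contrast) != 2) stop("config error: 'contrast' needs two group labels")
    divergence <- stage("divergence",
      divergence_profile(proj, cfg$contrast[[1]], cfg$contrast[[2]],
                         pseudocount = cfg$pseudocount,
                         s_conserved = cfg$s_conserved))
    outputs$divergence <- file.path(out_dir, "divergence.tsv")
    write_divergence_tsv(divergence, outputs$divergence,
                         group_names = unlist(cfg$contrast))
  }

  representatives <- NULL
  if (!is.null(cfg$k_representatives) &&
      cfg$k_representatives < nrow(proj$ali)) {
    dm <- stage("distance", pairwise_identity_matrix(proj$ali))
    keep <- stage("reduce", select_representatives(dm, cfg$k_representatives))
    representatives <- recs[recs$id %in% keep, ]
    class(representatives) <- c("seq_set", "data.frame")
    outputs$representatives <- file.path(out_dir, "representatives.fasta")
    write_fasta(representatives, outputs$representatives)
    message("reduced ", nrow(proj$ali), " sequences to ",
            length(keep), " representatives")
  }

  write_manifest(out_dir, cfg, list(msa = cfg$msa), outputs)
  invisible(list(projection = proj, grouping = grouping, profiles = profiles,
                 divergence = divergence, representatives = representatives,
                 outputs = outputs))
}

#' Run the structure-analysis pipeline
#'
#' Reads the wild-type structure and any variant structures, writes the
#' inter-helix contact network with both count conventions, per-variant
#' C-alpha deviation tables, a conservation-painted PDB (when a profile is
#' supplied), and the disease-mutation overlap table.
#'
#' Config keys used: \code{wildtype} (PDB path), \code{variants} (named list
#' label -> PDB path), \code{helices} (list of \code{name}/\code{chain}/
#' \code{start}/\code{end}), \code{contact} (\code{h_max}, \code{angle_min},
#' \code{i_max}), \code{cmt_sites}, \code{focus} (e.g. a6-a7 loop residues),
#' \code{profile_tsv} or a \code{conservation_profile} under \code{profile},
#' \code{chain}, \code{scale}, \code{s_highly}, \code{out_dir}.
#'
#' @param cfg A \code{run_config} (or plain list).
#' @return Invisible list of result objects and output paths.
#' @export
run_structure_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$wildtype)) stop("config error: 'wildtype' (PDB path) is required")
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  inputs <- list(wildtype = cfg$wildtype)

  wt <- stage("read_wildtype", read_structure(cfg$wildtype))
  crit <- contact_criteria(h_max = cfg$contact$h_max %||% 3.5,
                           angle_min = cfg$contact$angle_min %||% 90,
                           i_max = cfg$contact$i_max %||% 4.0)

  network <- NULL
  if (!is.null(cfg$helices)) {
    hx <- stage("helices", helix_annotation(
      name = vapply(cfg$helices, `[[`, "", "name"),
      chain = vapply(cfg$helices, function(h) h$chain %||% (cfg$chain %||% "A"), ""),
      start = vapply(cfg$helices, function(h) as.integer(h$start), integer(1)),
      end = vapply(cfg$helices, function(h) as.integer(h$end), integer(1))))
    network <- stage("network", helix_network_report(wt, hx, crit))
    outputs$network <- file.path(out_dir, "network_edges.tsv")
    write_network_tsv(network$edges, outputs$network)
    outputs$network_counts <- file.path(out_dir, "network_counts.tsv")
    utils::write.table(network$pair_counts, outputs$network_counts,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message("inter-helix contacts: ", network$n_residue_pairs,
            " residue pairs / ", network$n_atom_pairs, " atom pairs")
  }

  deviations <- list()
  for (lab in names(cfg$variants %||% list())) {
    inputs[[lab]] <- cfg$variants[[lab]]
    var <- stage(paste0("read_", lab), read_structure(cfg$variants[[lab]]))
    dev <- stage(paste0("deviation_", lab),
                 ca_deviation_profile(var, wt, chain = cfg$chain))
    deviations[[lab]] <- dev
    outputs[[paste0("deviation_", lab)]] <-
      file.path(out_dir, paste0("deviation_", lab, ".tsv"))
    utils::write.table(as.data.frame(dev), outputs[[paste0("deviation_", lab)]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message("variant ", lab, ": fit RMSD ",
            formatC(attr(dev, "rmsd"), format = "f", digits = 3), " A over ",
            nrow(dev), " residues")
  }

  profile <- cfg$profile
  if (is.null(profile) && !is.null(cfg$profile_tsv)) {
    inputs$profile <- cfg$profile_tsv
    tab <- utils::read.delim(cfg$profile_tsv)
    profile <- data.frame(site = tab[[1]], entropy = as.numeric(tab[[2]]),
                          nongap_fraction = as.numeric(tab[[3]]),
                          consensus = as.character(tab[[4]]),
                          n_observed = NA_integer_)
    class(profile) <- c("conservation_profile", "data.frame")
  }

  painted <- NULL
  if (!is.null(profile)) {
    painted <- stage("paint", map_scores_to_structure(
      wt, profile, chain = cfg$chain %||% "A", scale = cfg$scale))
    outputs$painted <- file.path(out_dir, "conservation_painted.pdb")
    write_structure(painted, outputs$painted)
    if (length(attr(painted, "unpainted")) > 0) {
      message("residues without a conservation value (sentinel B-factor): ",
              paste(utils::head(attr(painted, "unpainted"), 10), collapse = ", "),
              if (length(attr(painted, "unpainted")) > 10) ", ..." else "")
    }
  }

  overlap <- NULL
  if (!is.null(cfg$cmt_sites) && !is.null(profile)) {
    overlap <- stage("overlap", mutation_overlap_report(
      if (!is.null(network)) network$edges else NULL,
      profile, as.integer(unlist(cfg$cmt_sites)),
      s_max = cfg$s_highly,
      focus = if (!is.null(cfg$focus)) as.integer(unlist(cfg$focus)) else NULL))
    outputs$overlap <- file.path(out_dir, "mutation_overlap.tsv")
    utils::write.table(overlap$classes, outputs$overlap, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  write_manifest(out_dir, cfg, inputs, outputs)
  invisible(list(wildtype = wt, network = network, deviations = deviations,
                 painted = painted, overlap = overlap, outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
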