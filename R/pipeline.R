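#' Analysis configuration
#'
#' Collects every tunable of the workflow with the analysis constants as
#' defaults: three protein rotamer states on 120-degree bins, the DNA
#' syn/anti split at 140/330 degrees, the ten-transition retention filter,
#' a dynamical-memory reporting threshold of 4, an inter-residue coupling
#' threshold of 2, 0.5 nm distance bins to 10 nm, and 2000 permutations.
#' Configurations round-trip losslessly through YAML.
#'
#' @param angle_files character vector of angle-matrix files (one per
#'   replica), the precomputed-series input path.
#' @param topology,trajectories alternative trajectory input: a PDB topology
#'   and one coordinate file per replica.
#' @param polymer \code{"protein"} or \code{"dna"} (selects dihedral type
#'   and state alphabet).
#' @param protein_boundaries,dna_boundaries state-bin cut points, degrees.
#' @param min_transitions retention filter (per replica).
#' @param memory_threshold dynamical-memory cutoff for [memory_report()].
#' @param coupling_threshold activity cutoff for coupled pairs.
#' @param mi_threshold_frac MI cutoff as a fraction of its off-diagonal max.
#' @param bin_width_nm,max_dist_nm distance-profile bins.
#' @param n_permutations circular-shift draws for p-values.
#' @param max_tested_pairs cap on pairs sent to the permutation test.
#' @param frame_interval trajectory frame spacing (ps) when no sidecar
#'   states it.
#' @param stride frame subsampling for trajectory extraction.
#' @param seed root seed; every random stage derives from it.
#' @param outdir output directory for [run_condact()].
#' @return object of class \code{"condact_config"} (a named list).
#' @export
condact_config <- function(angle_files = character(0),
                           topology = NULL, trajectories = character(0),
                           polymer = c("protein", "dna"),
                           protein_boundaries = c(0, 120, 240, 360),
                           dna_boundaries = c(140, 330),
                           min_transitions = 10L,
                           memory_threshold = 4,
                           coupling_threshold = 2,
                           mi_threshold_frac = 0.2,
                           bin_width_nm = 0.5, max_dist_nm = 10,
                           n_permutations = 2000L,
                           max_tested_pairs = 20L,
                           frame_interval = 1,
                           stride = 1L,
                           seed = 1L,
                           outdir = "condact_out") {
  polymer <- match.arg(polymer)
  cfg <- list(angle_files = as.character(angle_files),
              topology = topology,
              trajectories = as.character(trajectories),
              polymer = polymer,
              protein_boundaries = protein_boundaries,
              dna_boundaries = dna_boundaries,
              min_transitions = as.integer(min_transitions),
              memory_threshold = memory_threshold,
              coupling_threshold = coupling_threshold,
              mi_threshold_frac = mi_threshold_frac,
              bin_width_nm = bin_width_nm, max_dist_nm = max_dist_nm,
              n_permutations = as.integer(n_permutations),
              max_tested_pairs = as.integer(max_tested_pairs),
              frame_interval = frame_interval,
              stride = as.integer(stride),
              seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "condact_config"
  cfg
}

#' @rdname condact_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "condact_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname condact_config
#' @param cfg a \code{"condact_config"}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- unclass(do.call(condact_config, raw[setdiff(names(raw), "topology")]))
  cfg["topology"] <- list(raw$topology)   # preserve an explicit NULL
  structure(cfg[names(unclass(condact_config()))], class = "condact_config")
}

.alphabet_from_config <- function(cfg) {
  if (cfg$polymer == "protein") protein_alphabet(cfg$protein_boundaries)
  else dna_alphabet(cfg$dna_boundaries)
}

#' Run the full conditional-activity workflow
#'
#' Stages, in order: load or extract dihedral series (one input per
#' replica), discretize into states, detect transitions, apply the
#' minimum-transition filter, fit the conditional-activity matrix per
#' replica, pool replicas, compute the mutual-information matrices,
#' permutation p-values for the strongest couplings, eigen-domain scores,
#' and (when a topology is available) the distance profile.  All artifacts
#' are written to \code{cfg$outdir} as delimited text plus a JSON manifest
#' with content hashes and per-stage record counts.  Identical config and
#' seed reproduce identical outputs.
#'
#' @param cfg a [condact_config()].
#' @param positions optional precomputed residue positions (nm) for the
#'   distance profile, bypassing the topology.
#' @param grouping optional named character vector (residue key -> group)
#'   for a [memory_report()].
#' @return invisibly, a list with \code{fits} (per replica), \code{pooled},
#'   \code{mi}, \code{domains}, \code{couplings}, \code{profile},
#'   \code{memory_report}, \code{manifest}.
#' @export
run_condact <- function(cfg, positions = NULL, grouping = NULL) {
  stopifnot(inherits(cfg, "condact_config"))
  set.seed(cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  alphabet <- .alphabet_from_config(cfg)
  counts <- list()

  ## stage: load / extract per-replica angle series
  series_by_rep <- if (length(cfg$angle_files)) {
    lapply(cfg$angle_files, read_angle_matrix,
           frame_interval = cfg$frame_interval)
  } else if (!is.null(cfg$topology) && length(cfg$trajectories)) {
    extract <- if (cfg$polymer == "protein") extract_chi1 else extract_glycosidic
    lapply(cfg$trajectories, function(tr)
      extract(cfg$topology, tr, stride = cfg$stride,
              frame_interval = cfg$frame_interval))
  } else stop("stage extract: config needs angle_files or topology + trajectories")
  n_rep <- length(series_by_rep)
  counts$extracted <- vapply(series_by_rep, length, integer(1))

  ## stage: discretize + detect + filter, per replica
  records_by_rep <- vector("list", n_rep)
  states_by_rep <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    st <- lapply(series_by_rep[[r]], function(s) {
      ss <- discretize_angles(s, alphabet)
      ss$replica <- r
      ss
    })
    recs <- lapply(st, detect_transitions)
    recs <- filter_min_transitions(recs, cfg$min_transitions, quiet = TRUE)
    kept <- vapply(recs, `[[`, character(1), "key")
    records_by_rep[[r]] <- recs
    states_by_rep[[r]] <- st[kept]
  }
  counts$retained <- vapply(records_by_rep, length, integer(1))
  if (any(counts$retained < 2L)) {
    # degenerate but not an error: report the counts and stop gracefully
    manifest <- list(
      package_version = as.character(utils::packageVersion("condact")),
      seed = cfg$seed, n_replicas = n_rep, counts = counts,
      status = sprintf(
        "fewer than two residues retained (min_transitions = %d); no matrices computed",
        cfg$min_transitions),
      files = list())
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    warning(manifest$status, call. = FALSE)
    return(invisible(list(fits = NULL, pooled = NULL, mi = NULL,
                          domains = NULL, couplings = NULL, profile = NULL,
                          memory_report = NULL, manifest = manifest,
                          records = records_by_rep)))
  }

  ## stage: activity per replica, then pool
  fits <- lapply(records_by_rep, condact)
  pooled <- if (n_rep > 1L) pool_replicas(fits) else fits[[1L]]

  ## stage: mutual information
  mis <- lapply(states_by_rep, mi_matrix)

  ## stage: permutation significance on the strongest couplings (replica 1)
  couplings <- coupling_table(fits[[1L]], records_by_rep[[1L]],
                              min_A = cfg$coupling_threshold,
                              max_pairs = cfg$max_tested_pairs,
                              n_permutations = cfg$n_permutations,
                              seed = cfg$seed + 1000L)

  ## stage: eigendomains on the pooled matrix
  domains <- eigendomains(pooled)

  ## stage: spatial profile (needs positions)
  if (is.null(positions) && !is.null(cfg$topology)) {
    positions <- residue_positions(cfg$topology,
                                   series = series_by_rep[[1L]])
  }
  profile <- if (!is.null(positions)) {
    distance_profile(lapply(fits, `[[`, "activity"), positions,
                     mi_matrices = mis,
                     ca_threshold = cfg$coupling_threshold,
                     mi_threshold_frac = cfg$mi_threshold_frac,
                     bin_width = cfg$bin_width_nm,
                     max_dist = cfg$max_dist_nm)
  } else NULL

  mem_report <- if (!is.null(grouping))
    memory_report(pooled, grouping, cfg$memory_threshold) else NULL

  ## stage: write artifacts + manifest
  files <- character(0)
  wr <- function(fun, obj, name) {
    p <- file.path(cfg$outdir, name)
    fun(obj, p)
    files <<- c(files, p)
    p
  }
  for (r in seq_len(n_rep)) {
    wr(write_transition_records, records_by_rep[[r]],
       sprintf("transitions_rep%d.tsv", r))
    wr(write_matrix_txt, fits[[r]]$activity,
       sprintf("activity_rep%d.tsv", r))
    wr(write_matrix_txt, mis[[r]], sprintf("mi_rep%d.tsv", r))
  }
  wr(write_matrix_txt, pooled$activity, "activity_pooled.tsv")
  if (!is.null(pooled$sem))
    wr(write_matrix_txt, pooled$sem, "activity_sem.tsv")
  wr(function(x, p) utils::write.table(
       data.frame(key = names(x$scores), score = x$scores),
       p, sep = "\t", row.names = FALSE, quote = FALSE),
     domains, "eigendomains.tsv")
  wr(function(x, p) utils::write.table(x, p, sep = "\t", row.names = FALSE,
                                       quote = FALSE),
     couplings, "couplings.tsv")
  if (!is.null(profile))
    wr(function(x, p) utils::write.table(as.data.frame(x), p, sep = "\t",
                                         row.names = FALSE, quote = FALSE),
       profile, "distance_profile.tsv")
  if (!is.null(mem_report))
    wr(function(x, p) utils::write.table(x, p, sep = "\t", row.names = FALSE,
                                         quote = FALSE),
       mem_report, "memory_report.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("condact")),
    seed = cfg$seed,
    n_replicas = n_rep,
    counts = counts,
    matrix_orientation = "rows = affected residue X, columns = influencing Y",
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  mpath <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fits = fits, pooled = pooled, mi = mis, domains = domains,
                 couplings = couplings, profile = profile,
                 memory_report = mem_report,
                 manifest = manifest, records = records_by_rep))
}

#' Percentage of residues with high dynamical memory, per group
#'
#' For each residue group (histone subunit, tail vs core region, ...), the
#' percentage of retained residues whose dynamical memory (the diagonal of
#' the activity matrix) exceeds the threshold.
#'
#' @param x a \code{"condact"} fit or a square activity matrix.
#' @param grouping named character vector mapping residue keys to group
#'   names; keys absent from the fit are ignored, retained residues missing
#'   from the grouping fall into group \code{"(ungrouped)"}.
#' @param threshold dynamical-memory cutoff (default 4).
#' @return data.frame: \code{group}, \code{n_residues}, \code{n_above},
#'   \code{percent} (\code{NA} for empty groups).
#' @export
memory_report <- function(x, grouping, threshold = 4) {
  M <- if (inherits(x, "condact")) x$activity else as.matrix(x)
  mem <- diag(M)
  names(mem) <- rownames(M)
  grp <- grouping[names(mem)]
  grp[is.na(grp)] <- "(ungrouped)"
  groups <- unique(c(unique(unname(grouping)), unique(grp)))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- mem[grp == g & !is.na(mem)]
    data.frame(group = g, n_residues = length(v),
               n_above = sum(v > threshold),
               percent = if (length(v)) 100 * sum(v > threshold) / length(v)
                         else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
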