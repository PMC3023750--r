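# End-to-end orchestration: profile -> PPP -> optional SIMBAL -> optional
# ORF scan, with a JSON run manifest so every output table is regenerable
# from the recorded configuration.

#' Configuration for an end-to-end discovery run
#'
#' Inputs may come from files (proteome FASTAs + genome map, trait TSV,
#' tabular hits) or from a synthetic spec. Exactly one of
#' `synth` / (`collection_fastas` + `genome_map`) must be given.
#'
#' @param out_dir output directory for tables and the manifest.
#' @param target_genome genome to rank by PPP (default for a synthetic
#'   run: the first trait-positive genome).
#' @param synth optional [synth_spec()]; generates inputs in memory.
#' @param collection_fastas,genome_map file-based collection input.
#' @param profile_file trait TSV; alternatively `marker_members` derives
#'   the profile from marker protein identifiers.
#' @param marker_members marker protein identifiers (synthetic runs
#'   default to the generated marker family).
#' @param hits_file tabular (outfmt 6) hits, required when
#'   `engine = "tabular"`.
#' @param engine `"tabular"` (read `hits_file`), `"builtin"` (align with
#'   [rank_hits()]) or `"synthetic"` (model-based [synth_hit_lists()];
#'   synthetic runs only).
#' @param simbal optional list: `family` (truth family id or protein ids)
#'   and optionally `probe`, `min_len`, `len_step`, `pos_step`.
#' @param orf optional list: `motif` (pattern string), optionally
#'   `contigs` (FASTA path; synthetic runs use generated contigs),
#'   `min_aa`, `max_aa`.
#' @param seed run seed (synthetic stages re-derive their own seeds).
#' @param ppp a [ppp_config()].
#' @param align a [scoring_params()].
#' @return object of class `DiscoveryConfig`.
#' @export
discovery_config <- function(out_dir, target_genome = NULL, synth = NULL,
                             collection_fastas = NULL, genome_map = NULL,
                             profile_file = NULL, marker_members = NULL,
                             hits_file = NULL,
                             engine = c("tabular", "builtin", "synthetic"),
                             simbal = NULL, orf = NULL, seed = 1L,
                             ppp = ppp_config(), align = scoring_params()) {
  engine <- match.arg(engine)
  if (is.null(synth) && (is.null(collection_fastas) || is.null(genome_map)))
    stop("missing input: supply `synth` or `collection_fastas` + `genome_map`")
  if (engine == "tabular" && is.null(synth) && is.null(hits_file))
    stop("missing input: engine \"tabular\" requires `hits_file`")
  if (engine == "synthetic" && is.null(synth))
    stop("engine \"synthetic\" requires a synthetic spec")
  structure(list(out_dir = out_dir, target_genome = target_genome,
                 synth = synth, collection_fastas = collection_fastas,
                 genome_map = genome_map, profile_file = profile_file,
                 marker_members = marker_members, hits_file = hits_file,
                 engine = engine, simbal = simbal, orf = orf,
                 seed = as.integer(seed), ppp = ppp, align = align),
            class = "DiscoveryConfig")
}

#' Run the discovery workflow
#'
#' Executes, in order: input loading/generation, trait profile
#' construction, PPP ranking of the target genome, optional SIMBAL
#' heat-map of a probe against a trait-partitioned family, and optional
#' six-frame ORF / motif scanning. Each stage's output is written as TSV
#' under `out_dir`, and `manifest.json` records inputs, parameters, seed,
#' package version and per-stage status. A stage failure aborts the run
#' with the stage name; completed outputs are kept and a `FAILED` marker
#' file names the failing stage.
#'
#' @param config a [discovery_config()].
#' @return invisibly, a list with the stage results (`profile`, `ppp`,
#'   `simbal`, `orfs`) and the manifest.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "DiscoveryConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(); status <- character()
  results <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stages <<- c(stages, name); status <<- c(status, "FAILED")
      .write_manifest(config, stages, status)
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name); status <<- c(status, "PASS")
    res
  }

  inp <- run_stage("inputs", function() {
    if (!is.null(config$synth)) {
      bundle <- generate_collection(config$synth)
      list(bundle = bundle, collection = bundle$collection,
           contigs = bundle$contigs)
    } else {
      list(bundle = NULL,
           collection = read_fasta_collection(config$collection_fastas,
                                              config$genome_map),
           contigs = NULL)
    }
  })

  results$profile <- run_stage("profile", function() {
    if (!is.null(config$profile_file))
      read_profile(config$profile_file, inp$collection)
    else if (!is.null(config$marker_members))
      profile_from_marker(inp$collection, config$marker_members)
    else if (!is.null(inp$bundle))
      inp$bundle$profile
    else stop("no profile source: supply profile_file or marker_members")
  })
  write_profile(results$profile, file.path(config$out_dir, "profile.tsv"))

  results$ppp <- run_stage("ppp", function() {
    target <- config$target_genome %||% {
      if (is.null(inp$bundle)) stop("target_genome required")
      with(inp$bundle$truth$genomes, genome[trait][1L])
    }
    hits <- switch(config$engine,
      tabular = read_search_tabular(config$hits_file, inp$collection),
      builtin = {
        prots <- names(inp$collection$protein_index)[
          inp$collection$protein_index == target]
        stats::setNames(
          lapply(prots, rank_hits, collection = inp$collection,
                 params = config$align), prots)
      },
      synthetic = synth_hit_lists(inp$bundle, queries = target))
    tbl <- ppp_rank_genome(target, hits, results$profile, inp$collection,
                           config$ppp)
    write_ppp_table(tbl, file.path(config$out_dir, "ppp.tsv"),
                    meta = c(paste("target genome", target),
                             sprintf("profile %d/%d", results$profile$yes_count,
                                     results$profile$total)))
    tbl
  })

  if (!is.null(config$simbal)) {
    results$simbal <- run_stage("simbal", function() {
      sb <- config$simbal
      if (!is.null(inp$bundle) && length(sb$family) == 1L) {
        pr <- inp$bundle$truth$proteins
        fam_ids <- pr$protein[pr$group == pr$group[pr$family == sb$family][1L]]
      } else fam_ids <- sb$family
      seqs <- inp$collection$sequences[fam_ids]
      tr <- build_training(seqs, genome_of(inp$collection, fam_ids),
                           results$profile, params = config$align)
      probe_id <- sb$probe %||% fam_ids[1L]
      grid <- simbal_heatmap(
        stats::setNames(inp$collection$sequences[probe_id], probe_id), tr,
        params = config$align,
        min_len = sb$min_len %||% 8, len_step = sb$len_step %||% 4,
        pos_step = sb$pos_step %||% 2)
      write_simbal_grid(grid, file.path(config$out_dir, "simbal.tsv"))
      grid
    })
  }

  if (!is.null(config$orf)) {
    results$orfs <- run_stage("orfscan", function() {
      contigs <- if (!is.null(config$orf$contigs))
        Biostrings::readDNAStringSet(config$orf$contigs)
      else inp$contigs
      if (is.null(contigs)) stop("no contigs available for orfscan")
      orfs <- six_frame_orfs(contigs,
                             min_aa = config$orf$min_aa %||% 20,
                             max_aa = config$orf$max_aa %||% 120)
      hits <- scan_cterm_motif(orfs, config$orf$motif)
      write_orf_table(hits, file.path(config$out_dir, "orf_hits.tsv"),
                      meta = paste("motif", config$orf$motif))
      hits
    })
  }

  manifest <- .write_manifest(config, stages, status)
  results$manifest <- manifest
  invisible(results)
}

.write_manifest <- function(config, stages, status) {
  manifest <- list(
    package = "traitscan",
    version = as.character(utils::packageVersion("traitscan")),
    seed = config$seed,
    engine = config$engine,
    target_genome = config$target_genome,
    inputs = list(collection_fastas = config$collection_fastas,
                  genome_map = config$genome_map,
                  profile_file = config$profile_file,
                  hits_file = config$hits_file,
                  synth = if (!is.null(config$synth)) unclass(config$synth)),
    parameters = list(ppp = unclass(config$ppp),
                      simbal = config$simbal, orf = config$orf,
                      align = list(matrix = config$align$matrix_name,
                                   gap_open = config$align$gap_open,
                                   gap_extend = config$align$gap_extend,
                                   score_floor = config$align$score_floor)),
    stages = data.frame(stage = stages, status = status,
                        stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  manifest
}
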