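.PIPELINE_STAGES <- c("synth", "missingness", "diram", "dircod",
                      "abundance", "recreate", "axis", "diffcorr",
                      "characterize")

.CONFIG_KEYS <- c("seed", "out_dir", "input", .PIPELINE_STAGES)

# stable per-stage seed derived from the global seed and the stage name
.stageSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 8191 + h) %% 2147483647L)
}

#' Read and validate a pipeline run configuration
#'
#' A YAML file with optional keys `seed`, `out_dir`, `input` (paths
#' `matrix`, `phenotypes`) and one block per stage (`synth`,
#' `missingness`, `diram`, `dircod`, `abundance`, `recreate`, `axis`,
#' `diffcorr`, `characterize`) holding that stage's parameters. Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg
}

.writeTsv <- function(d, path, what, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(what, params), con)
  utils::write.table(as.data.frame(d), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the segmentation pipeline end to end
#'
#' Executes the requested stages in order over a shared state: a synthetic
#' or file-based cohort, the two clustering paths, abundance calls, and
#' the downstream recreation / axis / coregulation / characterization
#' analyses. Every stage writes delimited text with a `#` provenance line;
#' a manifest records each output's stage, parameters and MD5 hash, and
#' the resolved configuration is written next to the outputs. All
#' randomness derives from the global seed through stable per-stage
#' seeds, so a rerun with the same configuration is byte-identical.
#'
#' Stage dependencies are checked before execution: `missingness` (when
#' requested) must precede `diram`; a clustering stage must precede
#' `abundance` and `characterize`; `abundance` must precede `recreate`,
#' `axis` and `diffcorr`.
#'
#' @param config configuration list (see [readRunConfig()]).
#' @param stages ordered character vector of stages to run.
#' @return invisibly, the final pipeline state (matrix, phenotypes,
#'   assignments, calls, stage results).
#' @export
runPipeline <- function(config, stages = c("synth", "dircod", "abundance",
                                           "recreate")) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  pos <- function(s) match(s, stages)
  needBefore <- function(later, earlier, either = FALSE) {
    if (is.na(pos(later))) return(invisible())
    ok <- if (either) any(!is.na(pos(earlier)) & pos(earlier) < pos(later))
          else is.na(pos(earlier)) || pos(earlier) < pos(later)
    if (!ok)
      stop(sprintf("stage '%s' requires %s to run before it", later,
                   paste(earlier, collapse = " or ")))
  }
  needBefore("diram", "missingness")
  for (s in c("abundance", "characterize"))
    if (!is.na(pos(s)) &&
        !any(!is.na(pos(c("diram", "dircod"))) &
             stats::na.omit(pos(c("diram", "dircod"))) < pos(s)))
      stop(sprintf("stage '%s' requires a clustering stage before it", s))
  for (s in c("recreate", "axis", "diffcorr"))
    needBefore(s, "abundance")
  if (!"synth" %in% stages && is.null(config$input))
    stop("no 'synth' stage and no 'input' paths configured")

  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file, params) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)),
      params = paste(sprintf("%s=%s", names(params),
                             vapply(params, function(p)
                               paste(format(p), collapse = ","), "")),
                     collapse = ";"))
  }
  arg <- function(stage, name, default) {
    v <- config[[stage]][[name]]
    if (is.null(v)) default else v
  }
  state <- list()

  if (!"synth" %in% stages) {
    state$matrix <- readProteinMatrix(config$input$matrix)
    if (!is.null(config$input$phenotypes))
      state$phenotypes <- readPhenotypeTable(config$input$phenotypes)
  }

  for (stage in stages) {
    sseed <- .stageSeed(seed, stage)
    switch(stage,
      synth = {
        sc_args <- config$synth
        if (is.null(sc_args$seed)) sc_args$seed <- sseed
        sc <- do.call(SyntheticConfig, sc_args)
        cohort <- generateCohort(sc)
        state$matrix <- cohort$matrix
        state$phenotypes <- cohort$phenotypes
        state$truth <- cohort$truth
        f <- file.path(out_dir, "matrix.tsv")
        writeProteinMatrix(state$matrix, f)
        note(stage, f, list(seed = sc@seed))
        f <- file.path(out_dir, "phenotypes.tsv")
        writePhenotypeTable(state$phenotypes, f)
        note(stage, f, list(seed = sc@seed))
        f <- file.path(out_dir, "truth.tsv")
        .writeTsv(data.frame(participant_id = names(cohort$truth),
                             true_cluster = cohort$truth),
                  f, "truth", list(seed = sc@seed))
        note(stage, f, list(seed = sc@seed))
      },
      missingness = {
        thr <- arg(stage, "threshold", 0.5)
        mg <- arg(stage, "min_group_participants", 100L)
        state$grouping <- groupByMissingness(state$matrix, thr, mg)
        gp <- groupProteins(state$grouping)
        d <- data.frame(group_id = rep(names(gp), lengths(gp)),
                        protein_id = unlist(gp, use.names = FALSE))
        f <- file.path(out_dir, "groups.tsv")
        .writeTsv(d, f, "missingness_groups", list(threshold = thr))
        note(stage, f, list(threshold = thr,
                            min_group_participants = mg))
      },
      diram = {
        params <- list(similarity_threshold = arg(stage, "threshold", 0.5),
                       min_group_participants =
                         arg(stage, "min_group_participants", 100L),
                       eps = arg(stage, "eps", 0.1),
                       min_samples = arg(stage, "min_samples", 10L),
                       min_cluster_size = arg(stage, "min_size", 100L),
                       max_cluster_size = arg(stage, "max_size", 20000L),
                       merge_margin = arg(stage, "merge_margin", 0.4),
                       seed = sseed,
                       audit_seeds = arg(stage, "audit_seeds", 0L))
        state$assignments$DIRAM <- do.call(diramCluster,
                                           c(list(state$matrix), params))
        f <- file.path(out_dir, "diram_clusters.tsv")
        writeAssignments(state$assignments$DIRAM, f)
        note(stage, f, params)
      },
      dircod = {
        params <- list(T = arg(stage, "iterations", 20L),
                       alpha = arg(stage, "alpha", 0.05),
                       pattern_threshold =
                         arg(stage, "pattern_threshold", 0.9),
                       min_cluster_size = arg(stage, "min_size", 100L),
                       seed = sseed)
        state$assignments$DIRCOD <- do.call(dircodCluster,
                                            c(list(state$matrix), params))
        f <- file.path(out_dir, "dircod_clusters.tsv")
        writeAssignments(state$assignments$DIRCOD, f)
        note(stage, f, params)
        hist <- state$assignments$DIRCOD@provenance$history
        d <- data.frame(iteration = vapply(hist, function(h) h@iteration, 0L),
                        n_selected = vapply(hist, function(h)
                          length(h@selected_proteins), 0L),
                        n_communities = vapply(hist, function(h)
                          length(unique(h@community_of)), 0L))
        f <- file.path(out_dir, "history.tsv")
        .writeTsv(d, f, "dircod_history", params["T"])
        note(stage, f, params)
      },
      abundance = {
        method <- arg(stage, "method",
                      if (!is.null(state$assignments$DIRCOD)) "DIRCOD"
                      else "DIRAM")
        mo <- arg(stage, "min_observed", 20L)
        state$calls <- abundanceTable(state$matrix,
                                      state$assignments[[method]], mo)
        f <- file.path(out_dir, "calls.tsv")
        .writeTsv(state$calls, f, "abundance_calls",
                  list(method = method, min_observed = mo))
        note(stage, f, list(method = method, min_observed = mo))
      },
      recreate = {
        method <- arg(stage, "method", names(state$assignments)[1L])
        asg <- state$assignments[[method]]
        cl_ids <- arg(stage, "cluster_ids",
                      names(sort(clusterSizes(asg), decreasing = TRUE))[1L])
        direction <- arg(stage, "direction", "high")
        disease <- arg(stage, "disease", "I10")
        sig_prot <- commonSignature(state$calls, cl_ids, direction)
        if (!length(sig_prot))
          stop("recreate: empty common signature for the chosen clusters")
        signature <- data.frame(protein_id = sig_prot,
                                direction = direction)
        pooled <- unlist(lapply(cl_ids, function(cl)
          clusterMembers(asg, cl)))
        grid <- arg(stage, "percentiles", seq(5, 95, by = 5))
        curve <- if (isTRUE(arg(stage, "loo", FALSE)) &&
                     nrow(signature) >= 2L)
          leaveOneOut(state$matrix, state$phenotypes, pooled, signature,
                      disease, grid)
        else recreate(state$matrix, state$phenotypes, pooled, signature,
                      disease, grid)
        state$recreation <- curve
        d <- curveTable(curve)
        d$omitted <- "none"
        for (pn in names(looTables(curve))) {
          li <- looTables(curve)[[pn]]
          li$omitted <- pn
          d <- rbind(d, li[, colnames(d)])
        }
        f <- file.path(out_dir, "curve.tsv")
        .writeTsv(d, f, "recreation_curve",
                  list(disease = disease, direction = direction,
                       clusters = cl_ids))
        note(stage, f, list(disease = disease, method = method))
      },
      axis = {
        method <- arg(stage, "method", names(state$assignments)[1L])
        asg <- state$assignments[[method]]
        cl_ids <- arg(stage, "cluster_ids",
                      names(sort(clusterSizes(asg), decreasing = TRUE))[1L])
        direction <- arg(stage, "direction", "high")
        disease <- arg(stage, "disease", "I10")
        sig_prot <- commonSignature(state$calls, cl_ids, direction)
        if (length(sig_prot) < 1L)
          stop("axis: empty common signature for the chosen clusters")
        pooled <- unlist(lapply(cl_ids, function(cl)
          clusterMembers(asg, cl)))
        tr <- fitAxis(state$matrix, pooled, sig_prot,
                      standardize = arg(stage, "standardize", TRUE))
        ab <- binPrevalence(tr, state$matrix,
                            phenotypes = state$phenotypes,
                            disease_code = disease,
                            n_bins = arg(stage, "bins", 20L))
        state$axis <- ab
        f <- file.path(out_dir, "axis.tsv")
        .writeTsv(ab@bins, f, "axis_bins",
                  list(disease = disease, bins = nrow(ab@bins),
                       slope = ab@regression$slope))
        note(stage, f, list(disease = disease, method = method))
      },
      diffcorr = {
        method <- arg(stage, "method", names(state$assignments)[1L])
        asg <- state$assignments[[method]]
        cl_ids <- arg(stage, "cluster_ids",
                      names(sort(clusterSizes(asg), decreasing = TRUE))[1L])
        direction <- arg(stage, "direction", "high")
        cand <- commonSignature(state$calls, cl_ids, direction,
                                tolerance = 1L)
        pooled <- unlist(lapply(cl_ids, function(cl)
          clusterMembers(asg, cl)))
        kept <- prefilterProteins(state$matrix, cand,
                                  r_keep = arg(stage, "r_keep", 0.8))
        if (length(kept) < 2L)
          stop("diffcorr: fewer than 2 proteins survive the prefilter")
        dc <- differentialCorrelation(state$matrix, pooled, kept,
                                      min_pairs = arg(stage, "min_pairs",
                                                      30L))
        state$diffcorr <- dc
        d <- as.data.frame(deltaMatrix(dc))
        d <- cbind(protein_id = rownames(d), d)
        f <- file.path(out_dir, "delta.tsv")
        .writeTsv(d, f, "differential_correlation",
                  list(critical_r_in = dc@critical_r_in,
                       critical_r_out = dc@critical_r_out))
        note(stage, f, list(method = method, n_proteins = length(kept)))
      },
      characterize = {
        method <- arg(stage, "method", names(state$assignments)[1L])
        asg <- state$assignments[[method]]
        codes <- arg(stage, "codes",
                     sort(unique(unlist(icd10Codes(state$phenotypes)))))
        if (length(codes)) {
          enr <- diseaseEnrichment(asg, state$phenotypes, codes,
                                   stratify_sex = arg(stage, "by_sex",
                                                      FALSE))
          state$enrichment <- enr
          f <- file.path(out_dir, "enrichment.tsv")
          .writeTsv(enr, f, "disease_enrichment",
                    list(codes = codes, method = method))
          note(stage, f, list(method = method))
        }
        dem <- demographicContrast(asg, state$phenotypes)
        state$demographics <- dem
        f <- file.path(out_dir, "demographics.tsv")
        .writeTsv(dem, f, "demographic_contrast", list(method = method))
        note(stage, f, list(method = method))
      })
  }
  f <- file.path(out_dir, "manifest.tsv")
  .writeTsv(do.call(rbind, manifest), f, "manifest",
            list(seed = seed, stages = stages))
  cfg_resolved <- config
  cfg_resolved$seed <- seed
  cfg_resolved$stages <- stages
  yaml::write_yaml(cfg_resolved, file.path(out_dir, "config_resolved.yaml"))
  invisible(state)
}
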