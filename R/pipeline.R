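# End-to-end orchestration: scan -> mature peptides -> peak matching ->
# families -> phylogeny, with a serialisable config, a run log, and
# deterministic outputs.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the
#' experiment-level defaults: 600-4000 Da detection sieve, 300 ppm
#' precursor-mass tolerance, 0.6 Da fragment tolerance, score filter at
#' 20, similarity edges at p < 1e-5, 1000 bootstrap replicates with
#' collapse below 50.  Round-trips through YAML.
#'
#' @param fasta protein FASTA path (`NULL` to use `synthetic = TRUE`).
#' @param peaklist optional observed peak list (CSV/TSV).
#' @param alignment optional pre-aligned FASTA for phylogeny.
#' @param out_dir output directory for the artifact bundle.
#' @param sieve_low,sieve_high detection window in Da.
#' @param tol_ppm precursor-mass tolerance (ppm).
#' @param frag_tol fragment tolerance (Da).
#' @param score_threshold MS/MS significance score filter.
#' @param p_threshold clustering edge threshold.
#' @param bootstrap_reps,bootstrap_cutoff phylogeny bootstrap settings.
#' @param scan a [scan_config()].
#' @param synthetic run on a generated synthetic proteome instead of
#'   `fasta`, and score recovery against its ground truth.
#' @param seed RNG seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, peaklist = NULL,
                            alignment = NULL, out_dir = "neuropep_run",
                            sieve_low = 600, sieve_high = 4000,
                            tol_ppm = 300, frag_tol = 0.6,
                            score_threshold = 20, p_threshold = 1e-5,
                            bootstrap_reps = 1000, bootstrap_cutoff = 50,
                            scan = scan_config(), synthetic = is.null(fasta),
                            seed = 1L) {
  cfg <- structure(list(fasta = fasta, peaklist = peaklist,
                        alignment = alignment, out_dir = out_dir,
                        sieve_low = sieve_low, sieve_high = sieve_high,
                        tol_ppm = tol_ppm, frag_tol = frag_tol,
                        score_threshold = score_threshold,
                        p_threshold = p_threshold,
                        bootstrap_reps = bootstrap_reps,
                        bootstrap_cutoff = bootstrap_cutoff,
                        scan = scan, synthetic = isTRUE(synthetic),
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$sieve_low >= cfg$sieve_high)
    stop("config error: sieve bounds must satisfy low < high")
  if (cfg$tol_ppm <= 0 || cfg$frag_tol <= 0)
    stop("config error: tolerances must be positive")
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1)
    stop("config error: p_threshold must be in (0, 1]")
  if (cfg$bootstrap_reps < 1)
    stop("config error: bootstrap_reps must be >= 1")
  if (!cfg$synthetic && is.null(cfg$fasta))
    stop("config error: either a FASTA input or synthetic = TRUE")
  invisible(cfg)
}

#' Read / write a pipeline config as YAML
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  scan_args <- y$scan
  y$scan <- NULL
  do.call(pipeline_config,
          c(y, list(scan = do.call(scan_config,
                                   as.list(scan_args %||% list())))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$scan <- unclass(x$scan)
  yaml::write_yaml(x, path)
  invisible(path)
}

# Figure-style per-precursor summary table
summary_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    s <- a$summary
    data.frame(id = a$protein$id, n_peptides = s$n_peptides,
               n_amidated = s$n_amidated, n_acetylated = s$n_acetylated,
               n_pyroglu = s$n_pyroglu, has_signal = s$has_signal,
               top_repeat = s$top_repeat$peptide,
               top_repeat_count = s$top_repeat$count,
               score = a$score, ms_evidence = NA,
               stringsAsFactors = FALSE)
  }))
}

# all mature peptides of a set of annotations as one table
peptide_table <- function(annotations) {
  tabs <- lapply(annotations, `[[`, "peptides")
  tabs <- tabs[vapply(tabs, nrow, 0L) > 0]
  if (length(tabs) == 0) return(NULL)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Run the full mining pipeline
#'
#' Stages: (1) load or synthesise the proteome; (2) scan for precursor
#' candidates and mature their peptides; (3) if a peak list is present
#' (or synthetic), sieve it and match precursor masses at `tol_ppm`,
#' flagging MS evidence; (4) cluster all mature peptides into families;
#' (5) if an alignment is present, build the bootstrapped NJ tree.
#' Outputs (TSV/JSON/FASTA/Newick plus a log) land in `out_dir`; reruns
#' with the same config are identical.  Any stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`annotations`,
#'   `summary`, `matches`, `clusters`, `tree`, `recovery`, `paths`).
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- c(sprintf("neuropep pipeline, seed %d", config$seed),
                 sprintf("config hash: %s", config_hash(config)))
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  emit <- function(fname) {
    path <- file.path(out_dir, fname)
    written <<- c(written, path)
    path
  }

  # 1: inputs
  truth <- NULL
  proteome <- stage("input", {
    if (config$synthetic) {
      sp <- make_proteome(synthetic_spec(seed = config$seed))
      truth <- sp$truth
      log_lines <- c(log_lines, "input: synthetic proteome")
      sp$proteins
    } else {
      log_lines <- c(log_lines, paste("input:", config$fasta))
      read_fasta(config$fasta)
    }
  })

  # 2: scan + maturation
  annotations <- stage("scan",
    scan_proteome(proteome, default_motif_library(), config$scan))
  log_lines <- c(log_lines,
                 sprintf("scan: %d candidates of %d proteins (threshold %g)",
                         length(annotations), length(proteome),
                         config$scan$threshold))
  peptides <- peptide_table(annotations)
  summary <- summary_table(annotations)

  # 3: MS matching
  matches <- NULL
  if (!is.null(config$peaklist) || config$synthetic) {
    matches <- stage("mass_spec", {
      peaks <- if (!is.null(config$peaklist))
        read_peaklist(config$peaklist)
      else
        make_peaklist(structure(list(truth = truth,
                                     spec = synthetic_spec(seed = config$seed)),
                                class = "synthetic_proteome"))
      sieved <- mass_sieve(peaks, config$sieve_low, config$sieve_high)
      log_lines <- c(log_lines,
                     sprintf("mass_spec: %d/%d peaks pass the %g-%g sieve",
                             nrow(sieved), nrow(peaks), config$sieve_low,
                             config$sieve_high))
      if (is.null(peptides)) NULL else
        match_precursor_masses(sieved, peptides, config$tol_ppm)
    })
    if (!is.null(matches) && !is.null(summary)) {
      with_ev <- unique(peptides$precursor_id[
        peptides$sequence %in% matches$sequence])
      summary$ms_evidence <- summary$id %in% with_ev
    }
  }

  # 4: families
  clusters <- NULL
  if (!is.null(peptides) && nrow(peptides) >= 2) {
    clusters <- stage("families", {
      seqs <- peptides$sequence
      names(seqs) <- make.unique(paste0(peptides$precursor_id, ":",
                                        peptides$sequence))
      build_cluster_graph(seqs, p_threshold = config$p_threshold)
    })
    log_lines <- c(log_lines,
                   sprintf("families: %d components at p < %g",
                           length(clusters$components), config$p_threshold))
  }

  # 5: phylogeny
  tree <- NULL
  if (!is.null(config$alignment)) {
    tree <- stage("phylogeny", {
      aln <- read_fasta(config$alignment)
      seqs <- stats::setNames(vapply(aln, `[[`, "", "residues"),
                              vapply(aln, `[[`, "", "id"))
      bootstrap_support(seqs, n_reps = config$bootstrap_reps,
                        cutoff = config$bootstrap_cutoff,
                        seed = config$seed)
    })
    log_lines <- c(log_lines,
                   sprintf("phylogeny: %d replicates, cutoff %g",
                           config$bootstrap_reps, config$bootstrap_cutoff))
  }

  # 6: recovery vs truth
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(annotations, truth)
    log_lines <- c(log_lines,
                   sprintf("recovery: precursor P=%.3f R=%.3f",
                           recovery$precursor[["precision"]],
                           recovery$precursor[["recall"]]))
  }

  # write bundle
  paths <- stage("report", {
    p <- list()
    if (!is.null(peptides)) {
      hdr <- sprintf("%s|%d-%d ptm=%s", peptides$precursor_id,
                     peptides$start, peptides$end,
                     vapply(seq_len(nrow(peptides)), function(i)
                       ptm_tags(row_ptms(peptides[i, ])), ""))
      seqs <- stats::setNames(peptides$sequence, hdr)
      p$peptides_fasta <- write_fasta(seqs, emit("mature_peptides.fasta"))
    }
    if (!is.null(summary)) {
      p$summary <- emit("summary.tsv")
      utils::write.table(summary, p$summary, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    p$annotations <- emit("annotations.json")
    jsonlite::write_json(lapply(annotations, annotation_json),
                         p$annotations, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    if (!is.null(matches)) {
      p$matches <- emit("matches.tsv")
      utils::write.table(matches, p$matches, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    if (!is.null(clusters))
      p$clusters <- write_clusters(clusters, emit("clusters.tsv"))
    if (!is.null(tree))
      p$tree <- write_newick(tree, emit("tree.nwk"))
    if (!is.null(recovery)) {
      p$recovery <- emit("recovery.json")
      jsonlite::write_json(list(precursor = as.list(recovery$precursor),
                                peptide = as.list(recovery$peptide)),
                           p$recovery, auto_unbox = TRUE, digits = NA)
    }
    p$log <- emit("run.log")
    writeLines(log_lines, p$log)
    p
  })
  invisible(list(annotations = annotations, summary = summary,
                 matches = matches, clusters = clusters, tree = tree,
                 recovery = recovery, paths = paths))
}

config_hash <- function(config) {
  x <- unclass(config)
  x$scan <- unclass(x$scan)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%09d", h)
}

annotation_json <- function(a) {
  list(id = a$protein$id,
       length = nchar(a$protein$residues),
       score = a$score,
       signal = list(present = a$signal$present,
                     cleavage_pos = a$signal$cleavage_pos,
                     score = if (is.finite(a$signal$score))
                       a$signal$score else NULL),
       sites = a$sites,
       peptides = a$peptides,
       summary = list(n_peptides = a$summary$n_peptides,
                      n_amidated = a$summary$n_amidated,
                      n_acetylated = a$summary$n_acetylated,
                      n_pyroglu = a$summary$n_pyroglu,
                      has_signal = a$summary$has_signal,
                      top_repeat = a$summary$top_repeat))
}
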