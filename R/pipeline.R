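# End-to-end orchestration: simulate -> qc -> map -> quantify -> diff ->
# novel -> verify_ago -> signatures -> report, with a single global seed
# fanned out to per-stage seeds, a per-stage read-count funnel, and a run
# manifest with output file hashes.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage and per-library seeds are derived from
#'   it deterministically.
#' @param n_reads reads per condition library.
#' @param genome_length,n_known,n_novel,n_mrna synthetic genome design.
#' @param contaminants contaminant fractions (see [default_truth()]).
#' @param conditions condition names; the first is the baseline.
#' @param qc QC parameters ([qc_params()]).
#' @param threshold differential fold threshold (> 1).
#' @param m_mode multiplicity semantics for [quantify()].
#' @param quorum,flank novel-discovery settings ([consensus_detect()]).
#' @param stack_max_gap,stack_min_reads read-stack clustering settings.
#' @param ago_n_datasets,ago_depth,ago_supported_n Ago-RIP simulation: number
#'   of libraries, reads per supported candidate per library, and how many of
#'   the planted novel miRNAs carry Ago support.
#' @param ago_min_reads,ago_min_datasets verification thresholds.
#' @param n_perm GSEA permutations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mirnome_run_"), seed = 1L,
                            n_reads = 1e5, genome_length = 1e5,
                            n_known = 12L, n_novel = 10L, n_mrna = 4L,
                            contaminants = c(polyA = 0.03, ambiguous = 0.02,
                                             adapter5 = 0.02, mrna = 0.05),
                            conditions = c("vec", "kapb", "kapb_myc"),
                            qc = qc_params(), threshold = 1.5,
                            m_mode = "max", quorum = 3L, flank = 70L,
                            stack_max_gap = 10L, stack_min_reads = 5L,
                            ago_n_datasets = 2L, ago_depth = 10L,
                            ago_supported_n = 7L, ago_min_reads = 5L,
                            ago_min_datasets = 1L, n_perm = 1000L) {
  if (threshold <= 1) stop("config error: threshold must be > 1")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$contaminants)) vals$contaminants <-
      unlist(vals$contaminants)
  if (!is.null(vals$qc)) vals$qc <- do.call(qc_params, vals$qc)
  do.call(pipeline_config, vals)
}

pipeline_stages <- c("simulate", "qc", "map", "quantify", "diff", "novel",
                     "verify_ago", "signatures", "report")

stage_deps <- list(
  simulate = character(), qc = "simulate", map = "qc", quantify = "map",
  diff = "quantify", novel = "map", verify_ago = c("novel", "simulate"),
  signatures = "diff", report = "signatures")

#' Run the smRNA-Seq analysis pipeline
#'
#' Executes the requested stages in topological order on the synthetic study
#' defined by the configuration. Each stage logs its read/tag counts to the
#' funnel; re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate","qc","map","quantify","diff","novel","verify_ago",
#'   "signatures","report")`.
#' @param state results of a previous partial run, to satisfy stage
#'   dependencies when re-running a suffix of the pipeline.
#' @return invisibly, a list with all stage results, the `funnel`
#'   data.frame and the run `manifest` (stage, output files, md5 hashes).
#' @export
run_pipeline <- function(config, stages = pipeline_stages, state = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  env <- if (is.null(state)) new.env(parent = emptyenv()) else
    list2env(state, parent = emptyenv())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  funnel <- list()
  manifest <- list()
  outfile <- function(...) file.path(config$out_dir, ...)

  need <- function(stage) {
    for (dep in stage_deps[[stage]]) {
      if (!exists(paste0("done_", dep), envir = env, inherits = FALSE))
        stop("dependency error: stage '", stage, "' requires stage '",
             dep, "'")
    }
  }
  log_funnel <- function(stage, library, reads) {
    funnel[[length(funnel) + 1L]] <<-
      data.frame(stage = stage, library = library, reads = reads,
                 stringsAsFactors = FALSE)
  }
  finish <- function(stage, files) {
    assign(paste0("done_", stage), TRUE, envir = env)
    if (length(files) == 0) return(invisible())
    hash <- unname(tools::md5sum(files))
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, file = basename(files), md5 = hash,
                 stringsAsFactors = FALSE)
  }

  for (stage in stages) {
    need(stage)
    switch(stage,
      simulate = {
        sim <- build_simulation(config$genome_length, config$n_known,
                                config$n_novel, config$n_mrna,
                                seed = derive_seed(config$seed, 1L))
        truth <- default_truth(sim$mirnas, config$contaminants)
        env$sim <- sim; env$truth <- truth
        env$libraries <- lapply(seq_along(config$conditions), function(i) {
          cfg <- library_config(config$n_reads,
                                seed = derive_seed(config$seed, 10L + i))
          simulate_library(sim$mirnas, truth, cfg, config$conditions[i],
                           mrna = sim$mrna)
        })
        names(env$libraries) <- config$conditions
        novel_ids <- sim$mirnas$mirna_id[!sim$mirnas$is_known]
        env$ago_supported <- sort(novel_ids)[
          seq_len(min(config$ago_supported_n, length(novel_ids)))]
        env$ago_libraries <- simulate_agoip(
          sim$mirnas, env$ago_supported, config$ago_depth,
          config$ago_n_datasets, library_config(1L),
          seed = derive_seed(config$seed, 50L))
        files <- c(outfile("genome.fa"), outfile("known_mirnas.gff3"),
                   outfile("truth.tsv"))
        Biostrings::writeXStringSet(sim$genome, files[1])
        export_mirna_gff(sim$mirnas[sim$mirnas$is_known, , drop = FALSE],
                         files[2])
        write_truth(truth, files[3])
        mrna_fa <- outfile("mrna.fa")
        Biostrings::writeXStringSet(sim$mrna, mrna_fa)
        fq <- vapply(config$conditions, function(cn) {
          p <- outfile(paste0(cn, ".fastq"))
          write_fastq(env$libraries[[cn]], p)
          log_funnel("simulate", cn, nrow(env$libraries[[cn]]))
          p
        }, character(1))
        ago_fq <- vapply(seq_along(env$ago_libraries), function(d) {
          p <- outfile(sprintf("ago%02d.fastq", d))
          write_fastq(env$ago_libraries[[d]], p)
          p
        }, character(1))
        finish("simulate", c(files, mrna_fa, fq, ago_fq))
      },
      qc = {
        env$qc <- lapply(names(env$libraries), function(cn) {
          qc_reads(env$libraries[[cn]], params = config$qc)
        })
        names(env$qc) <- names(env$libraries)
        env$ago_qc <- lapply(env$ago_libraries, qc_reads,
                             params = config$qc)
        files <- character(0)
        for (cn in names(env$qc)) {
          fa <- outfile(paste0(cn, "_tags.fa"))
          write_tags_fasta(env$qc[[cn]]$tags, fa)
          js <- outfile(paste0(cn, "_qc.json"))
          jsonlite::write_json(as.list(env$qc[[cn]]$report), js,
                               auto_unbox = TRUE)
          files <- c(files, fa, js)
          log_funnel("qc", cn, sum(env$qc[[cn]]$tags$count))
        }
        finish("qc", files)
      },
      map = {
        known <- env$sim$mirnas[env$sim$mirnas$is_known, , drop = FALSE]
        env$refset <- reference_set(env$sim$genome, env$sim$mrna, known)
        env$annotations <- lapply(names(env$qc), function(cn) {
          ann <- annotate_tags(env$qc[[cn]]$tags, env$refset)
          log_funnel("map", cn,
                     sum(ann$count[ann$n_placements > 0]))
          ann
        })
        names(env$annotations) <- names(env$qc)
        env$ago_placements <- lapply(env$ago_qc, function(q) {
          place_tags(q$tags, env$refset)
        })
        files <- vapply(names(env$annotations), function(cn) {
          p <- outfile(paste0(cn, "_annotations.tsv"))
          write_tsv(env$annotations[[cn]], p)
          p
        }, character(1))
        finish("map", files)
      },
      quantify = {
        env$profiles <- lapply(names(env$annotations), function(cn) {
          quantify(env$annotations[[cn]], m_mode = config$m_mode)
        })
        names(env$profiles) <- names(env$annotations)
        files <- vapply(names(env$profiles), function(cn) {
          p <- outfile(paste0(cn, "_profile.tsv"))
          write_tsv(env$profiles[[cn]], p)
          log_funnel("quantify", cn, sum(env$profiles[[cn]]$C))
          p
        }, character(1))
        finish("quantify", files)
      },
      diff = {
        conds <- config$conditions
        base <- conds[1]
        pairs <- list()
        for (cn in conds[-1]) pairs[[paste0(cn, "_vs_", base)]] <-
            c(cn, base)
        if (length(conds) >= 3) {
          for (i in 3:length(conds)) {
            pairs[[paste0(conds[i], "_vs_", conds[i - 1])]] <-
              c(conds[i], conds[i - 1])
          }
        }
        env$calls <- lapply(names(pairs), function(lbl) {
          pr <- pairs[[lbl]]
          call_differential(env$profiles[[pr[1]]], env$profiles[[pr[2]]],
                            threshold = config$threshold, label = lbl)
        })
        names(env$calls) <- names(pairs)
        files <- vapply(names(env$calls), function(lbl) {
          p <- outfile(paste0("diff_", lbl, ".tsv"))
          write_tsv(env$calls[[lbl]]$folds, p)
          p
        }, character(1))
        finish("diff", files)
      },
      novel = {
        un <- lapply(env$annotations, function(ann) {
          tags <- ann[ann$category == "unannotated", , drop = FALSE]
          pl <- attr(ann, "placements")
          if (is.null(pl) || nrow(tags) == 0) {
            return(data.frame(tag_seq = character(), chrom = character(),
                              start = integer(), end = integer(),
                              strand = character(), count = integer(),
                              stringsAsFactors = FALSE))
          }
          pl <- pl[pl$tag_seq %in% tags$seq |
                     pl$tag_seq %in% tags$tag_seq, , drop = FALSE]
          pl$count <- tags$count[match(pl$tag_seq, tags$tag_seq)]
          pl
        })
        pooled <- do.call(rbind, un)
        if (nrow(pooled)) {
          key <- paste(pooled$tag_seq, pooled$chrom, pooled$start,
                       pooled$strand)
          agg <- stats::aggregate(count ~ key, pooled, sum)
          pooled <- pooled[!duplicated(key), , drop = FALSE]
          pooled$count <- agg$count[match(paste(pooled$tag_seq,
                                                pooled$chrom, pooled$start,
                                                pooled$strand), agg$key)]
        }
        env$stacks <- build_stacks(pooled, config$stack_max_gap,
                                   config$stack_min_reads)
        env$candidates <- consensus_detect(env$stacks, env$sim$genome,
                                           quorum = config$quorum,
                                           flank = config$flank)
        log_funnel("novel", "pooled",
                   if (nrow(env$candidates)) sum(env$candidates$total_count)
                   else 0L)
        p <- outfile("novel_candidates.tsv")
        write_tsv(env$candidates, p)
        finish("novel", p)
      },
      verify_ago = {
        env$candidates <- verify_agoip(env$candidates, env$ago_placements,
                                       config$ago_min_reads,
                                       config$ago_min_datasets)
        p <- outfile("novel_candidates_ago.tsv")
        write_tsv(env$candidates, p)
        finish("verify_ago", p)
      },
      signatures = {
        env$signatures <- lapply(env$calls, as_signature)
        conds <- config$conditions
        ov <- list()
        en <- list()
        if (length(conds) >= 3) {
          a <- paste0(conds[2], "_vs_", conds[1]) # e.g. kapb_vs_vec
          b <- paste0(conds[3], "_vs_", conds[1]) # e.g. kapb_myc_vs_vec
          ov[["up"]] <- overlap(env$signatures[[a]]$up,
                                env$signatures[[b]]$up)
          ov[["down"]] <- overlap(env$signatures[[a]]$down,
                                  env$signatures[[b]]$down)
          rk <- paste0(conds[3], "_vs_", conds[2])
          ranked <- env$calls[[rk]]$folds
          ranked <- ranked$mirna_id[radix_order(-ranked$fold,
                                                ranked$mirna_id)]
          for (dir in c("up", "down")) {
            gs <- env$signatures[[a]][[dir]]
            if (length(gs) > 0 && length(gs) < length(ranked) &&
                all(gs %in% ranked)) {
              en[[paste0(a, "_", dir)]] <-
                gsea_enrichment(ranked, gs, config$n_perm,
                                seed = derive_seed(config$seed, 90L))
            }
          }
        }
        env$overlaps <- ov; env$enrichments <- en
        assign("done_signatures", TRUE, envir = env)
        finish("signatures", character(0))
      },
      report = {
        nv <- if (!is.null(env$candidates) && nrow(env$candidates)) {
          list(n_candidates = nrow(env$candidates),
               n_consensus = sum(env$candidates$consensus),
               n_ago_verified = if ("ago_verified" %in%
                                      names(env$candidates))
                 sum(env$candidates$ago_verified) else 0L)
        } else NULL
        env$report <- signature_report(env$signatures, env$overlaps,
                                       env$enrichments, nv)
        files <- c(outfile("report.json"), outfile("report.tsv"),
                   outfile("funnel.tsv"))
        write_signature_report(env$report, files[1], files[2])
        write_tsv(do.call(rbind, funnel), files[3])
        finish("report", files)
      })
  }
  res <- as.list(env)
  res$funnel <- if (length(funnel)) do.call(rbind, funnel) else NULL
  res$manifest <- if (length(manifest)) do.call(rbind, manifest) else NULL
  invisible(res)
}

#' Verify the internal consistency of a published fold table
#'
#' Applies the ratio identity rpm_a/rpm_b == fold_a/fold_b
#' ([check_table_row()]) to every row of a table in the published layout
#' (name, RPM condition A, RPM condition B, fold A vs baseline, fold B vs
#' baseline). Transcriptions of both published top-50 tables ship with the
#' package (see `system.file("extdata", ..., package = "mirnome")`).
#'
#' @param table a data.frame in that layout or a path to a TSV file.
#' @param tol flagging residual (default 1e-3).
#' @return list: `rows` (per-row name, residual, consistent flag, implied
#'   baseline RPM, row error message if malformed), `n_rows`,
#'   `n_consistent`, `n_inconsistent`, `n_malformed`.
#' @export
verify_tables <- function(table, tol = 1e-3) {
  if (is.character(table)) {
    if (length(readLines(table, n = 1)) == 0) {
      return(list(rows = data.frame(), n_rows = 0L, n_consistent = 0L,
                  n_inconsistent = 0L, n_malformed = 0L))
    }
    table <- read_tsv(table)
  }
  if (nrow(table) == 0) {
    return(list(rows = data.frame(), n_rows = 0L, n_consistent = 0L,
                n_inconsistent = 0L, n_malformed = 0L))
  }
  if (ncol(table) < 5) stop("table needs a name column plus four values")
  rows <- lapply(seq_len(nrow(table)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(table[i, 2:5])))
    if (anyNA(v) || any(v <= 0)) {
      return(data.frame(name = as.character(table[i, 1]), residual = NA_real_,
                        consistent = NA, baseline_rpm = NA_real_,
                        error = "malformed row", stringsAsFactors = FALSE))
    }
    chk <- check_table_row(v[1], v[2], v[3], v[4], tol)
    data.frame(name = as.character(table[i, 1]), residual = chk$residual,
               consistent = chk$consistent, baseline_rpm = chk$baseline_rpm,
               error = "", stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  list(rows = rows, n_rows = nrow(rows),
       n_consistent = sum(rows$consistent, na.rm = TRUE),
       n_inconsistent = sum(!rows$consistent, na.rm = TRUE),
       n_malformed = sum(is.na(rows$consistent)))
}
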