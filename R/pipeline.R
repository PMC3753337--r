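#' Run the full breakpoint-analysis pipeline
#'
#' Orchestrates every stage on a seeded simulation: genome and
#' rearrangement simulation, mate-pair simulation, PEM-signature SV
#' detection, copy-number profiling, gene-impact annotation, junction
#' resolution, microhomology statistics, motif enrichment, RNA-seq
#' expression evidence and chromothripsis scoring. Stage outputs are
#' written as plain-text tables under `outdir` together with a JSON
#' manifest of parameters and seeds; any stage failure aborts with a
#' stage-labelled error and earlier outputs are preserved.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `seed` — master seed (all stage seeds derive from it);
#'   * `genome` — `n_chrom`, `lengths` (bp);
#'   * `rearrangements` — `mode` (`"simple"`/`"chromothripsis"`),
#'     `n_events`, optional `min_segment`;
#'   * `reads` — `coverage`, optional `insert_mean`, `insert_sd`,
#'     `read_len`;
#'   * `cnv` — optional `window_size` (default 10 kb);
#'   * `genes` — optional `n_genes` (default 20);
#'   * `outdir` — output directory (`NULL` to skip writing).
#' @return Invisibly, a named list ("report bundle") with every stage
#'   result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package.")
    }
    config <- yaml::read_yaml(config)
  }
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(x, name) {
    if (!is.null(outdir)) write_tsv_table(x, file.path(outdir, name))
    x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, ": ", conditionMessage(e)))
    })
  }
  seeds <- child_seeds(config$seed %||% 1L, 6)
  bundle <- list(config = config)

  bundle$genome <- stage("simulate", {
    simulate_genome(config$genome$n_chrom, config$genome$lengths,
                    seed = seeds[1])
  })
  bundle$genes <- stage("simulate", {
    simulate_gene_models(bundle$genome, config$genes$n_genes %||% 20,
                         seed = seeds[2])
  })
  bundle$plans <- stage("simulate", {
    plan_rearrangements(
      bundle$genome, mode = config$rearrangements$mode %||% "simple",
      n_events = config$rearrangements$n_events %||% 4,
      seed = seeds[3],
      min_segment = config$rearrangements$min_segment %||% 5e3
    )
  })
  bundle$derived <- stage("simulate",
                          render_derived_genome(bundle$genome, bundle$plans))
  ct_mode <- identical(config$rearrangements$mode, "chromothripsis")
  bundle$pairs <- stage("simulate", {
    r <- config$reads %||% list()
    pool <- sum(genome_lengths(bundle$genome)) * (1 + ct_mode)
    simulate_mate_pairs(
      bundle$derived,
      n_pairs = pairs_for_coverage(r$coverage %||% 10, pool,
                                   r$insert_mean %||% 3000),
      insert_mean = r$insert_mean %||% 3000,
      insert_sd = r$insert_sd %||% 300,
      read_len = r$read_len %||% 50,
      seed = seeds[4],
      include_reference_homolog = ct_mode
    )
  })
  bundle$insert_model <- stage("detect", fit_insert_model(bundle$pairs))
  bundle$links <- stage("detect", {
    emit(cluster_links(bundle$pairs, bundle$insert_model), "links.tsv")
  })
  bundle$profile <- stage("cnv", {
    prof <- window_counts(bundle$pairs,
                          config$cnv$window_size %||% 10000,
                          bundle$genome)
    prof <- normalize_and_segment(prof)
    emit(prof$segments, "cnv_segments.tsv")
    prof
  })
  bundle$annotated <- stage("annotate", {
    emit(annotate_links(bundle$links, bundle$genes), "links_annotated.tsv")
  })
  bundle$junctions <- stage("junction", {
    calls <- resolve_junctions(
      setNames(bundle$derived$truth$region_seq,
               bundle$derived$truth$junction_id),
      bundle$derived$reference
    )
    emit(calls, "junction_calls.tsv")
  })
  bundle$mh_report <- stage("mhtest", {
    calls <- bundle$junctions |>
      filter(.data$status == "ok") |>
      distinct(.data$read_id, .keep_all = TRUE) |>
      mutate(sample = "sim", chromothripsis = ct_mode)
    rep <- stratified_report(calls,
                             mh_null(base_frequencies(bundle$genome)))
    emit(rep$tests, "mh_tests.tsv")
    rep
  })
  bundle$motifs <- stage("motifs", {
    bps <- tibble(chrom = c(bundle$derived$truth$chromA,
                            bundle$derived$truth$chromB),
                  pos = c(bundle$derived$truth$posA,
                          bundle$derived$truth$posB))
    emit(motif_enrichment(bps, bundle$derived$reference,
                          n_background = 200, seed = seeds[5]),
         "motif_enrichment.tsv")
  })
  bundle$rna <- stage("rna", {
    eligible <- bundle$annotated |>
      filter(.data$category %in% RNA_ELIGIBLE)
    if (nrow(eligible) > 0) {
      expr <- setNames(rep(1, nrow(bundle$genes)), bundle$genes$gene_id)
      rna <- simulate_rnaseq_pairs(bundle$genes, expression = expr,
                                   n_pairs = 5000, seed = seeds[6])
      emit(transcript_evidence(bundle$annotated, rna, bundle$genes),
           "rna_evidence.tsv")
    } else {
      tibble()
    }
  })
  bundle$chromothripsis <- stage("shatterscan", {
    emit(chromothripsis_score(bundle$profile, bundle$links),
         "chromothripsis.tsv")
  })
  if (!is.null(outdir)) {
    stage("report", {
      write_truth_junctions(bundle$derived$truth,
                            file.path(outdir, "truth_junctions.tsv"),
                            file.path(outdir, "truth_junctions.fa"))
      manifest <- list(
        package = "svbreaks",
        version = as.character(utils::packageVersion("svbreaks")),
        seed = config$seed %||% 1L, stage_seeds = seeds,
        config = config[setdiff(names(config), "outdir")]
      )
      if (requireNamespace("jsonlite", quietly = TRUE)) {
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    })
  }
  invisible(bundle)
}
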