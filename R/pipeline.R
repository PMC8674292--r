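# End-to-end orchestration: io -> jei -> events/psi -> psiexons -> scan ->
# nmd -> kmer, driven by one config holding every threshold. Threshold
# defaults are the study's printed values, centralised so sensitivity
# analyses are one-line edits.

#' Pipeline run configuration
#'
#' @param genome,annotation,junctions,manifest Input paths (FASTA, GTF,
#'   generic junction TSV, manifest TSV).
#' @param expression Optional externally computed differential-expression
#'   TSV (gene_id, log2fc, fdr, base_mean).
#' @param acceptor_model Optional serialised PWM acceptor model path; when
#'   `NULL` one is trained from the annotation.
#' @param control,treated Group labels.
#' @param out_dir Output directory.
#' @param dpsi_threshold,p_threshold PSI call thresholds (20, 0.001).
#' @param min_denominator PSI denominator floor (20).
#' @param jei_reduction,jei_p JEI flag thresholds (25, 0.05).
#' @param fold_threshold,fdr_threshold Expression thresholds (1.5, 0.05).
#' @param scan_min_len,scan_max_len,scan_min_score Scan filters (6, 200, 2.3).
#' @param seed Seed recorded in the run manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, annotation, junctions, manifest,
                       expression = NULL, acceptor_model = NULL,
                       control = "DMSO", treated = "treated",
                       out_dir = "pipeline_out",
                       dpsi_threshold = 20, p_threshold = 0.001,
                       min_denominator = 20,
                       jei_reduction = 25, jei_p = 0.05,
                       fold_threshold = 1.5, fdr_threshold = 0.05,
                       scan_min_len = 6, scan_max_len = 200,
                       scan_min_score = 2.3, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order and writes per-stage TSV/BED
#' outputs plus a run manifest (input checksums, thresholds, per-stage row
#' counts) under `config$out_dir`. Any missing input fails pre-flight,
#' before computation.
#'
#' @param config A [run_config()].
#' @return Invisible list of stage results (introns, jei, events, psi,
#'   psiexons, scan, nmd, kmer, expression).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ins <- c(genome = config$genome, annotation = config$annotation,
           junctions = config$junctions, manifest = config$manifest)
  if (!is.null(config$expression)) ins["expression"] <- config$expression
  if (!is.null(config$acceptor_model)) ins["acceptor_model"] <- config$acceptor_model
  missing <- ins[!file.exists(ins)]
  if (length(missing)) {
    stop("pre-flight failure, missing input(s): ",
         paste(names(missing), missing, sep = "=", collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  wtsv <- function(x, f) {
    utils::write.table(x, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  genome <- stage("io", read_genome(config$genome))
  anno <- stage("io", read_annotation(config$annotation, "gtf"))
  jt <- stage("io", read_junctions(config$junctions, "tsv"))
  mf <- stage("io", read_manifest(config$manifest))
  jt <- stage("io", resolve_junction_strands(jt, anno))
  introns <- stage("io", derive_introns(anno))

  jei <- stage("jei", compare_jei_groups(
    jt, introns, mf, control = config$control, treated = config$treated,
    reduction_threshold = config$jei_reduction, p_threshold = config$jei_p))
  wtsv(jei, "jei.tsv")

  events <- stage("events", build_event_catalog(jt, anno))
  wtsv(events, "events.tsv")
  psi <- stage("events", psi_table(
    events, jt, mf, config$control, config$treated,
    min_denominator = config$min_denominator,
    dpsi_threshold = config$dpsi_threshold, p_threshold = config$p_threshold))
  wtsv(psi, "psi.tsv")
  wtsv(psi[, c("event_id", "kind", "dpsi", "p", "call", "call_reason")],
       "calls.tsv")

  px <- stage("psiexons", classify_psiexons(events, psi, anno, genome))
  wtsv(px, "psiexons.tsv")
  if (nrow(px)) {
    write_psiexon_bed(px[px$is_psiexon, , drop = FALSE],
                      file.path(config$out_dir, "psiexons.bed"))
  }

  acc_model <- stage("scores", {
    if (!is.null(config$acceptor_model)) read_pwm_model(config$acceptor_model)
    else {
      w <- annotated_ss_windows(anno, genome)
      train_pwm_fallback(w$acceptor23, "acceptor23",
                         min_sites = min(50, length(w$acceptor23)))
    }
  })
  scan <- stage("scan", scan_introns(
    genome, introns, acc_model, annos = anno,
    min_len = config$scan_min_len, max_len = config$scan_max_len,
    min_acceptor_score = config$scan_min_score))
  wtsv(scan, "scan.tsv")
  if (nrow(scan)) write_scan_bed(scan, file.path(config$out_dir, "scan.bed"))

  nmd <- stage("nmd", {
    tgt <- px[px$is_psiexon, , drop = FALSE]
    if (nrow(tgt)) {
      classify_nmd_batch(
        data.frame(event_id = tgt$event_id, contig = tgt$contig,
                   strand = tgt$strand, start = tgt$exon_start,
                   end = tgt$exon_end, stringsAsFactors = FALSE),
        anno, genome)
    } else data.frame()
  })
  wtsv(nmd, "nmd.tsv")

  kmer <- stage("kmer", {
    inc <- events[events$event_id %in% psi$event_id[psi$call == "Inc"] &
                  events$kind == "CE", , drop = FALSE]
    nc <- events[events$event_id %in% psi$event_id[psi$call == "NC"] &
                 events$kind == "CE", , drop = FALSE]
    if (nrow(inc) && nrow(nc)) {
      kmer_enrichment_scan(inc, nc, genome)
    } else data.frame()
  })
  wtsv(kmer, "kmer.tsv")

  expr <- NULL
  if (!is.null(config$expression)) {
    expr <- stage("expression", {
      e <- read_expression_table(config$expression)
      volcano_classify(e, config$fold_threshold, config$fdr_threshold)
    })
    wtsv(expr, "expression_labels.tsv")
  }

  counts <- c(introns = nrow(introns), jei = nrow(jei), events = nrow(events),
              psi = nrow(psi), psiexons = nrow(px), scan = nrow(scan),
              nmd = nrow(nmd), kmer = nrow(kmer))
  manifest <- c(
    sprintf("pipeline: psiexon %s",
            as.character(utils::packageVersion("psiexon"))),
    sprintf("seed: %d", config$seed),
    sprintf("input %s: %s md5=%s", names(ins), ins,
            unname(tools::md5sum(ins))),
    sprintf("threshold %s: %s",
            c("dpsi", "p", "min_denominator", "jei_reduction", "jei_p",
              "fold", "fdr", "scan_min_len", "scan_max_len", "scan_min_score"),
            c(config$dpsi_threshold, config$p_threshold,
              config$min_denominator, config$jei_reduction, config$jei_p,
              config$fold_threshold, config$fdr_threshold,
              config$scan_min_len, config$scan_max_len,
              config$scan_min_score)),
    sprintf("rows %s: %d", names(counts), counts))
  writeLines(manifest, file.path(config$out_dir, "run_manifest.txt"))

  invisible(list(introns = introns, jei = jei, events = events, psi = psi,
                 psiexons = px, scan = scan, nmd = nmd, kmer = kmer,
                 expression = expr))
}
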