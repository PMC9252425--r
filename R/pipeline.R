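# End-to-end pipeline driver over the synthetic inputs, with a run manifest.

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline with their standard defaults
#' (TPM floor 5, 2-fold / FDR 0.05 differential-expression cut-offs,
#' 16,000 retained edges, 0.8 motif presence fraction, 100 trees). Unknown
#' keys are rejected.
#'
#' @param ... Overrides of the defaults; see the returned list for the
#'   available keys.
#' @return Named list of configuration values (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "mybscope_run",
    # synthetic-data sizes
    n_true_r2r3 = 12L, n_decoys_per_kind = 3L, mutation_rate = 0.05,
    n_genes = 30L, n_grn_genes = 40L, n_tfs = 6L, n_grn_samples = 40L,
    grn_noise_sd = 0.3,
    # thresholds (standard defaults)
    score_threshold_bits = 50, tpm_threshold = 5, fc_threshold = 2,
    de_alpha = 0.05, top_k = 16000L, motif_threshold = 0.8,
    n_trees = 100L, min_reps = 3L, go_min_size = 10L, go_max_size = 1000L,
    go_permutations = 200L, go_alpha = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes the stages in dependency order — synthetic-data generation,
#' domain scanning and classification, family curation and naming, motif
#' scanning and clade classification, qPCR quantification, GRN inference
#' with sub-network extraction and GO enrichment — writing every stage's
#' TSV output plus a machine-readable JSON manifest (package version,
#' parameters, seed, output checksums) into `config$out_dir`. Identical
#' configuration produces byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a path to a JSON file of
#'   overrides).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- do.call(pipeline_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- as.integer(config$seed)

  ## stage 1: synthetic inputs
  fam <- simulate_family(config$n_true_r2r3, config$n_decoys_per_kind,
                         mutation_rate = config$mutation_rate, seed = seed)
  write_fasta(fam$sequences, out("proteins.fa"))
  write_results_tsv(fam$truth, out("family_truth.tsv"))
  gm <- simulate_gene_models(config$n_genes, seed = seed + 1L)
  write_gff3(gm$gff, out("models.gff3"))

  ## stage 2: domain scan + classification
  prof <- repeat_profile(fam$template_seq, fam$template)
  anns <- lapply(fam$sequences, annotate_domain, profile = prof,
                 template = fam$template,
                 score_threshold_bits = config$score_threshold_bits)
  hits <- do.call(rbind, lapply(names(anns), function(id) {
    h <- anns[[id]]$hits
    if (nrow(h)) cbind(seq_id = id, h) else NULL
  }))
  write_results_tsv(hits, out("hits.tsv"))
  classes <- data.frame(
    seq_id = names(anns),
    myb_class = vapply(anns, `[[`, character(1), "myb_class"),
    integrity_pass = vapply(anns, `[[`, logical(1), "integrity_pass"),
    integrity_reason = vapply(anns, `[[`, character(1), "integrity_reason"),
    stringsAsFactors = FALSE)
  write_results_tsv(classes, out("classes.tsv"))

  ## stage 3: curation + naming over the synthetic gene models
  iso_ann <- data.frame(mrna_id = gm$isoforms$mrna_id,
                        integrity_pass = gm$isoforms$domain_complete,
                        myb_class = ifelse(gm$isoforms$domain_complete,
                                           "R2R3", "MYB_related"),
                        stringsAsFactors = FALSE)
  family <- curate_family(gm$genes, gm$isoforms, iso_ann)
  write_results_tsv(family, out("family.tsv"))

  ## stage 4: motif scan + clade classification
  motifs <- synthetic_ps_motifs(seed = seed)
  plan <- matrix(FALSE, 6, 6,
                 dimnames = list(sprintf("q%02d", 1:6), names(motifs)))
  plan[1, c("PS1", "motif12")] <- TRUE
  plan[2, c("PS1", "PS2")] <- TRUE
  plan[3, "PS3"] <- TRUE
  plan[4, c("PS4", "PS5")] <- TRUE
  sim_motif <- simulate_motif_sequences(motifs, plan, seed = seed + 2L)
  pres <- scan_motif_set(sim_motif$sequences, motifs,
                         threshold_fraction = config$motif_threshold)
  clades <- data.frame(
    seq_id = rownames(pres$present),
    clade = apply(pres$present, 1, classify_poaceae_clade),
    stringsAsFactors = FALSE)
  write_results_tsv(clades, out("clades.tsv"))

  ## stage 5: qPCR quantification
  folds <- data.frame(gene = c("tdmybA", "tdmybB"),
                      tissue = "root", time_h = 6L, fold = c(7.8, 1))
  qp <- simulate_qpcr(folds, seed = seed + 3L)
  write_results_tsv(qp$ct, out("ct.tsv"))
  rel <- do.call(rbind, lapply(unique(folds$gene), function(g) {
    delta_delta_ct(qp$ct, g, "RLIa")
  }))
  write_results_tsv(rel, out("relative_expression.tsv"))

  ## stage 6: GRN + enrichment
  grn_sim <- simulate_grn_expression(config$n_grn_genes, config$n_tfs,
                                     n_samples = config$n_grn_samples,
                                     noise_sd = config$grn_noise_sd,
                                     seed = seed + 4L)
  expr <- filter_expressed(grn_sim$tpm, config$tpm_threshold)
  write_matrix_tsv(grn_sim$tpm, out("tpm.tsv"))
  edges <- infer_network(expr,
                         intersect(grn_sim$regulators, rownames(expr)),
                         n_trees = config$n_trees, seed = seed + 5L)
  edges <- prune_top_edges(edges, config$top_k)
  write_results_tsv(edges, out("edges.tsv"))
  subnet <- extract_subnetwork(edges, grn_sim$regulators[1:3])

  go_sim <- simulate_go_annotation(400L, 25L, 30L, seed = seed + 6L)
  enr <- go_enrichment(go_sim$target_set, go_sim$annotation,
                       go_sim$universe, min_size = config$go_min_size,
                       max_size = config$go_max_size,
                       n_permutations = config$go_permutations,
                       seed = seed + 7L, alpha = config$go_alpha)
  write_results_tsv(enr, out("enrichment.tsv"))

  ## manifest
  outputs <- list.files(config$out_dir, pattern = "\\.(tsv|fa|gff3)$",
                        full.names = TRUE)
  manifest <- list(
    package = "mybscope",
    version = as.character(utils::packageVersion("mybscope")),
    parameters = unclass(config),
    checksums = as.list(stats::setNames(unname(tools::md5sum(sort(outputs))),
                                        basename(sort(outputs)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(family = family, classes = classes, clades = clades,
                 relative_expression = rel, edges = edges, subnet = subnet,
                 enrichment = enr, manifest = manifest))
}
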