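#' Default end-to-end pipeline configuration (standard synthetic fixture)
#'
#' Builds the standard desk-scale study: two cohorts of 10 patients (one
#' sample each, plus a second sample for the first case patient to
#' exercise patient pooling), three planted bacterial genera with
#' different prevalence patterns (case-enriched, balanced,
#' control-enriched), one planted viral transcript, and one protein
#' family planted in exactly five case patients whose presence carries a
#' survival hazard (log HR = log 3). Classifier training uses a separate,
#' larger reference set from the same origin models; planted transcripts
#' are 500-800 bases at 20x coverage, 75-base reads, N rate 0.005, 300
#' host reads per sample.
#'
#' @param rng_seed Root seed; all stage seeds derive from it.
#' @param epochs Classifier training epochs.
#' @param host_read_count Background host reads per sample.
#' @param coverage Fold-coverage of planted transcripts.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(rng_seed = 1L, epochs = 4L,
                                    host_read_count = 300L, coverage = 20) {
  structure(list(
    rng_seed = as.integer(rng_seed),
    simulate = list(
      n_case = 10L, n_control = 10L,
      train_refs = list(n_human = 12L, len_human = c(2000L, 2600L),
                        n_viral = 12L, len_viral = c(250L, 350L),
                        n_bacterial = 12L, len_bacterial = c(11000L, 13000L)),
      plant_refs = list(n_bacterial = 9L, len_bacterial = c(500L, 800L),
                        n_viral = 2L, len_viral = c(400L, 600L),
                        n_genera = 3L),
      coverage = coverage, read_length = 75L, n_rate = 0.005,
      host_read_count = as.integer(host_read_count),
      cohort = list(covariate_effects = c(age = 0.8, seq_depth = 0.8),
                    survival_log_hr = log(3), censoring_rate = 0.2)),
    classifier = list(epochs = as.integer(epochs)),
    assembly = list(seed_threshold = 0.46, min_overlap = 24L,
                    max_contig_length = 2000L),
    annotation = list(e_max_nt = 0.01, e_max_prot = 1e-5,
                      backend = "builtin"),
    contaminants = character(0),
    stages = list(assembly = TRUE, annotation = TRUE, stats = TRUE)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the defaults from [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(rng_seed = user$rng_seed %||% 1L)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
        merge_into(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user[setdiff(names(user), "rng_seed")]),
            class = "pipeline_config")
}

# Build the fixture's reference sets, sample specs, truth presence and
# cohort tables from a pipeline config.
build_fixture <- function(config) {
  sim <- config$simulate
  models <- default_origin_models()
  tr <- sim$train_refs
  train_refs <- dplyr::bind_rows(
    make_references(models["human"], tr$n_human, tr$len_human,
                    derive_seed(config$rng_seed, "refs_human")),
    make_references(models["viral"], tr$n_viral, tr$len_viral,
                    derive_seed(config$rng_seed, "refs_viral")),
    make_references(models["bacterial"], tr$n_bacterial, tr$len_bacterial,
                    derive_seed(config$rng_seed, "refs_bacterial")))
  pr <- sim$plant_refs
  plant_bact <- make_references(models["bacterial"], pr$n_bacterial,
                                pr$len_bacterial,
                                derive_seed(config$rng_seed, "plant_bact"))
  plant_vir <- make_references(models["viral"], pr$n_viral, pr$len_viral,
                               derive_seed(config$rng_seed, "plant_vir"))
  # planted accessions keep distinct ids from training references
  plant_bact$accession <- sub("^BAC", "PBA", plant_bact$accession)
  plant_vir$accession <- sub("^VIR", "PVI", plant_vir$accession)
  plant_refs <- dplyr::bind_rows(plant_bact, plant_vir)
  nt_db <- make_annotation_db(plant_refs, n_genera = pr$n_genera)
  prot_db <- make_protein_db(plant_refs,
                             accessions = plant_bact$accession)

  n_case <- sim$n_case; n_ctrl <- sim$n_control
  patient_id <- sprintf("P%04d", seq_len(n_case + n_ctrl))
  cohort <- rep(c("case", "control"), c(n_case, n_ctrl))
  # planting design over the genus round-robin (PBA_0001 -> Genus01,
  # PBA_0002 -> Genus02, PBA_0003 -> Genus03):
  #   Genus01 case-enriched, Genus02 balanced (carries the survival
  #   protein family), Genus03 control-enriched, one viral transcript in
  #   the last patient of each arm.
  acc_g1 <- "PBA_0001"; acc_g2 <- "PBA_0002"; acc_g3 <- "PBA_0003"
  survival_family <- prot_db$family[prot_db$source_accession == acc_g2][1]
  plan <- vector("list", n_case + n_ctrl)
  for (i in seq_len(n_case + n_ctrl)) {
    accs <- character(0)
    if (cohort[i] == "case") {
      j <- i
      if (j <= ceiling(0.8 * n_case)) accs <- c(accs, acc_g1)
      if (j <= ceiling(0.5 * n_case)) accs <- c(accs, acc_g2)
      if (j == n_case - 1L) accs <- c(accs, acc_g3)
      if (j == n_case) accs <- c(accs, "PVI_0001")
    } else {
      j <- i - n_case
      if (j == 1L) accs <- c(accs, acc_g1)
      if (j >= 4L && j <= 8L) accs <- c(accs, acc_g2)
      if (j <= ceiling(0.7 * n_ctrl)) accs <- c(accs, acc_g3)
      if (j == n_ctrl) accs <- c(accs, "PVI_0002")
    }
    plan[[i]] <- accs
  }
  samples <- lapply(seq_len(n_case + n_ctrl), function(i) {
    sample_spec(sprintf("S%04d", i), patient_id[i], cohort[i],
                planted = stats::setNames(rep(sim$coverage,
                                              length(plan[[i]])), plan[[i]]),
                read_length = sim$read_length, n_rate = sim$n_rate,
                host_read_count = sim$host_read_count,
                rng_seed = derive_seed(config$rng_seed,
                                       paste0("reads_", i)))
  })
  # second sample for the first case patient (nothing planted): pooling
  samples[[length(samples) + 1L]] <-
    sample_spec(sprintf("S%04d", length(samples) + 1L), patient_id[1],
                cohort[1], planted = numeric(0),
                read_length = sim$read_length, n_rate = sim$n_rate,
                host_read_count = sim$host_read_count,
                rng_seed = derive_seed(config$rng_seed, "reads_extra"))

  truth_presence <- matrix(FALSE, n_case + n_ctrl, 1,
                           dimnames = list(patient_id, survival_family))
  truth_presence[vapply(plan, function(a) acc_g2 %in% a, logical(1)), 1] <- TRUE
  cspec <- cohort_spec(
    n_case, n_ctrl,
    covariate_effects = sim$cohort$covariate_effects,
    feature_hazard = stats::setNames(sim$cohort$survival_log_hr,
                                     survival_family),
    censoring_rate = sim$cohort$censoring_rate,
    rng_seed = derive_seed(config$rng_seed, "cohort"))
  cohort_tables <- make_cohort(cspec, truth_presence)

  list(models = models, train_refs = train_refs, plant_refs = plant_refs,
       nt_db = nt_db, prot_db = prot_db, samples = samples,
       truth_presence = truth_presence, cohort_tables = cohort_tables,
       survival_family = survival_family,
       enriched_genus = nt_db$genus[nt_db$accession == acc_g1][1],
       depleted_genus = nt_db$genus[nt_db$accession == acc_g3][1])
}

#' Run the full pipeline on the configured synthetic study
#'
#' Stages: simulate -> train classifier -> per sample (host filter,
#' score, assemble, annotate) -> presence matrices -> statistics
#' (binomial prevalence, IPW-corrected prevalence, survival screen).
#' All stage outputs and a machine-readable run report are written under
#' `out_dir`; re-running with the same config and seed reproduces
#' byte-identical outputs.
#'
#' @param config A `pipeline_config` (list) or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param classifier Optional pre-trained `microseek_classifier`; when
#'   NULL one is trained from the fixture's training references.
#' @return Invisibly, a list with all intermediate and final objects
#'   (classifier, scores, contigs, hits, presence matrices, stats
#'   tables, report).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         classifier = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fx <- stage("simulate", build_fixture(config))
  write_reference_fasta(fx$train_refs, file.path(out_dir, "train_refs.fasta"))
  write_reference_fasta(fx$plant_refs, file.path(out_dir, "plant_refs.fasta"))
  write_nucleotide_db_fasta(fx$nt_db, file.path(out_dir, "nt_db.fasta"))
  write_protein_db_fasta(fx$prot_db, file.path(out_dir, "prot_db.fasta"))
  write_tsv_plain(fx$cohort_tables$covariates,
                  file.path(out_dir, "covariates.tsv"))
  write_tsv_plain(fx$cohort_tables$survival,
                  file.path(out_dir, "survival.tsv"))

  if (is.null(classifier)) {
    classifier <- stage("train", {
      ds <- build_dataset(fx$train_refs, segmentation_config(),
                          derive_seed(config$rng_seed, "split"))
      cfg <- classifier_config(epochs = config$classifier$epochs,
                               rng_seed = derive_seed(config$rng_seed,
                                                      "train"))
      train_classifier(ds, cfg)
    })
  }

  params <- assembly_params(config$assembly$seed_threshold,
                            config$assembly$min_overlap,
                            config$assembly$max_contig_length)
  per_sample <- list()
  genus_presence <- list(); protein_presence <- list()
  sample_to_patient <- character(0)
  counts <- list()
  for (sp in fx$samples) {
    sid <- sp$sample_id
    sample_to_patient[sid] <- sp$patient_id
    reads <- stage("simulate", make_reads(sp, dplyr::bind_rows(fx$train_refs,
                                                               fx$plant_refs)))
    kept <- stage("host_filter", filter_host_reads(reads, fx$train_refs))
    n_host <- nrow(attr(kept, "removed"))
    scored <- stage("score", score_reads(classifier, kept,
                                         derive_seed(config$rng_seed,
                                                     paste0("score_", sid))))
    write_tsv_plain(scored[, c("read_id", "p_human", "p_viral",
                               "p_bacterial", "excluded")],
                    file.path(out_dir, paste0(sid, "_scores.tsv")))
    cnt <- list(sample_id = sid, reads_in = nrow(reads),
                reads_host_filtered = n_host,
                reads_excluded_N = sum(scored$excluded),
                reads_scored = sum(!scored$excluded))
    if (!isTRUE(config$stages$assembly)) {
      counts[[sid]] <- cnt
      per_sample[[sid]] <- list(scored = scored)
      next
    }
    asm <- stage("assemble", assemble_sample(scored, params))
    write_contig_fasta(asm$contigs, file.path(out_dir,
                                              paste0(sid, "_contigs.fasta")))
    write_tsv_plain(asm$members, file.path(out_dir,
                                           paste0(sid, "_members.tsv")))
    cnt$seeds <- nrow(select_and_sort_seeds(scored, params$seed_threshold))
    cnt$contigs <- nrow(asm$contigs)
    if (isTRUE(config$stages$annotation)) {
      nt_hits <- stage("annotate",
                       nucleotide_search(asm$contigs, fx$nt_db,
                                         config$annotation$e_max_nt,
                                         backend = config$annotation$backend))
      nt_hits <- screen_contaminants(nt_hits, config$contaminants)
      prot_hits <- stage("annotate",
                         translated_search(asm$contigs, fx$prot_db,
                                           config$annotation$e_max_prot,
                                           backend = config$annotation$backend))
      write_tsv_plain(nt_hits, file.path(out_dir, paste0(sid, "_nt_hits.tsv")))
      write_tsv_plain(prot_hits,
                      file.path(out_dir, paste0(sid, "_prot_hits.tsv")))
      genus_presence[[sid]] <- pool_to_genus(nt_hits)
      protein_presence[[sid]] <- sort(unique(prot_hits$family))
      cnt$nt_hits <- nrow(nt_hits)
      cnt$prot_hits <- nrow(prot_hits)
    }
    counts[[sid]] <- cnt
    per_sample[[sid]] <- list(scored = scored, contigs = asm$contigs,
                              members = asm$members)
  }

  result <- list(config = config, fixture = fx, classifier = classifier,
                 per_sample = per_sample, counts = counts)

  if (isTRUE(config$stages$assembly) && isTRUE(config$stages$annotation) &&
      isTRUE(config$stages$stats)) {
    cohort_labels <- stats::setNames(
      fx$cohort_tables$covariates$cohort,
      fx$cohort_tables$covariates$patient_id)
    long <- function(pres_list) {
      dplyr::bind_rows(lapply(names(pres_list), function(s) {
        if (length(pres_list[[s]]) == 0) return(NULL)
        tibble::tibble(sample_id = s, feature = pres_list[[s]])
      }))
    }
    g_long <- long(genus_presence)
    if (is.null(g_long) || nrow(g_long) == 0) {
      g_long <- tibble::tibble(sample_id = character(0),
                               feature = character(0))
    }
    pm_genus <- stage("stats", build_presence_matrix(
      g_long, sample_to_patient, cohort_labels, kind = "genus"))
    p_long <- long(protein_presence)
    if (is.null(p_long) || nrow(p_long) == 0) {
      p_long <- tibble::tibble(sample_id = character(0),
                               feature = character(0))
    }
    pm_prot <- stage("stats", build_presence_matrix(
      p_long, sample_to_patient, cohort_labels, kind = "protein"))

    prevalence <- stage("stats", prevalence_analysis(pm_genus))
    covars <- fx$cohort_tables$covariates[
      match(rownames(pm_genus), fx$cohort_tables$covariates$patient_id),
      c("race", "age", "sex", "weight", "smoking", "seq_depth")]
    corrected <- stage("stats", corrected_prevalence_analysis(
      pm_genus, covars,
      rng_seed = derive_seed(config$rng_seed, "ipw")))
    case_pm <- pm_prot[pm_cohort(pm_prot) == "case", , drop = FALSE]
    attr(case_pm, "cohort") <- pm_cohort(pm_prot)[pm_cohort(pm_prot) == "case"]
    attr(case_pm, "kind") <- "protein"
    survival <- stage("stats", survival_screen(
      case_pm, fx$cohort_tables$survival))

    write_tsv_plain(prevalence, file.path(out_dir, "prevalence.tsv"))
    write_tsv_plain(corrected, file.path(out_dir, "prevalence_corrected.tsv"))
    write_tsv_plain(survival, file.path(out_dir, "survival_screen.tsv"))
    pm_out <- tibble::as_tibble(as.data.frame(unclass(pm_genus)))
    pm_out <- dplyr::bind_cols(tibble::tibble(patient_id = rownames(pm_genus)),
                               pm_out)
    write_tsv_plain(pm_out, file.path(out_dir, "presence_genus.tsv"))
    result$presence_genus <- pm_genus
    result$presence_protein <- pm_prot
    result$prevalence <- prevalence
    result$corrected <- corrected
    result$survival <- survival
  }

  report <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("microseek")),
      error = function(e) "dev"),
    rng_seed = config$rng_seed,
    counts = counts)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$report <- report
  invisible(result)
}
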