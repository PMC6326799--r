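#' Default pipeline configuration
#'
#' One structured object holding every tunable of the pipeline with its
#' default: the periphery band (10-66.6 %DAPI), the 33.3% single-signal
#' reference cut, the 0.5 um pairing radius, the enrichment-test
#' parameters (s0 0.5, 250 randomizations, FDR 0.05, imputation width
#' 0.3 / downshift 1.8), the Q-rich window rule (60-mers, >= 7
#' residues), the reciprocal-hit cutoff (1e-5), and the synthetic
#' geometry/optics blocks. Round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param seed master seed; every stochastic stage derives a child seed
#'   from it with [derive_seed()].
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    band = c(10, 66.6),
    single_signal_cut = 33.3,
    pairing_radius = 0.5,
    detection = list(k_mad = 5, merge_nsigma = 2),
    profiles = list(step = 0.05, n_rays = 4L, robust_min = TRUE),
    enrichment = list(s0 = 0.5, n_randomizations = 250L, fdr = 0.05,
                      imputation_width = 0.3, imputation_downshift = 1.8,
                      min_valid = 2L, filter_scope = "any",
                      fdr_estimator = "mean"),
    qrich = list(window = 60L, min_count = 7L, residue = "Q", offset = 0L),
    rbh = list(evalue_cutoff = 1e-5, cutoff_on = "reverse"),
    geometry = unclass(scene_geometry()),
    optics = unclass(optics_params()),
    scene = list(counts = list(intact.nucleus = 3L,
                               intact.cytoplasm = 4L,
                               five_prime_part.nuclear_periphery = 4L,
                               three_prime_part.cytoplasm = 3L),
                 orientation_fraction = 0.81,
                 compaction = 0.5, min_separation = 0.7),
    lfq = unclass(lfq_ground_truth()),
    sequences = list(n = 20L, lengths = 300L, planted = c(0L, 1L, 2L),
                     background_rate = 0.02))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Rejects out-of-domain thresholds with a message naming the offending
#' field.
#'
#' @param cfg a `pipeline_config`.
#' @return The config, invisibly usable.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(length(cfg$band) == 2L && cfg$band[1] >= 0 && cfg$band[2] <= 100 &&
      cfg$band[1] < cfg$band[2], "band must be an increasing pair in [0, 100]")
  chk(cfg$single_signal_cut > 0 && cfg$single_signal_cut < 100,
      "single_signal_cut must be in (0, 100)")
  chk(cfg$pairing_radius > 0, "pairing_radius must be positive")
  chk(cfg$enrichment$s0 >= 0, "s0 must be non-negative")
  chk(cfg$enrichment$fdr > 0 && cfg$enrichment$fdr < 1, "fdr must be in (0, 1)")
  chk(cfg$enrichment$imputation_width >= 0, "imputation width must be >= 0")
  chk(cfg$enrichment$imputation_downshift >= 0,
      "imputation downshift must be >= 0")
  chk(cfg$qrich$window >= 1 && cfg$qrich$min_count >= 1 &&
      cfg$qrich$min_count <= cfg$qrich$window,
      "qrich min_count must be in [1, window]")
  chk(cfg$rbh$evalue_cutoff > 0, "rbh evalue_cutoff must be positive")
  chk(cfg$profiles$step > 0, "profile step must be positive")
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml flattens length-1 vectors; restore known numeric pairs
  cfg$band <- as.numeric(cfg$band)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

config_optics <- function(cfg) do.call(optics_params, cfg$optics)
config_geometry <- function(cfg) do.call(scene_geometry, cfg$geometry)

#' Run the end-to-end synthetic pipeline
#'
#' Executes the requested stages in dependency order, writing every
#' stage's outputs as TSV/TIFF/FASTA under `out_dir` and a YAML manifest
#' (config snapshot, seed, package version, per-file MD5 digests) at the
#' end. Stages: `simulate` (scene, image stack, LFQ matrix, sequences,
#' homology tables, all with ground truth), `calibrate` (four-ray border
#' calibration by both methods), `quantify` (detect, group, classify,
#' localize, count), `orient` (export-orientation analysis), `enrich`
#' (filter, log2, impute, moderated test, volcano), `qrich` and `rbh`.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of the stage names above.
#' @param out_dir output directory (created if needed).
#' @param seed master seed override; defaults to `config$seed`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "calibrate", "quantify",
                                    "orient", "enrich", "qrich", "rbh"),
                         out_dir = ".", seed = NULL) {
  validate_config(config)
  all_stages <- c("simulate", "calibrate", "quantify", "orient", "enrich",
                  "qrich", "rbh")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  written <- character(0)
  note <- function(...) written <<- c(written, p(...))
  optics <- config_optics(config)
  geometry <- config_geometry(config)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires missing input: ", path,
           " (run the 'simulate' stage first)")
    }
    path
  }

  if ("simulate" %in% stages) {
    counts <- molecule_counts(data.frame(
      species = sub("\\..*$", "", names(config$scene$counts)),
      location = sub("^[^.]*\\.", "", names(config$scene$counts)),
      n = unlist(config$scene$counts), stringsAsFactors = FALSE))
    scene <- generate_cell_scene(
      counts, orientation_fraction = config$scene$orientation_fraction,
      geometry = geometry, optics = optics,
      compaction = config$scene$compaction,
      min_separation = config$scene$min_separation,
      seed = derive_seed(seed, "scene"))
    write_scene_truth(scene, p("scene"))
    note("scene_molecules.tsv"); note("scene_probes.tsv")
    stack <- render_image(scene, optics, seed = derive_seed(seed, "render"))
    write_image_stack(stack, p("stack"))
    note("stack.yaml")
    for (ch in names(stack$channels)) note("stack_", ch, ".tif")

    lfq <- generate_lfq_dataset(do.call(lfq_ground_truth, config$lfq),
                                seed = derive_seed(seed, "lfq"))
    write_lfq_tsv(lfq$matrix, p("lfq.tsv")); note("lfq.tsv")
    tsv(data.frame(protein = lfq$truth$enriched_ids), p("lfq_truth.tsv"))

    sq <- generate_protein_sequences(
      n = config$sequences$n, lengths = config$sequences$lengths,
      planted = config$sequences$planted,
      window = config$qrich$window, min_count = config$qrich$min_count,
      residue = config$qrich$residue,
      background_rate = config$sequences$background_rate,
      seed = derive_seed(seed, "sequences"))
    write_fasta(sq$sequences, p("proteins.fasta")); note("proteins.fasta")
    tsv(sq$truth, p("proteins_truth.tsv"))

    hom <- generate_homology_tables(sq$truth$protein,
                                    evalue_cutoff = config$rbh$evalue_cutoff,
                                    seed = derive_seed(seed, "homology"))
    tsv(hom$forward, p("hits_forward.tsv"))
    tsv(hom$reverse, p("hits_reverse.tsv"))
    tsv(as.data.frame(hom$truth), p("homology_truth.tsv"))
  }

  if ("calibrate" %in% stages) {
    stack <- read_image_stack(sub("\\.yaml$", "", need(p("stack.yaml"), "calibrate")))
    profs <- border_profiles(stack, channels = c("dapi", "pore"),
                             n_rays = config$profiles$n_rays, mode = "plane",
                             step = config$profiles$step)
    cal_peak <- calibrate_border(profs, method = "marker_peak",
                                 threshold = config$single_signal_cut)
    profs_m <- border_profiles(stack, channels = c("dapi", "cyto"),
                               n_rays = config$profiles$n_rays, mode = "max",
                               step = config$profiles$step)
    cal_int <- calibrate_border(profs_m, method = "intersection",
                                threshold = config$single_signal_cut)
    tsv(data.frame(method = c("marker_peak", "intersection"),
                   mean = c(cal_peak$mean, cal_int$mean),
                   sd = c(cal_peak$sd, cal_int$sd),
                   n = c(cal_peak$n, cal_int$n),
                   fraction_below_33 = c(cal_peak$fraction_below_33,
                                         cal_int$fraction_below_33)),
        p("calibration.tsv"))
  }

  quantified <- NULL
  if (any(c("quantify", "orient") %in% stages)) {
    stack <- read_image_stack(sub("\\.yaml$", "", need(p("stack.yaml"), "quantify")))
    spots <- do.call(rbind, lapply(c("red", "ir", "green"), function(ch) {
      detect_spots(stack, ch, k_mad = config$detection$k_mad,
                   psf_sigma = optics$psf_sigma,
                   merge_nsigma = config$detection$merge_nsigma)
    }))
    spots <- group_spots_to_molecules(spots, config$pairing_radius)
    quantified <- localize_molecules(spots, stack,
                                     band = config$band,
                                     cyto_cut = config$band[1])
  }
  if ("quantify" %in% stages) {
    tsv(quantified$spots, p("spots.tsv"))
    tsv(quantified$molecules, p("molecules.tsv"))
    cc <- per_cell_counts(quantified$molecules)
    tsv(cc$counts, p("counts.tsv"))
  }
  if ("orient" %in% stages) {
    stack <- read_image_stack(sub("\\.yaml$", "", p("stack.yaml")))
    ores <- orientation_analysis(quantified$spots, stack)
    tsv(ores$records, p("orientation.tsv"))
    tsv(data.frame(n_eligible = ores$n_eligible,
                   n_five_prime_first = ores$n_five_prime_first,
                   fraction = ores$fraction,
                   n_excluded = ores$n_excluded),
        p("orientation_summary.tsv"))
  }

  if ("enrich" %in% stages) {
    m <- read_lfq_tsv(need(p("lfq.tsv"), "enrich"))
    e <- config$enrichment
    m <- filter_matrix(m, min_valid = e$min_valid, scope = e$filter_scope)
    m <- log2_transform(m)
    m <- impute_mnar(m, width = e$imputation_width,
                     downshift = e$imputation_downshift,
                     seed = derive_seed(seed, "impute"))
    res <- sam_welch_test(m, s0 = e$s0,
                          n_randomizations = e$n_randomizations,
                          fdr = e$fdr, seed = derive_seed(seed, "sam"),
                          fdr_estimator = e$fdr_estimator)
    tsv(res$table, p("enrichment.tsv"))
    volcano_table(res, p("volcano.tsv")); note("volcano.tsv")
  }

  if ("qrich" %in% stages) {
    seqs <- read_fasta(need(p("proteins.fasta"), "qrich"))
    q <- config$qrich
    tsv(qrich_scan_set(seqs, window = q$window, min_count = q$min_count,
                       residue = q$residue, offset = q$offset),
        p("qrich.tsv"))
  }

  if ("rbh" %in% stages) {
    fw <- utils::read.delim(need(p("hits_forward.tsv"), "rbh"),
                            stringsAsFactors = FALSE)
    rv <- utils::read.delim(need(p("hits_reverse.tsv"), "rbh"),
                            stringsAsFactors = FALSE)
    prot <- utils::read.delim(p("proteins_truth.tsv"),
                              stringsAsFactors = FALSE)$protein
    tsv(rbh_classify(fw, rv, proteins = prot,
                     evalue_cutoff = config$rbh$evalue_cutoff,
                     cutoff_on = config$rbh$cutoff_on),
        p("rbh.tsv"))
  }

  manifest <- list(config = unclass(config), seed = seed,
                   package_version = as.character(utils::packageVersion("periFISH")),
                   stages = stages,
                   files = as.list(tools::md5sum(unique(written))))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(manifest)
}
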