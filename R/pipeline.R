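## End-to-end orchestration: simulate -> call -> groups -> diff -> aei ->
## survive, from a single flat config with one master seed.

.configDefaults <- function() list(
    seed = 1L,
    out_dir = "editscape_run",
    stages = c("simulate", "call", "groups", "diff", "aei", "survive"),
    ## simulation
    n_sites = 1000L, frac_des = 0.1, n_group1 = 10L, n_group2 = 8L,
    coverage_mean = 50, coverage_dispersion = 0.1, null_mean = 0.1,
    null_overdispersion = 0.05, des_log2fc = 2.5, frac_dna_variant = 0.1,
    dropout_rate = 0.05, frac_alu = 0.5, frac_non_alu = 0.2,
    ## grouping
    drugs = c("olaparib", "doxorubicin", "cisplatin"), drug = "olaparib",
    ic50_separation = 2, quantile_type = 7,
    ## calling
    min_edited_reads = 5, min_af = 0.05, min_prevalence = 0.5,
    presence = "observed",
    ## differential editing
    p_max = 0.05, fdr_max = 0.1, fc_min = 2.5, fc_scale = "log2",
    fc_pseudo = 1e-4, llr_df = 2,
    ## survival validation
    n_patients = 86L, baseline_hazard = 0.03, effect_beta = 6,
    censor_rate = 0.3, patient_missing_rate = 0.1)

#' Validate a pipeline configuration
#'
#' Loads a YAML file (or takes a named list), rejects unknown keys, fills
#' defaults, and range-checks every threshold, reporting the offending
#' field by name. The returned object round-trips through
#' [writeConfig()] / `validateConfig()`.
#'
#' @param config path to a YAML file, or a named list of settings.
#' @return A validated `RunConfig` (classed list).
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    defaults <- .configDefaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)

    chk <- function(ok, field, what) if (!ok)
        stop("config field '", field, "' ", what)
    inRange <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
        !is.na(x) && x >= lo && x <= hi
    chk(inRange(cfg$min_af, 0, 1), "min_af", "must lie in [0,1]")
    chk(inRange(cfg$min_prevalence, 0, 1), "min_prevalence",
        "must lie in [0,1]")
    chk(inRange(cfg$min_edited_reads, 0, Inf), "min_edited_reads",
        "must be >= 0")
    chk(inRange(cfg$p_max, 0, 1) && cfg$p_max > 0, "p_max",
        "must lie in (0,1]")
    chk(inRange(cfg$fdr_max, 0, 1) && cfg$fdr_max > 0, "fdr_max",
        "must lie in (0,1]")
    chk(inRange(cfg$fc_min, 0, Inf), "fc_min", "must be >= 0")
    chk(inRange(cfg$fc_pseudo, 0, 1), "fc_pseudo", "must lie in [0,1]")
    chk(inRange(cfg$llr_df, 1, 10), "llr_df", "must lie in [1,10]")
    chk(cfg$quantile_type %in% 1:9, "quantile_type",
        "must be a stats::quantile type (1-9)")
    chk(cfg$presence %in% c("observed", "called"), "presence",
        "must be 'observed' or 'called'")
    chk(cfg$fc_scale %in% c("log2", "ratio"), "fc_scale",
        "must be 'log2' or 'ratio'")
    chk(all(cfg$stages %in% defaults$stages), "stages",
        "contains an unknown stage name")
    chk(cfg$drug %in% cfg$drugs, "drug", "must be one of 'drugs'")
    chk(inRange(cfg$patient_missing_rate, 0, 1), "patient_missing_rate",
        "must lie in [0,1]")
    chk(inRange(cfg$seed, 1, 2^31 - 10), "seed",
        "must be a positive 32-bit integer")
    ## simulation ranges are enforced by the SimConfig validity method
    simCfg <- SimConfig(
        n_sites = cfg$n_sites, frac_des = cfg$frac_des,
        n_group1 = cfg$n_group1, n_group2 = cfg$n_group2,
        coverage_mean = cfg$coverage_mean,
        coverage_dispersion = cfg$coverage_dispersion,
        null_mean = cfg$null_mean,
        null_overdispersion = cfg$null_overdispersion,
        des_log2fc = cfg$des_log2fc,
        frac_dna_variant = cfg$frac_dna_variant,
        dropout_rate = cfg$dropout_rate, seed = cfg$seed)
    validObject(SurvSimConfig(
        n_patients = cfg$n_patients,
        baseline_hazard = cfg$baseline_hazard,
        effect_beta = cfg$effect_beta, censor_rate = cfg$censor_rate,
        seed = cfg$seed))
    cfg$seed <- as.integer(cfg$seed)
    structure(cfg, class = "RunConfig", sim_config = simCfg)
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config a `RunConfig` (or plain list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(unclass(config)[names(.configDefaults())], path)
    invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate the cohort and its
#' fixtures, call sites through the filter cascade (reading the fixture
#' files back through the package readers), assign IC50 sensitivity
#' groups, test for differential editing, compute the Alu Editing Index,
#' and validate DESs against simulated progression-free survival — and
#' writes every output plus a run manifest under `config$out_dir`. One
#' master seed drives all stages through fixed per-stage offsets, so two
#' runs with an equal config produce byte-identical tables.
#'
#' @param config a `RunConfig` from [validateConfig()], a path to a YAML
#'   config, or a named list.
#' @return The run manifest (list), invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
runPipeline <- function(config = list()) {
    if (!inherits(config, "RunConfig")) config <- validateConfig(config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    inputsDir <- file.path(config$out_dir, "inputs")
    manifest <- list(
        tool = "editscape",
        version = as.character(packageVersion("editscape")),
        seed = config$seed, started = format(Sys.time(), usetz = TRUE),
        stages = list())
    cfgPath <- writeConfig(config,
                           file.path(config$out_dir, "config_used.yaml"))
    manifest$config_hash <- unname(tools::md5sum(cfgPath))
    seed <- config$seed
    stage <- function(s) s %in% config$stages
    note <- function(...) message(sprintf(...))

    ## --- simulate -------------------------------------------------------
    simCfg <- attr(config, "sim_config")
    sim <- simulateEditing(simCfg)
    repeats <- simulateRepeats(sim$truth, config$frac_alu,
                               config$frac_non_alu, seed = seed + 1L)
    ic50 <- simulateIC50(
        ncol(sim$experiment), drugs = config$drugs,
        separation = config$ic50_separation,
        group = colData(sim$experiment)$group,
        sample_ids = colnames(sim$experiment), seed = seed + 2L)
    if (stage("simulate")) {
        writeFixtures(sim, inputsDir, repeats = repeats, ic50 = ic50)
        note("simulate: %d sites x %d samples written to %s",
             nrow(sim$experiment), ncol(sim$experiment), inputsDir)
        manifest$stages$simulate <- list(
            n_sites = nrow(sim$experiment),
            n_samples = ncol(sim$experiment),
            n_des_planted = sum(sim$truth$is_des),
            n_variants_planted = sum(sim$truth$is_dna_variant))
    }

    ## --- call -----------------------------------------------------------
    obs <- do.call(rbind, lapply(colnames(sim$experiment), function(s)
        readSiteCounts(file.path(inputsDir, "counts",
                                 paste0(s, ".tsv")), s)))
    variants <- readVcfVariants(file.path(inputsDir, "variants.vcf"))
    casc <- runCascade(obs, variants,
                       min_edited_reads = config$min_edited_reads,
                       min_af = config$min_af,
                       min_frac = config$min_prevalence,
                       presence = config$presence,
                       samples = colnames(sim$experiment))
    ee <- casc$experiment
    if (stage("call")) {
        writeEditingMatrix(ee, file.path(config$out_dir, "matrix.tsv"))
        writeTsv(casc$report,
                 file.path(config$out_dir, "filter_report.tsv"))
        for (r in seq_len(nrow(casc$report)))
            note("call/%s: %d -> %d (-%d)", casc$report$stage[r],
                 casc$report$n_in[r], casc$report$n_out[r],
                 casc$report$n_removed[r])
        manifest$stages$call <- casc$report
    }

    ## --- groups ---------------------------------------------------------
    groupsTab <- assignSensitivity(ic50, config$drug,
                                   config$quantile_type)
    if (stage("groups")) {
        writeTsv(groupsTab, file.path(config$out_dir, "groups.tsv"))
        manifest$stages$groups <- as.list(table(groupsTab$label))
        note("groups(%s): %s", config$drug,
             paste(names(table(groupsTab$label)), table(groupsTab$label),
                   sep = "=", collapse = " "))
    }

    des <- NULL
    if (stage("diff")) {
        keep <- groupsTab$sample_id[groupsTab$label != "INTERMEDIATE"]
        lab <- groupsTab$label[match(keep, groupsTab$sample_id)]
        groups <- factor(lab,
                         levels = c("LOW_SENSITIVITY",
                                    "HIGH_SENSITIVITY"))
        des <- diffEditing(ee[, keep], groups,
                           p_max = config$p_max,
                           fdr_max = config$fdr_max,
                           fc_min = config$fc_min,
                           fc_scale = config$fc_scale,
                           pseudo = config$fc_pseudo, df = config$llr_df)
        writeTsv(des, file.path(config$out_dir, "des.tsv"))
        manifest$stages$diff <- list(
            n_tested = sum(is.na(des$skipped)),
            n_skipped = sum(!is.na(des$skipped)),
            n_des = sum(des$is_des))
        note("diff: %d sites tested, %d DESs", sum(is.na(des$skipped)),
             sum(des$is_des))
    }

    if (stage("aei")) {
        aei <- computeAei(ee, repeats)
        writeTsv(aei, file.path(config$out_dir, "aei.tsv"))
        manifest$stages$aei <- list(
            n_samples = nrow(aei),
            mean_aei = mean(aei$aei, na.rm = TRUE))
        note("aei: mean %.4f over %d samples",
             mean(aei$aei, na.rm = TRUE), nrow(aei))
    }

    ## --- survive --------------------------------------------------------
    if (stage("survive")) {
        if (is.null(des)) stop("stage 'survive' requires stage 'diff'")
        desSites <- des$site[des$is_des]
        if (!length(desSites)) {
            note("survive: no DESs, stage skipped")
            manifest$stages$survive <- list(n_sites = 0L)
        } else {
            lv <- editingLevels(ee[desSites, ])
            siteMeans <- pmin(pmax(rowMeans(lv, na.rm = TRUE), 0.01),
                              0.99)
            full <- simulatePatientLevels(
                siteMeans, config$n_patients,
                overdispersion = config$null_overdispersion,
                missing_rate = 0, seed = seed + 3L)
            survCfg <- SurvSimConfig(
                n_patients = config$n_patients,
                baseline_hazard = config$baseline_hazard,
                effect_beta = config$effect_beta,
                censor_rate = config$censor_rate, seed = seed + 4L)
            surv <- simulateSurvival(full[1L, ], survCfg)
            set.seed(seed + 5L)
            mask <- matrix(runif(length(full)) <
                               config$patient_missing_rate,
                           nrow(full), ncol(full))
            scanLv <- full
            scanLv[mask] <- NA_real_
            writeTsv(surv, file.path(inputsDir, "survival.tsv"))
            scan <- siteSurvivalScan(scanLv, surv, p_max = config$p_max)
            writeTsv(scan$results,
                     file.path(config$out_dir, "site_survival.tsv"))
            kmDir <- file.path(config$out_dir, "km")
            dir.create(kmDir, showWarnings = FALSE)
            for (s in names(scan$km)) {
                safe <- gsub("[^A-Za-z0-9]+", "_", s)
                writeTsv(scan$km[[s]]$hyper,
                         file.path(kmDir, paste0(safe, "_hyper.tsv")))
                writeTsv(scan$km[[s]]$hypo,
                         file.path(kmDir, paste0(safe, "_hypo.tsv")))
            }
            manifest$stages$survive <- list(
                n_sites = nrow(scan$results),
                n_skipped = nrow(scan$skipped),
                n_significant = sum(scan$results$significant),
                driver_site = desSites[1L])
            note("survive: %d sites scanned, %d significant at p<%g",
                 nrow(scan$results), sum(scan$results$significant),
                 config$p_max)
        }
    }

    manifest$finished <- format(Sys.time(), usetz = TRUE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
    invisible(manifest)
}
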