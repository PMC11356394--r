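# End-to-end orchestration from a single YAML configuration, with a
# machine-readable run manifest and reproducible seeds.

#' Validate a pipeline configuration
#'
#' Configurations are YAML files (or equivalent lists). Either a
#' `simulate:` block (arguments of [sim_config()]) or an `inputs:` block
#' with `alignment` / `metadata` paths must be present; input files are
#' checked for existence before any compute. All seeds must be explicit.
#'
#' @param config Path to a YAML file, or a list.
#' @return The validated configuration list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) mt_stop("config", sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) mt_stop("config", "an explicit top-level seed is required")
  if (is.null(config$simulate) && is.null(config$inputs))
    mt_stop("config", "config needs a 'simulate' or an 'inputs' block")
  if (!is.null(config$inputs)) {
    for (f in c("alignment", "metadata")) {
      if (is.null(config$inputs[[f]]))
        mt_stop("config", sprintf("inputs block needs a '%s' path", f))
      if (!file.exists(config$inputs[[f]]))
        mt_stop("config", sprintf("input file '%s' not found", config$inputs[[f]]))
    }
    if (!is.null(config$inputs$motifs) && !file.exists(config$inputs$motifs))
      mt_stop("config", sprintf("motif file '%s' not found", config$inputs$motifs))
  }
  config$window <- config$window %||% list(start = 15476, end = 15749)
  config$group_by <- config$group_by %||% "region"
  config$n_boot <- config$n_boot %||% 100
  config$n_perm <- config$n_perm %||% 200
  config$n_sim <- config$n_sim %||% 100
  config$demography <- config$demography %||%
    list(mu_site_year = 6.13e-8, gen_years = 8)
  config$out_dir <- config$out_dir %||% "mthapnet-run"
  config
}

#' Run the full analysis pipeline
#'
#' Executes harmonize -> classify -> diversity -> demography -> AMOVA ->
#' network on the configured dataset (simulated or read from disk) and
#' writes a report bundle: a per-group diversity table, a per-haplogroup
#' demography table, AMOVA tables (one- and two-level designs), network
#' node/edge TSVs plus GraphML, the harmonized haplotype table, and a
#' JSON run manifest recording package version, seeds and parameters.
#' Reruns with the same configuration produce byte-identical outputs.
#'
#' @param config Path to a YAML configuration or an equivalent list (see
#'   [validate_config()]).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      mt_stop("pipeline", sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- input stage -----------------------------------------------------
  aln <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      sim <- simulate_two_haplogroup_dataset(sc)
      utils::write.table(sim$truth, out("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sim$aln
    } else {
      a <- read_alignment(cfg$inputs$alignment, cfg$inputs$metadata)
      a <- trim_to_window(a, cfg$window$start, cfg$window$end,
                          reference_row = cfg$inputs$reference_row,
                          ref_start = cfg$inputs$ref_start %||% 1L)
      drop_indel_columns(a)
    }
  })
  motifs <- stage("input", {
    if (!is.null(cfg$inputs$motifs)) read_motifs(cfg$inputs$motifs) else default_motifs()
  })

  # --- harmonize / classify -------------------------------------------
  sites <- stage("harmonize", site_summary(aln))
  table <- stage("classify", {
    tb <- collapse_haplotypes(aln, group_by = cfg$group_by)
    asn <- classify_haplotypes(tb, motifs)
    name_haplotypes(tb, asn)
  })
  assignments <- data.frame(name = table$haps$name, label = table$haps$haplogroup)
  stage("classify", {
    write_haplotype_table(table, out("haplotypes.tsv"), out("haplotypes.fasta"))
    utils::write.table(
      data.frame(metric = c("variable", "parsimony_informative", "singleton",
                            "substitutions", "transitions", "transversions"),
                 value = c(sites$n_variable, sites$n_parsimony_informative,
                           sites$n_singleton, sites$n_substitutions,
                           sites$n_transitions, sites$n_transversions)),
      out("site_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- diversity -------------------------------------------------------
  diversity <- stage("diversity", summarize_groups(table, assignments))
  stage("diversity", write_diversity_table(diversity, out("diversity.tsv")))

  # --- demography ------------------------------------------------------
  demography <- stage("demography", demography_summary(
    table, assignments, n_boot = cfg$n_boot, n_sim = cfg$n_sim,
    seed = cfg$seed + 1L,
    mu_site_year = cfg$demography$mu_site_year,
    gen_years = cfg$demography$gen_years))
  stage("demography", utils::write.table(
    format(demography, digits = 6), out("demography.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))

  # --- AMOVA -----------------------------------------------------------
  amova_results <- stage("amova", {
    sd1 <- sample_distances(table, aln, population = cfg$group_by)
    res <- list(regions = amova(sd1$d, sd1$design, n_perm = cfg$n_perm,
                                seed = cfg$seed + 2L))
    sd2 <- sample_distances(table, aln, population = cfg$group_by,
                            group = "haplogroup")
    # nest populations within haplogroups (a region hosts both clades)
    sd2$design$population <- paste(sd2$design$group, sd2$design$population,
                                   sep = ":")
    ok2 <- length(unique(sd2$design$group)) >= 2 &&
      length(unique(sd2$design$population)) > length(unique(sd2$design$group))
    if (ok2)
      res$haplogroups_regions <- amova(sd2$d, sd2$design, n_perm = cfg$n_perm,
                                       seed = cfg$seed + 3L)
    res
  })
  stage("amova", for (nm in names(amova_results))
    write_amova(amova_results[[nm]], out(sprintf("amova_%s.tsv", nm))))

  # --- network ---------------------------------------------------------
  net <- stage("network", build_mjn(table, weights = cfg$network$weights,
                                    epsilon = cfg$network$epsilon %||% 0))
  stage("network", {
    export_network(net, out("network.graphml"), "graphml")
    export_network(net, out("network_edges.tsv"), "edge-tsv")
    export_network(net, out("network_nodes.tsv"), "node-tsv")
  })

  manifest <- list(
    package = "mthapnet",
    version = as.character(utils::packageVersion("mthapnet")),
    seed = cfg$seed,
    stage_seeds = list(demography = cfg$seed + 1L, amova_regions = cfg$seed + 2L,
                       amova_haplogroups = cfg$seed + 3L),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    n_samples = table$n_samples,
    n_haplotypes = nrow(table$haps),
    outputs = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(aln = aln, sites = sites, table = table,
                 diversity = diversity, demography = demography,
                 amova = amova_results, network = net, manifest = manifest))
}
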