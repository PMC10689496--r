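#' Validate a pipeline configuration
#'
#' Reads (or takes) a YAML configuration, rejects unknown stages and fields,
#' type-checks the values and fills defaults (thinning, burn-in, 20 nested
#' sampling particles, ...). The configuration drives [run_pipeline()].
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return validated config (class `pipeline_config`) with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    out_dir = "pipeline_out",
    stages = c("simulate"),
    simulate = list(reference_tree = TRUE, sim = list()),
    phylo = list(cognates = NULL, model = "covarion", gamma = 1L,
                 clock = "ucln", generations = 2e5, thin = 200,
                 burnin = 0.1, zan_sigma = 10,
                 calibration_tips = c("Megrelian", "Laz")),
    compare = list(cognates = NULL,
                   models = c("covarion_relaxed", "covarion_strict",
                              "ctmc_relaxed"),
                   particles = 20L, subchain = 30L),
    niche = list(n_taxa = 3L, background = 2000L),
    biome = list(),
    pca = list(prefix = NULL, k = 10L)
  )
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  known_stages <- c("simulate", "phylo", "compare", "niche", "biome", "pca")
  bad_stage <- setdiff(cfg$stages, known_stages)
  if (length(bad_stage)) {
    stop("unknown stage name(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  for (blk in intersect(names(config), known_stages)) {
    bad_f <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(bad_f)) {
      stop("unknown field in '", blk, "': ", paste(bad_f, collapse = ", "),
           call. = FALSE)
    }
  }
  if (cfg$phylo$generations <= 0) {
    stop("phylo$generations must be positive", call. = FALSE)
  }
  if (cfg$phylo$thin <= 0) stop("phylo$thin must be positive", call. = FALSE)
  if (cfg$compare$particles < 2) {
    stop("compare$particles must be at least 2", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

model_spec_from_label <- function(label) {
  parts <- strsplit(label, "_")[[1]]
  kind <- parts[1]
  clock_kind <- if (length(parts) > 1 && parts[2] == "strict") "strict" else "ucln"
  gamma <- if (length(parts) > 2 && parts[3] == "g4") 4L else 1L
  list(
    model = substitution_model(kind, gamma_categories = gamma),
    clock = clock_model(clock_kind, rate = 2.5e-4)
  )
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (simulate, phylo,
#' compare, niche, biome, pca), writing each stage's outputs under
#' `out_dir` and a `manifest.json` recording the seed, per-stage outputs
#' and their MD5 checksums.
#'
#' @param config a [validate_config()] result, a YAML path, or a named list
#' @return the manifest (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  manifest <- list(seed = cfg$seed, stages = list())
  note <- function(stage, files) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = unname(tools::md5sum(files))
    )
  }
  order_ <- c("simulate", "phylo", "compare", "niche", "biome", "pca")
  stages <- order_[order_ %in% cfg$stages]
  sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate$sim))

  for (stage in stages) {
    switch(stage,
      simulate = {
        tree <- if (isTRUE(cfg$simulate$reference_tree)) {
          kartvelian_reference_tree(seed = cfg$seed)
        } else {
          simulate_dated_tree(sim)
        }
        ape::write.tree(tree, out("true_tree.nwk"))
        cm <- simulate_cognate_matrix(tree, sim)
        write_cognate_matrix(cm, out("cognates.csv"))
        write_cognate_matrix(add_ascertainment_columns(cm),
                             out("cognates.nex"))
        grids <- simulate_climate_series(sim)
        for (i in seq_along(grids)) {
          write_climate_grid(grids[[i]], out(sprintf("climate_%05dbp",
                                                     grids[[i]]$time_bp)))
        }
        occ <- simulate_taxon_occurrences(grids[[length(grids)]], sim)
        utils::write.csv(occ, out("occurrences.csv"), row.names = FALSE)
        pol <- simulate_pollen_sites(grids, sim)
        utils::write.csv(pol, out("pollen_sites.csv"), row.names = FALSE)
        cs <- simulate_culture_sites(grids, sim)
        utils::write.csv(cs, out("culture_sites.csv"), row.names = FALSE)
        g <- simulate_genotype_data(sim)
        write_eigenstrat(g, out("panel"))
        note("simulate", out(c("true_tree.nwk", "cognates.csv",
                               "cognates.nex", "occurrences.csv",
                               "pollen_sites.csv", "culture_sites.csv",
                               "panel.geno", "panel.snp", "panel.ind")))
      },
      phylo = {
        path <- cfg$phylo$cognates %||% out("cognates.csv")
        if (!file.exists(path)) stop("phylo stage: missing cognate file ",
                                     path, call. = FALSE)
        cm <- read_cognate_matrix(path)
        if (!any(cm$columns$is_ascertainment)) {
          cm <- add_ascertainment_columns(cm)
        }
        cal <- if (cfg$phylo$zan_sigma > 0 &&
                   all(cfg$phylo$calibration_tips %in% languages(cm))) {
          calibration_set(node_calibrations = list(list(
            tips = cfg$phylo$calibration_tips, mean = 1200,
            sigma = cfg$phylo$zan_sigma)))
        } else {
          calibration_set()
        }
        ps <- run_mcmc(
          cm,
          substitution_model(cfg$phylo$model,
                             gamma_categories = as.integer(cfg$phylo$gamma)),
          clock_model(cfg$phylo$clock, rate = 2.5e-4), cal,
          mcmc_config(n_generations = cfg$phylo$generations,
                      thin = cfg$phylo$thin,
                      burnin_fraction = cfg$phylo$burnin,
                      seed = cfg$seed)
        )
        utils::write.table(ps$trace, out("trace.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        class(ps$trees) <- "multiPhylo"
        ape::write.nexus(ps$trees, file = out("trees.nex"))
        # drop ape's timestamp comment so reruns are byte-identical
        tn <- readLines(out("trees.nex"))
        writeLines(tn[!grepl("^\\[R-package APE", tn)], out("trees.nex"))
        mcc <- mcc_tree(ps)
        ape::write.tree(mcc$tree, out("mcc.nwk"))
        jsonlite::write_json(mcc$clades, out("mcc_summary.json"),
                             digits = NA, auto_unbox = TRUE)
        note("phylo", out(c("trace.tsv", "trees.nex", "mcc.nwk",
                            "mcc_summary.json")))
      },
      compare = {
        path <- cfg$compare$cognates %||% out("cognates.csv")
        cm <- read_cognate_matrix(path)
        if (!any(cm$columns$is_ascertainment)) {
          cm <- add_ascertainment_columns(cm)
        }
        cal <- calibration_set(node_calibrations = list(list(
          tips = intersect(c("Megrelian", "Laz"), languages(cm)),
          mean = 1200, sigma = 10)))
        if (length(cal$nodes[[1]]$tips) < 2) cal <- calibration_set()
        results <- lapply(cfg$compare$models, function(lab) {
          spec <- model_spec_from_label(lab)
          nested_sampling_phylo(cm, spec$model, spec$clock, cal,
                                n_particles = cfg$compare$particles,
                                subchain_length = cfg$compare$subchain,
                                seed = cfg$seed)
        })
        names(results) <- cfg$compare$models
        tbl <- build_comparison_table(results)
        utils::write.csv(tbl, out("model_comparison.csv"), row.names = FALSE)
        note("compare", out("model_comparison.csv"))
      },
      niche = {
        grids <- simulate_climate_series(sim)
        ref <- grids[[length(grids)]]
        maps <- list()
        for (i in seq_len(cfg$niche$n_taxa)) {
          sp <- sim
          sp$species$optima$mat <- sim$species$optima$mat + (i - 2) * 2
          occ <- simulate_taxon_occurrences(ref, sp,
                                            taxon = paste0("taxon", i))
          th <- thin_one_per_pixel(occ, ref)
          bg <- sample_background(ref, min(cfg$niche$background,
                                           sum(ref$mask) - 1),
                                  seed = cfg$seed + i)
          fit <- fit_maxent(th, bg, ref)
          thr <- maxsss_threshold(suitability_at(fit, ref, th),
                                  suitability_at(fit, ref, bg))
          maps[[i]] <- binarize(project_suitability(fit, ref), thr)
        }
        co <- cooccurrence(maps)
        g_out <- climate_grid(co + 0, co + 0, time_bp = ref$time_bp)
        write_climate_grid(g_out, out("cooccurrence"))
        note("niche", out(c("cooccurrence_mat.asc", "cooccurrence_ap.asc")))
      },
      biome = {
        grids <- simulate_climate_series(sim)
        pol_path <- out("pollen_sites.csv")
        pol <- if (file.exists(pol_path)) {
          tibble::as_tibble(utils::read.csv(pol_path))
        } else {
          simulate_pollen_sites(grids, sim)
        }
        bm <- fit_biome_model(pol)
        met <- classification_metrics(bm, pol)
        utils::write.csv(
          tibble::tibble(accuracy = met$accuracy, kappa = met$kappa),
          out("biome_metrics.csv"), row.names = FALSE)
        rasters <- lapply(grids, function(g) project_biome_map(bm, g))
        modal <- aggregate_mode(rasters)
        g_out <- climate_grid(modal + 0, modal + 0,
                              time_bp = grids[[1]]$time_bp)
        write_climate_grid(g_out, out("biome_mode"))
        note("biome", out(c("biome_metrics.csv", "biome_mode_mat.asc")))
      },
      pca = {
        prefix <- cfg$pca$prefix %||% out("panel")
        if (!file.exists(paste0(prefix, ".geno"))) {
          stop("pca stage: missing EIGENSTRAT prefix ", prefix, call. = FALSE)
        }
        g <- read_eigenstrat(prefix)
        model <- fit_pca(g, k = min(cfg$pca$k,
                                    sum(g$ind$role == "modern-reference") - 1))
        rep <- pca_report(model, g)
        utils::write.csv(rep, out("pca_report.csv"), row.names = FALSE)
        note("pca", out("pca_report.csv"))
      }
    )
  }
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(manifest)
}
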