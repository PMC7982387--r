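# Pipeline driver: chains the analysis stages over on-disk inputs with a
# structured YAML config and reproducible seeds. The command-line entry
# point (inst/scripts/rhizogeo) is a thin wrapper over run_pipeline().

#' Default pipeline configuration
#'
#' Defaults mirror the study's stated constants: 40-km windows moved at
#' 10-km steps, 10,000 bootstrap draws of size 39, ANI threshold 0.95.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(data_dir = "rhizogeo-data",
       out_dir = "rhizogeo-out",
       loci = NULL,                  # named list locus -> FASTA path
       references = NULL,            # reference FASTA
       reference_labels = NULL,      # TSV: reference, genospecies
       metadata = NULL,              # CSV: strain, latitude, longitude, ...
       traits = NULL,                # CSV trait table
       window_width_km = 40,
       window_step_km = 10,
       n_perm = 9999,
       bootstrap_B = 10000,
       bootstrap_n_draw = 39,
       min_similarity = 0.95,
       control = "control",
       seed = 1)
}

load_config <- function(config = NULL) {
  cfg <- default_config()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_rg("config file not found: ", config,
              class = "rhizogeo_input_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown)) {
      stop_rg("unknown config field(s): ", paste(unknown, collapse = ", "),
              class = "rhizogeo_input_error")
    }
    cfg <- utils::modifyList(cfg, config)
  }
  cfg
}

pipeline_inputs <- function(cfg) {
  dd <- cfg$data_dir
  pick <- function(x, default) if (!is.null(x)) x else default
  loci_paths <- cfg$loci
  if (is.null(loci_paths)) {
    files <- setdiff(list.files(dd, pattern = "\\.fasta$", full.names = TRUE),
                     file.path(dd, "references.fasta"))
    if (!length(files)) {
      stop_rg("no locus FASTA files found in ", dd,
              class = "rhizogeo_input_error")
    }
    loci_paths <- stats::setNames(files, sub("\\.fasta$", "", basename(files)))
  }
  loci <- lapply(names(loci_paths), function(nm)
    read_fasta_alignment(loci_paths[[nm]], nm))
  mla <- concatenate_loci(loci)
  meta_path <- pick(cfg$metadata, file.path(dd, "metadata.csv"))
  meta <- if (file.exists(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(meta)) {
    meta <- meta[order(meta$strain), , drop = FALSE]
  }
  refs_path <- pick(cfg$references, file.path(dd, "references.fasta"))
  refs <- if (file.exists(refs_path)) {
    read_fasta_alignment(refs_path, "reference_panel")
  } else NULL
  lab_path <- pick(cfg$reference_labels, file.path(dd, "reference_labels.tsv"))
  ref_labels <- if (file.exists(lab_path)) {
    tab <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
    stats::setNames(tab$genospecies, tab$reference)
  } else NULL
  traits_path <- pick(cfg$traits, file.path(dd, "traits.csv"))
  traits <- if (file.exists(traits_path)) read_trait_table(traits_path)
            else NULL
  list(mla = mla, meta = meta, refs = refs, ref_labels = ref_labels,
       traits = traits)
}

log_msg <- function(...) message("[rhizogeo] ", ...)

#' Run pipeline stages
#'
#' Executes one or more analysis stages against the inputs named in the
#' configuration, writing TSV artifacts into `out_dir` and logging seeds
#' and parameter values. Stages: `simulate`, `sitestats`, `distances`,
#' `assign`, `diversity`, `mantel`, `pcoa-regress`, `window`, `symbiosis`,
#' or `all`.
#'
#' @param stages Character vector of stage names (default `"all"`).
#' @param config A config list, a YAML file path, or `NULL` for defaults;
#'   see [default_config()].
#' @return Invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(stages = "all", config = NULL) {
  cfg <- load_config(config)
  known <- c("simulate", "sitestats", "distances", "assign", "diversity",
             "mantel", "pcoa-regress", "window", "symbiosis")
  if (identical(stages, "all")) stages <- known
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop_rg("unknown stage(s): ", paste(bad, collapse = ", "),
            class = "rhizogeo_usage_error")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  log_msg("seed = ", cfg$seed)

  if ("simulate" %in% stages) {
    log_msg("simulate -> ", cfg$data_dir)
    ds <- simulate_dataset(simulation_config(seed = cfg$seed))
    write_dataset(ds, cfg$data_dir)
    emit(cfg$data_dir)
  }
  analysis <- setdiff(stages, "simulate")
  if (!length(analysis)) return(invisible(artifacts))

  inp <- pipeline_inputs(cfg)
  mla <- inp$mla

  if ("sitestats" %in% stages) {
    stats_tab <- site_stats_table(c(mla$loci, list(mla$concatenated)))
    p <- file.path(cfg$out_dir, "site_stats.tsv")
    write_site_stats(stats_tab, p); emit(p)
    log_msg("sitestats: ", nrow(stats_tab), " alignments")
  }

  need_dist <- any(c("distances", "diversity", "mantel", "pcoa-regress",
                     "window") %in% stages)
  if (need_dist) {
    nt <- p_distance_matrix(mla$concatenated)
    hap <- allele_sharing_distance(call_haplotypes(mla))
  }
  if ("distances" %in% stages) {
    tn <- tn93_distance_matrix(mla$concatenated)
    for (d in list(nt = nt, tn93 = tn, haplotype = hap)) {
      p <- file.path(cfg$out_dir, paste0("dist_", attr(d, "level"), ".tsv"))
      write_distance_tsv(d, p); emit(p)
    }
    log_msg("distances: nucleotide, TN93, haplotype")
  }

  assign <- NULL
  if (any(c("assign", "diversity", "mantel") %in% stages) &&
      !is.null(inp$refs)) {
    assign <- assign_genospecies(mla$concatenated, inp$refs,
                                 inp$ref_labels, cfg$min_similarity)
  }
  if ("assign" %in% stages) {
    if (is.null(assign)) {
      stop_rg("assign stage needs references.fasta and reference_labels.tsv",
              class = "rhizogeo_input_error")
    }
    p <- file.path(cfg$out_dir, "genospecies_assignment.tsv")
    write_assignment_tsv(assign, p); emit(p)
    log_msg("assign: ", sum(assign$genospecies != "unassigned"), "/",
            nrow(assign), " strains assigned")
  }

  if ("diversity" %in% stages) {
    if (is.null(assign)) {
      stop_rg("diversity stage needs genospecies assignments",
              class = "rhizogeo_input_error")
    }
    gs <- stats::setNames(assign$genospecies, assign$strain)
    rep_tab <- diversity_report(list(all = assign$strain), nt, hap, gs)
    p <- file.path(cfg$out_dir, "diversity.tsv")
    utils::write.table(rep_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
    log_msg("diversity: Shannon ", round(rep_tab$shannon[1], 3),
            ", Simpson ", round(rep_tab$simpson[1], 3))
  }

  need_geo <- any(c("mantel", "pcoa-regress", "window") %in% stages)
  if (need_geo) {
    if (is.null(inp$meta)) {
      stop_rg("spatial stages need metadata.csv with coordinates",
              class = "rhizogeo_input_error")
    }
    geo <- geographic_distance_matrix(inp$meta)
    alt <- scalar_distance_matrix(
      stats::setNames(inp$meta$elevation_m, inp$meta$strain), "elevation_m")
  }

  if ("mantel" %in% stages) {
    rows <- list()
    lvls <- list(nucleotides = nt, haplotypes = hap)
    if (!is.null(assign) && all(assign$genospecies != "unassigned")) {
      lvls$species <- species_distance_matrix(assign)
    }
    for (nm in names(lvls)) {
      m1 <- mantel_test(lvls[[nm]], geo, cfg$n_perm, seed = cfg$seed)
      m2 <- mantel_test(lvls[[nm]], alt, cfg$n_perm, seed = cfg$seed)
      m3 <- partial_mantel_test(lvls[[nm]], geo, alt, cfg$n_perm,
                                seed = cfg$seed, covariate = "Alt")
      rows[[nm]] <- data.frame(
        level = nm, matrix = c("Geo", "Alt", "Geo"),
        covariate = c("", "", "Alt"),
        r = c(m1$r, m2$r, m3$r), p = c(m1$p, m2$p, m3$p))
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    p <- file.path(cfg$out_dir, "mantel.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    log_msg("mantel: ", nrow(tab), " tests, n_perm = ", cfg$n_perm)
  }

  if ("pcoa-regress" %in% stages) {
    gen_pc <- principal_coordinates(nt)
    geo_pc <- principal_coordinates(geo)
    altv <- stats::setNames(inp$meta$elevation_m, inp$meta$strain)
    tab <- pcoa_regression(gen_pc, geo_pc, altv)
    p <- file.path(cfg$out_dir, "pcoa_regression.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    log_msg("pcoa-regress: ", nrow(tab), " terms")
  }

  if ("window" %in% stages) {
    prof <- sliding_window_decay(nt, hap, geo, cfg$window_width_km,
                                 cfg$window_step_km, seed = cfg$seed)
    p <- file.path(cfg$out_dir, "window_profile.tsv")
    utils::write.table(as.data.frame(prof), p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
    log_msg("window: ", nrow(prof), " windows (width ", cfg$window_width_km,
            " km, step ", cfg$window_step_km, " km), decay Spearman = ",
            round(window_decay_correlation(prof), 3))
  }

  if ("symbiosis" %in% stages) {
    if (is.null(inp$traits)) {
      stop_rg("symbiosis stage needs traits.csv",
              class = "rhizogeo_input_error")
    }
    tt <- inp$traits
    rs <- response_pca(tt)
    p <- file.path(cfg$out_dir, "response_scores.tsv")
    utils::write.table(rs$scores, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
    vc <- variance_components(rs$scores$score, rs$scores$strain,
                              rs$scores$replicate)
    inoc <- tt[tt$strain != cfg$control, ]
    dn <- dunnett_vs_control(tt$shoot_dw_g, tt$strain, cfg$control,
                             seed = cfg$seed)
    p2 <- file.path(cfg$out_dir, "dunnett.tsv")
    utils::write.table(dn, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p2)
    p3 <- file.path(cfg$out_dir, "variance_components.tsv")
    utils::write.table(
      data.frame(component = c("strain", "replicate", "error"),
                 sigma2 = c(vc$sigma2_strain, vc$sigma2_replicate,
                            vc$sigma2_error),
                 F = c(vc$F, NA, NA), p = c(vc$p.value, NA, NA)),
      p3, sep = "\t", quote = FALSE, row.names = FALSE); emit(p3)
    log_msg("symbiosis: strain F = ", round(vc$F, 3), ", ",
            sum(dn$significant), " strain(s) above control")
  }
  invisible(artifacts)
}

#' Command-line entry point
#'
#' Parses `rhizogeo <subcommand> [--config file.yaml] [--seed N]
#' [--data-dir D] [--out-dir D]` and dispatches to [run_pipeline()].
#' Subcommand `all` runs every stage.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
run_pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: rhizogeo <stage> [--config FILE] [--seed N] ",
    "[--data-dir DIR] [--out-dir DIR]\n",
    "stages: all simulate sitestats distances assign diversity mantel ",
    "pcoa-regress window symbiosis")
  if (!length(args)) {
    message(usage)
    return(invisible(2L))
  }
  stage <- args[1]
  rest <- args[-1]
  opt <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) {
      message("unrecognized argument: ", key, "\n", usage)
      return(invisible(2L))
    }
    val <- rest[i + 1L]
    opt[[sub("^--", "", key)]] <- val
    i <- i + 2L
  }
  config <- opt[["config"]]
  overrides <- list()
  if (!is.null(opt[["seed"]])) overrides$seed <- as.integer(opt[["seed"]])
  if (!is.null(opt[["data-dir"]])) overrides$data_dir <- opt[["data-dir"]]
  if (!is.null(opt[["out-dir"]])) overrides$out_dir <- opt[["out-dir"]]
  cfg <- tryCatch(load_config(config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(invisible(1L))
  }
  cfg <- utils::modifyList(cfg, overrides)
  status <- tryCatch({
    run_pipeline(if (stage == "all") "all" else stage, cfg)
    0L
  }, rhizogeo_usage_error = function(e) {
    message(conditionMessage(e), "\n", usage); 2L
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}
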