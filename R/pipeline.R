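# End-to-end orchestration: simulate or ingest -> standardize -> diversity ->
# correlation networks -> ordination models -> differential expression ->
# pathway models, written to one report directory with a machine-readable
# manifest. One global seed is expanded into per-stage substreams so each
# stage is reproducible in isolation; a rerun with the same configuration is
# bit-identical.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] (used when `input_dir` is NULL)
#' @param input_dir optional directory of an existing dataset written by
#'   [write_dataset()]; when given, simulation is skipped
#' @param alpha significance threshold used throughout
#' @param B_corr permutations for correlation networks
#' @param B_ord permutations for ordination tests
#' @param k_pathway_clusters fixed k for pathway clustering, or NULL to pick
#'   by silhouette
#' @param edge_cutoff quantile cutoff for the exported edge list
#' @param seed global seed expanded into per-stage substreams
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            alpha = 0.05, B_corr = 499L, B_ord = 199L,
                            k_pathway_clusters = NULL, edge_cutoff = 0.75,
                            seed = 1L) {
  cfg <- list(synth = synth, input_dir = input_dir, alpha = alpha,
              B_corr = as.integer(B_corr), B_ord = as.integer(B_ord),
              k_pathway_clusters = k_pathway_clusters,
              edge_cutoff = edge_cutoff, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `synth` block
#' holds [synth_config()] fields.
#' @param path YAML file
#' @return `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$cultures))
    synth_args$cultures <- do.call(rbind, lapply(synth_args$cultures,
                                                 as.data.frame))
  y$synth <- do.call(synth_config, synth_args)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' @param config [pipeline_config()] or a YAML path accepted by
#'   [read_pipeline_config()]
#' @param out_dir report directory (created; overwritten files are replaced)
#' @return invisibly, the manifest list; all outputs are TSV/JSON files under
#'   `out_dir`
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), fail_marker)
    stop(e)
  }
  withCallingHandlers(
    manifest <- .run_all_impl(config, out_dir),
    error = on_fail)
  invisible(manifest)
}

.run_all_impl <- function(config, out_dir) {
  seed <- config$seed
  alpha <- config$alpha
  dirs <- file.path(out_dir, c("data", "standardized", "diversity", "corrnet",
                               "ordination", "de", "pathways"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("symbiocor")),
                   seed = seed, alpha = alpha,
                   parameters = list(B_corr = config$B_corr,
                                     B_ord = config$B_ord,
                                     edge_cutoff = config$edge_cutoff))

  ## -- ingest / simulate ---------------------------------------------------
  ds <- .stage("ingest", {
    if (is.null(config$input_dir)) {
      cfg <- config$synth
      cfg$seed <- derive_seed(seed, 1L)
      ds <- generate_dataset(cfg)
      write_dataset(ds, file.path(out_dir, "data"))
      ds
    } else {
      read_dataset(config$input_dir)
    }
  })
  al <- align_samples(ds$counts, ds$meta)
  counts <- al$matrices
  meta <- al$meta
  status_of <- stats::setNames(meta$status, meta$sample_id)

  ## organism presence masks: a symbiont is analyzed over the samples whose
  ## cultures carry it
  present <- list(host = meta$sample_id,
                  symA = meta$sample_id[meta$status != "singleB"],
                  symB = meta$sample_id[meta$status != "singleA"])

  ## -- read proportions (unstandardized) -----------------------------------
  prop_tab <- .stage("proportions", {
    rows <- list()
    for (org in c("symA", "symB")) {
      s <- present[[org]]
      pr <- symbiont_host_proportion(counts[[org]][, s, drop = FALSE],
                                     counts$host[, s, drop = FALSE])
      grp <- ifelse(status_of[s] == "mixed", "mixed", "single")
      tst <- compare_proportions(pr, grp)
      rows[[org]] <- data.frame(organism = org, sample_id = s,
                                proportion = unname(pr), group = grp,
                                U = tst$U, z = tst$z, p = tst$p,
                                stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    .write_tsv(tab, file.path(out_dir, "standardized", "read_proportions.tsv"))
    tab
  })

  ## -- standardization ------------------------------------------------------
  std <- .stage("standardize", {
    std <- list()
    for (org in names(counts)) {
      sub <- counts[[org]][, present[[org]], drop = FALSE]
      std[[org]] <- downsample_to_min(sub, seed = derive_seed(seed, 10L))
      write_counts(std[[org]],
                   file.path(out_dir, "standardized",
                             paste0("counts_", org, ".tsv")))
    }
    std
  })

  ## -- diversity ------------------------------------------------------------
  .stage("diversity", {
    div <- do.call(rbind, lapply(names(std), function(org) {
      pr <- shannon_profile(std[[org]])
      pr$organism <- org
      pr$group <- ifelse(status_of[pr$sample_id] == "mixed", "mixed", "single")
      pr
    }))
    .write_tsv(div, file.path(out_dir, "diversity", "shannon.tsv"))
    comp <- do.call(rbind, lapply(unique(div$organism), function(org) {
      d <- div[div$organism == org, ]
      tst <- compare_diversity(d$H, d$group)
      data.frame(organism = org, U = tst$U, z = tst$z, p = tst$p,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(comp, file.path(out_dir, "diversity", "comparisons.tsv"))
    ## symbiont-B vs host diversity regression over shared samples
    hb <- merge(div[div$organism == "symB", c("sample_id", "H")],
                div[div$organism == "host", c("sample_id", "H")],
                by = "sample_id", suffixes = c("_symB", "_host"))
    if (nrow(hb) >= 3L && stats::var(hb$H_symB) > 0) {
      rg <- regress_diversity(hb$H_symB, hb$H_host)
      .write_tsv(data.frame(slope = rg$slope, intercept = rg$intercept,
                            r_squared = rg$r_squared, F = rg$F,
                            df1 = rg$df[1], df2 = rg$df[2], p = rg$p),
                 file.path(out_dir, "diversity", "regression_symB_host.tsv"))
      .write_tsv(rg$bands, file.path(out_dir, "diversity",
                                     "regression_bands.tsv"))
    }
    NULL
  })

  ## -- correlation networks -------------------------------------------------
  nets <- .stage("corrnet", {
    mixed_ids <- meta$sample_id[meta$status == "mixed"]
    specs <- list(
      AB_mixed = list(m1 = "symA", m2 = "symB", samples = mixed_ids),
      Ahost_single = list(m1 = "symA", m2 = "host",
                          samples = meta$sample_id[meta$status == "singleA"]),
      Ahost_mixed = list(m1 = "symA", m2 = "host", samples = mixed_ids),
      Bhost_single = list(m1 = "symB", m2 = "host",
                          samples = meta$sample_id[meta$status == "singleB"]),
      Bhost_mixed = list(m1 = "symB", m2 = "host", samples = mixed_ids))
    nets <- list()
    summaries <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      s <- sp$samples
      net <- suppressMessages(cross_network(
        std[[sp$m1]][, s, drop = FALSE], std[[sp$m2]][, s, drop = FALSE],
        B = config$B_corr, alpha = alpha,
        seed = derive_seed(seed, 20L + match(nm, names(specs))),
        condition = nm))
      sc <- signed_counts(net)
      summaries[[nm]] <- data.frame(network = nm, n_samples = length(s),
                                    total_pos = sc$total_pos,
                                    total_neg = sc$total_neg,
                                    stringsAsFactors = FALSE)
      .write_tsv(sc$profiles$rows,
                 file.path(out_dir, "corrnet", paste0("profiles_", nm, ".tsv")))
      nets[[nm]] <- net
    }
    .write_tsv(do.call(rbind, summaries),
               file.path(out_dir, "corrnet", "signed_counts.tsv"))
    el <- edge_list(nets$AB_mixed, config$edge_cutoff)
    .write_tsv(el, file.path(out_dir, "corrnet", "edges_AB_mixed.tsv"))
    ## outliers over host genes (columns of the host-partner networks)
    hostprof <- merge(signed_counts(nets$Bhost_single)$profiles$cols,
                      signed_counts(nets$Bhost_mixed)$profiles$cols,
                      by = "gene_id", suffixes = c("_single", "_mixed"))
    if (nrow(hostprof) >= 5L)
      .write_tsv(detect_outliers(hostprof),
                 file.path(out_dir, "corrnet", "host_outliers.tsv"))
    nets
  })

  ## -- ordination models ----------------------------------------------------
  .stage("ordination", {
    rows <- list()
    add_row <- function(dep, indep, fit, extra = NA_real_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        dependent = dep, independent = indep, df = fit$df,
        F = fit$F, R2 = fit$R2, p = fit$p, stringsAsFactors = FALSE)
    }
    ## ANOSIM single vs mixed per organism
    an_rows <- list()
    for (org in names(std)) {
      s <- colnames(std[[org]])
      grp <- ifelse(status_of[s] == "mixed", "mixed", "single")
      D <- bray_curtis(t(std[[org]]))
      an <- anosim_test(D, grp, B = config$B_ord,
                        seed = derive_seed(seed, 30L + match(org, names(std))))
      an_rows[[org]] <- data.frame(organism = org, R = an$R, p = an$p,
                                   method = an$method, stringsAsFactors = FALSE)
      ## SIMPER on the same contrast
      simp <- simper(t(std[[org]]), grp)
      .write_tsv(as.data.frame(simp),
                 file.path(out_dir, "ordination", paste0("simper_", org, ".tsv")))
    }
    .write_tsv(do.call(rbind, an_rows),
               file.path(out_dir, "ordination", "anosim.tsv"))
    ## directional presence/absence models: symbiont genes ~ other symbiont
    s_a <- colnames(std$symA)
    fitA <- dbrda(bray_curtis(t(std$symA)),
                  data.frame(partner = factor(status_of[s_a] == "mixed")),
                  B = config$B_ord, seed = derive_seed(seed, 41L))
    add_row("symA_genes", "symB_presence", fitA)
    s_b <- colnames(std$symB)
    fitB <- dbrda(bray_curtis(t(std$symB)),
                  data.frame(partner = factor(status_of[s_b] == "mixed")),
                  B = config$B_ord, seed = derive_seed(seed, 42L))
    add_row("symB_genes", "symA_presence", fitB)
    ## host genes ~ infection status
    fitH <- dbrda(bray_curtis(t(std$host)),
                  data.frame(status = factor(status_of[colnames(std$host)])),
                  B = config$B_ord, seed = derive_seed(seed, 43L))
    add_row("host_genes", "infection_status", fitH)
    .write_tsv(do.call(rbind, rows),
               file.path(out_dir, "ordination", "dbrda_models.tsv"))
    NULL
  })

  ## -- differential expression ----------------------------------------------
  .stage("diffexpr", {
    for (org in names(std)) {
      s <- colnames(std[[org]])
      grp <- factor(ifelse(status_of[s] == "mixed", "mixed", "single"),
                    levels = c("single", "mixed"))
      res <- de_test(std[[org]], grp, alpha = alpha)
      volcano_table(res, file.path(out_dir, "de", paste0("volcano_", org, ".tsv")))
      .write_tsv(as.data.frame(res),
                 file.path(out_dir, "de", paste0("de_", org, ".tsv")))
    }
    NULL
  })

  ## -- pathway models --------------------------------------------------------
  if (is.null(ds$annotation)) {
    warning("no annotation available: pathway stage skipped")
    manifest$pathway_stage <- "skipped (no annotation)"
  } else {
    .stage("pathways", {
      eff <- suppressWarnings(pathway_effects(
        std$host, ds$annotation,
        sym = list(symA = std$symA, symB = std$symB), meta = meta,
        B = config$B_ord, alpha = alpha, seed = derive_seed(seed, 50L)))
      cl <- cluster_pathways(eff$R2, k = config$k_pathway_clusters,
                             seed = derive_seed(seed, 51L))
      pathway_effect_table(eff, cl,
                           file.path(out_dir, "pathways", "pathway_effects.tsv"))
      .write_tsv(data.frame(metric = names(cl$summary),
                            value = unname(cl$summary)),
                 file.path(out_dir, "pathways", "cluster_summary.tsv"))
      NULL
    })
    manifest$pathway_stage <- "completed"
  }

  ## -- manifest --------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- lapply(stats::setNames(files, sub(paste0("^", out_dir, "/?"),
                                                      "", files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
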