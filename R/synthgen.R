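# Synthetic tripartite meta-transcriptome generator.
#
# Emulates the study design: two symbiont-A single-infected cultures (5L, 5S),
# two symbiont-B single-infected cultures (5N, 5P) and four mixed cultures
# (5LN, 5LP, 5SN, 5SP), seven replicate flasks each. Counts are
# gamma-Poisson (negative binomial) around gene means that combine a
# lognormal baseline, shared per-sample latent factors (planting
# inter-organism correlation), and planted fold changes in mixed cultures.
# Symbiont B reads drop by a configurable factor (default 10-fold) in mixed
# cultures; symbionts absent from a culture contribute exact zero counts.
#
# The latent correlation structure is planted through a small set of
# high-abundance "driver" genes per symbiont that respond to shared
# per-sample latent factors. Because downstream standardization fixes each
# sample's total (compositional closure), the remaining genes' relative
# shares move opposite to the drivers, so the signal survives rarefaction:
# with symbiont-B drivers sign-flipped in mixed samples (latent_sign_mix of
# them), the bulk of A-vs-B gene pairs correlate negatively, as a simple
# uniform per-gene loading would not after closure.

DEFAULT_CULTURES <- data.frame(
  culture = c("5L", "5S", "5N", "5P", "5LN", "5LP", "5SN", "5SP"),
  status = c("singleA", "singleA", "singleB", "singleB",
             "mixed", "mixed", "mixed", "mixed"),
  stringsAsFactors = FALSE
)

.per_organism <- function(x, field) {
  if (length(x) == 1L && is.null(names(x)))
    x <- stats::setNames(rep(x, 3L), ORGANISMS)
  if (!all(ORGANISMS %in% names(x)))
    stop("invalid '", field, "': must be a scalar or named for host, symA, symB")
  x[ORGANISMS]
}

.check_field <- function(ok, field, what) {
  if (!isTRUE(all(ok))) stop("invalid '", field, "': ", what)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults are the desk-scale analogue of the study design: 60 host genes,
#' 30 genes per symbiont, 7 replicates of the 8 cultures, a 10-fold drop of
#' the symbiont-B read proportion in mixed cultures, and 90% negative
#' symbiont-A-vs-B latent loadings in mixed samples.
#'
#' @param n_genes_host,n_genes_symA,n_genes_symB gene counts per organism
#' @param cultures data.frame with columns `culture`, `status`
#' @param n_replicates replicate flasks per culture
#' @param lib_size_mean expected total reads per sample
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2)
#' @param prop_symA_single,prop_symB_single expected read fraction of each
#'   symbiont in its single-infected cultures
#' @param prop_symB_mixed_factor multiplier on the symbiont-B fraction in
#'   mixed cultures (default 0.1: the 10-fold drop)
#' @param n_latent number of shared latent factors (0 disables planted
#'   correlation)
#' @param latent_sign_mix fraction of symbiont-B driver loadings whose sign
#'   is flipped in mixed samples, planting negative A-vs-B correlations
#' @param latent_sd scale of latent loadings (log-space half-normal)
#' @param driver_frac fraction of each symbiont's genes acting as
#'   latent-responsive drivers
#' @param driver_boost baseline-abundance multiplier for driver genes (large
#'   drivers make the closure back-reaction on the remaining genes
#'   detectable)
#' @param n_de_genes planted differentially expressed genes per organism;
#'   scalar or named vector (host, symA, symB)
#' @param de_log2fc planted absolute log2 fold change (mixed vs single);
#'   scalar or named vector
#' @param n_pathways,pathway_size host pathways in the synthetic annotation;
#'   the first half are planted as symbiont-responsive (their genes carry
#'   latent loadings), the second half as unresponsive
#' @param seed integer RNG seed
#' @return validated configuration list of class `synth_config`
#' @export
synth_config <- function(n_genes_host = 60L, n_genes_symA = 30L,
                         n_genes_symB = 30L, cultures = DEFAULT_CULTURES,
                         n_replicates = 7L, lib_size_mean = 5e5,
                         dispersion = 0.05,
                         prop_symA_single = 0.08, prop_symB_single = 0.1,
                         prop_symB_mixed_factor = 0.1,
                         n_latent = 1L, latent_sign_mix = 0.9,
                         latent_sd = 1, driver_frac = 0.04,
                         driver_boost = 25,
                         n_de_genes = c(host = 10L, symA = 6L, symB = 6L),
                         de_log2fc = 2,
                         n_pathways = 8L, pathway_size = 5L,
                         seed = 1L) {
  cfg <- list(
    n_genes_host = as.integer(n_genes_host),
    n_genes_symA = as.integer(n_genes_symA),
    n_genes_symB = as.integer(n_genes_symB),
    cultures = as.data.frame(cultures, stringsAsFactors = FALSE),
    n_replicates = as.integer(n_replicates),
    lib_size_mean = lib_size_mean, dispersion = dispersion,
    prop_symA_single = prop_symA_single,
    prop_symB_single = prop_symB_single,
    prop_symB_mixed_factor = prop_symB_mixed_factor,
    n_latent = as.integer(n_latent), latent_sign_mix = latent_sign_mix,
    latent_sd = latent_sd, driver_frac = driver_frac,
    driver_boost = driver_boost,
    n_de_genes = .per_organism(n_de_genes, "n_de_genes"),
    de_log2fc = .per_organism(de_log2fc, "de_log2fc"),
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    seed = as.integer(seed)
  )
  .check_field(cfg$n_genes_host >= 1, "n_genes_host", "must be >= 1")
  .check_field(cfg$n_genes_symA >= 1, "n_genes_symA", "must be >= 1")
  .check_field(cfg$n_genes_symB >= 1, "n_genes_symB", "must be >= 1")
  .check_field(all(c("culture", "status") %in% names(cfg$cultures)),
               "cultures", "needs columns culture, status")
  .check_field(all(cfg$cultures$status %in% STATUSES), "cultures",
               "status must be singleA, singleB or mixed")
  .check_field(!anyDuplicated(cfg$cultures$culture), "cultures",
               "culture ids must be unique")
  .check_field(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  .check_field(cfg$lib_size_mean > 0, "lib_size_mean", "must be > 0")
  .check_field(cfg$dispersion > 0, "dispersion", "must be > 0")
  .check_field(cfg$prop_symA_single > 0 && cfg$prop_symA_single <= 1,
               "prop_symA_single", "must be in (0, 1]")
  .check_field(cfg$prop_symB_single > 0 && cfg$prop_symB_single <= 1,
               "prop_symB_single", "must be in (0, 1]")
  .check_field(cfg$prop_symB_mixed_factor > 0 && cfg$prop_symB_mixed_factor <= 1,
               "prop_symB_mixed_factor", "must be in (0, 1]")
  .check_field(cfg$prop_symA_single + cfg$prop_symB_single < 1,
               "prop_symA_single", "symbiont fractions must leave host reads")
  .check_field(cfg$n_latent >= 0, "n_latent", "must be >= 0")
  .check_field(cfg$latent_sign_mix >= 0 && cfg$latent_sign_mix <= 1,
               "latent_sign_mix", "must be in [0, 1]")
  .check_field(cfg$latent_sd > 0, "latent_sd", "must be > 0")
  .check_field(cfg$driver_frac > 0 && cfg$driver_frac <= 1,
               "driver_frac", "must be in (0, 1]")
  .check_field(cfg$driver_boost >= 1, "driver_boost", "must be >= 1")
  .check_field(all(cfg$n_de_genes >= 0), "n_de_genes", "must be >= 0")
  .check_field(cfg$n_de_genes["host"] <= cfg$n_genes_host &&
                 cfg$n_de_genes["symA"] <= cfg$n_genes_symA &&
                 cfg$n_de_genes["symB"] <= cfg$n_genes_symB,
               "n_de_genes", "cannot exceed the organism's gene count")
  .check_field(cfg$n_pathways >= 0, "n_pathways", "must be >= 0")
  .check_field(cfg$n_pathways * cfg$pathway_size <= cfg$n_genes_host,
               "n_pathways", "n_pathways * pathway_size exceeds host genes")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic tripartite dataset with known ground truth
#'
#' @param config a [synth_config()]
#' @return list with `counts` (named list of host/symA/symB count matrices),
#'   `meta` (sample table), `annotation` (host gene annotation map) and
#'   `truth` (planted structure: DE genes with signs, latent loadings, the
#'   symbiont-B sign-flip indicator, expected per-culture read proportions,
#'   and the planted pathway cluster assignment)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  set.seed(config$seed)

  cult <- config$cultures
  meta <- do.call(rbind, lapply(seq_len(nrow(cult)), function(i) {
    data.frame(
      sample_id = paste0(cult$culture[i], "_r", seq_len(config$n_replicates)),
      culture = cult$culture[i], status = cult$status[i],
      replicate = seq_len(config$n_replicates), stringsAsFactors = FALSE)
  }))
  meta <- sample_table(meta)
  ns <- nrow(meta)

  gene_ids <- list(
    host = sprintf("hg%04d", seq_len(config$n_genes_host)),
    symA = sprintf("ag%04d", seq_len(config$n_genes_symA)),
    symB = sprintf("bg%04d", seq_len(config$n_genes_symB)))
  ngenes <- lengths(gene_ids)

  ## expected organism read fractions per sample
  prop <- matrix(0, ns, 3L, dimnames = list(meta$sample_id, ORGANISMS))
  prop[meta$status != "singleB", "symA"] <- config$prop_symA_single
  prop[meta$status == "singleB", "symB"] <- config$prop_symB_single
  prop[meta$status == "mixed", "symB"] <-
    config$prop_symB_single * config$prop_symB_mixed_factor
  prop[meta$status == "singleA", "symA"] <- config$prop_symA_single
  prop[, "host"] <- 1 - prop[, "symA"] - prop[, "symB"]

  ## host pathway annotation; first half of the pathways planted as
  ## symbiont-responsive
  annotation <- NULL
  pathway_clusters <- integer(0)
  responsive_host <- character(0)
  unresponsive_host <- character(0)
  if (config$n_pathways > 0L) {
    pw_ids <- sprintf("pw%02d", seq_len(config$n_pathways))
    pool <- utils::head(immune_regulatory_pathways,
                        config$n_pathways)
    pw_names <- c(pool, pw_ids[seq_len(max(0, config$n_pathways - length(pool)))])
    pw_names <- pw_names[seq_len(config$n_pathways)]
    assigned <- gene_ids$host[seq_len(config$n_pathways * config$pathway_size)]
    pw_of_gene <- rep(pw_ids, each = config$pathway_size)
    annotation <- annotation_map(data.frame(
      gene_id = assigned,
      ko = sprintf("K%05d", seq_along(assigned)),
      pathway_id = pw_of_gene,
      pathway_name = pw_names[match(pw_of_gene, pw_ids)],
      stringsAsFactors = FALSE))
    pathway_clusters <- stats::setNames(
      ifelse(seq_len(config$n_pathways) <= ceiling(config$n_pathways / 2), 1L, 2L),
      pw_ids)
    responsive_host <- assigned[pw_of_gene %in% pw_ids[pathway_clusters == 1L]]
    unresponsive_host <- assigned[pw_of_gene %in% pw_ids[pathway_clusters == 2L]]
  }

  ## latent factors shared by all organisms within a sample
  z <- if (config$n_latent > 0L)
    matrix(stats::rnorm(config$n_latent * ns), config$n_latent, ns) else
    matrix(0, 0L, ns)

  loadings <- list()
  drivers <- list(host = character(0), symA = character(0), symB = character(0))
  flip_symB <- stats::setNames(logical(ngenes[["symB"]]), gene_ids$symB)
  for (org in ORGANISMS) {
    L <- matrix(0, ngenes[[org]], max(config$n_latent, 0L),
                dimnames = list(gene_ids[[org]], NULL))
    if (config$n_latent > 0L) {
      if (org == "host") {
        ## responsive pathway genes carry signed loadings (no drivers):
        ## their expression tracks the latent factors that also drive the
        ## symbiont genes, making those pathways predictable from them
        aff <- which(gene_ids$host %in% responsive_host)
        if (length(aff)) {
          fac <- sample.int(config$n_latent, length(aff), replace = TRUE)
          val <- config$latent_sd * stats::runif(length(aff), 0.5, 1.5) *
            sample(c(-1, 1), length(aff), replace = TRUE)
          L[cbind(aff, fac)] <- val
        }
      } else {
        nd <- max(1L, round(config$driver_frac * ngenes[[org]]))
        didx <- sample.int(ngenes[[org]], nd)
        drivers[[org]] <- gene_ids[[org]][didx]
        fac <- sample.int(config$n_latent, nd, replace = TRUE)
        val <- config$latent_sd * stats::runif(nd, 0.8, 1.2)
        L[cbind(didx, fac)] <- val
        if (org == "symB") {
          nflip <- round(config$latent_sign_mix * nd)
          if (nflip > 0L)
            flip_symB[didx[sample.int(nd, nflip)]] <- TRUE
        }
      }
    }
    loadings[[org]] <- L
  }

  ## planted DE genes: respond to double infection (mixed vs single).
  ## Signs alternate up/down and (in the count model below) each up-gene is
  ## weight-paired with its down partner so the organism's total output is
  ## unchanged — otherwise standardization to a fixed total would shift every
  ## non-DE gene's share and break the null for unplanted genes. Driver genes
  ## are excluded from the DE pool.
  de <- list()
  for (org in ORGANISMS) {
    nde <- config$n_de_genes[[org]]
    pool <- setdiff(gene_ids[[org]], drivers[[org]])
    if (nde > length(pool)) nde <- length(pool)
    ids <- if (nde > 0L) sample(pool, nde) else character(0)
    sg <- if (nde > 0L) rep_len(c(1, -1), nde) else numeric(0)
    de[[org]] <- data.frame(gene_id = ids, sign = sg,
                            log2fc = sg * config$de_log2fc[[org]],
                            stringsAsFactors = FALSE)
  }

  mixed <- meta$status == "mixed"
  counts <- list()
  for (org in ORGANISMS) {
    w <- stats::rlnorm(ngenes[[org]], 0, 1)
    isdrv <- gene_ids[[org]] %in% drivers[[org]]
    if (any(isdrv)) w[isdrv] <- config$driver_boost * mean(w[!isdrv])
    ## weight-pair planted up/down DE genes (total-output preservation)
    dd <- de[[org]]
    if (nrow(dd) >= 2L) {
      fc <- 2^config$de_log2fc[[org]]
      for (i in seq(1L, nrow(dd) - 1L, by = 2L)) {
        up <- match(dd$gene_id[i], gene_ids[[org]])
        dn <- match(dd$gene_id[i + 1L], gene_ids[[org]])
        w[dn] <- w[up] * fc
      }
    }
    w <- w / sum(w)
    mu <- outer(w, config$lib_size_mean * prop[, org])
    if (config$n_latent > 0L) {
      L <- loadings[[org]]
      if (org == "symB" && any(flip_symB)) {
        mod <- exp(L %*% z)
        mod_flip <- exp((-L) %*% z)
        mod[flip_symB, mixed] <- mod_flip[flip_symB, mixed]
      } else {
        mod <- exp(L %*% z)
      }
      mu <- mu * mod
    }
    if (nrow(de[[org]])) {
      ridx <- match(de[[org]]$gene_id, gene_ids[[org]])
      mu[ridx, mixed] <- mu[ridx, mixed] * 2^de[[org]]$log2fc
    }
    cm <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                 ngenes[[org]], ns,
                 dimnames = list(gene_ids[[org]], meta$sample_id))
    cm[, prop[, org] == 0] <- 0L  # absent symbiont: exact zeros
    counts[[org]] <- count_matrix(cm, org)
  }

  truth <- list(
    de = de,
    loadings = loadings,
    drivers = drivers,
    flip_symB = flip_symB,
    expected_props = data.frame(cult,
                                prop_symA = prop[match(cult$culture, meta$culture), "symA"],
                                prop_symB = prop[match(cult$culture, meta$culture), "symB"],
                                stringsAsFactors = FALSE),
    pathway_clusters = pathway_clusters,
    config = config)

  list(counts = counts, meta = meta, annotation = annotation, truth = truth)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Produces `counts_host.tsv`, `counts_symA.tsv`, `counts_symB.tsv`,
#' `samples.tsv`, `annotation.tsv` (if present) and a `ground_truth.json`
#' manifest. All TSVs round-trip losslessly through the package readers.
#'
#' @param dataset result of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return named character vector of file paths, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- c()
  for (org in names(dataset$counts)) {
    p <- file.path(dir, paste0("counts_", org, ".tsv"))
    write_counts(dataset$counts[[org]], p)
    paths[paste0("counts_", org)] <- p
  }
  paths["samples"] <- write_sample_table(dataset$meta,
                                         file.path(dir, "samples.tsv"))
  if (!is.null(dataset$annotation))
    paths["annotation"] <- write_annotation(dataset$annotation,
                                            file.path(dir, "annotation.tsv"))
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  truth$config$cultures <- as.list(truth$config$cultures)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  paths["ground_truth"] <- file.path(dir, "ground_truth.json")
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#' @param dir directory containing the TSV files
#' @return list with `counts`, `meta` and (if present) `annotation`
#' @export
read_dataset <- function(dir) {
  counts <- list()
  for (org in ORGANISMS) {
    p <- file.path(dir, paste0("counts_", org, ".tsv"))
    if (file.exists(p)) counts[[org]] <- read_counts(p, org)
  }
  ann_path <- file.path(dir, "annotation.tsv")
  list(counts = counts,
       meta = read_sample_table(file.path(dir, "samples.tsv")),
       annotation = if (file.exists(ann_path)) read_annotation(ann_path))
}
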