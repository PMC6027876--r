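#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates one end-to-end run on generated data: founder simulation,
#' genotype masking/QC/imputation, hybrid projection, field-trial
#' simulation, REML BLUPs with heritability and mid-parent heterosis, and
#' scheme-comparison cross-validation. Writes every table as CSV to
#' `config$outdir` together with a manifest recording the seed, a config
#' hash and package versions, so a rerun with the same config is
#' numerically identical.
#'
#' @param config a list; see [default_config()] for the documented fields
#'   and defaults (any subset can be overridden)
#' @return invisibly, a list with elements `marker_stats`, `filter_tally`,
#'   `variance_components`, `heritability`, `heterosis_medians`, `blups`,
#'   `cv` (per-fold), `cv_accuracy` (per repetition), `scheme_comparison`
#'   and `manifest`
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir))
    dir.create(cfg$outdir, recursive = TRUE)

  ## genotypes -------------------------------------------------------------
  pools <- stage("simulate", simulate_founders(
    cfg$n_b, cfg$n_r, cfg$n_markers, cfg$maf_low, cfg$maf_high,
    seed = cfg$seed))
  inbreds <- combine_pools(pools)
  masked <- stage("genotyping", mask_genotypes(inbreds, cfg$missing_rate,
                                               seed = cfg$seed + 1))
  filtered <- stage("genotyping", filter_markers(masked))
  filtered <- stage("genotyping", maf_filter(filtered, cfg$maf_threshold))
  stats_tab <- stage("genotyping", marker_stats(filtered))
  imputed <- stage("genotyping", impute_naive(filtered, seed = cfg$seed + 2))

  ## projection ------------------------------------------------------------
  plan <- stage("projection", make_cross_plan(
    pools$B$genotypes$entries$id, pools$R$genotypes$entries$id,
    n_hybrids = cfg$n_hybrids, seed = cfg$seed + 3))
  hybrids <- stage("projection", project_all(plan, imputed))

  ## phenotypes ------------------------------------------------------------
  all_geno <- gm_rbind(imputed, hybrids)
  entry_types <- stats::setNames(all_geno$entries$type, all_geno$entries$id)
  controls <- cfg$controls
  if (is.null(controls))  # default: one inbred check and one hybrid check
    controls <- c(imputed$entries$id[1], plan$hybrid_id[1])
  fits <- list(); books <- list(); archs <- list()
  for (ti in seq_along(cfg$traits)) {
    tr <- cfg$traits[[ti]]
    arch <- random_architecture(
      n_markers = ncol(imputed$geno), n_qtl = tr$n_qtl,
      additive_sd = tr$additive_sd, dominance_mean = tr$dominance_mean,
      dominance_sd = tr$dominance_sd, seed = cfg$seed + 10 + ti,
      target_h2 = tr$target_h2, loc_sd = tr$loc_sd, gxe_sd = tr$gxe_sd,
      rep_sd = tr$rep_sd, block_sd = tr$block_sd)
    tv <- simulate_trait(arch, all_geno)
    book <- stage("mixed_models", simulate_field_book(
      tv, arch, n_locations = cfg$n_locations, n_reps = cfg$n_reps,
      block_size = cfg$block_size, controls = controls,
      entry_types = entry_types, trait_name = tr$name,
      seed = cfg$seed + 20 + ti))
    fits[[tr$name]] <- stage("mixed_models",
                             fit_random_model(book, tr$name))
    books[[tr$name]] <- book
    archs[[tr$name]] <- arch
  }

  vc_tab <- do.call(rbind, lapply(names(fits), function(nm)
    data.frame(trait = nm, t(fits[[nm]]$vc), h2 = fits[[nm]]$h2)))
  het_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    mph <- midparent_heterosis(fits[[nm]], plan)
    data.frame(trait = nm, median_heterosis = attr(mph, "median"),
               n_hybrids = sum(!is.na(mph$heterosis)),
               n_flagged = attr(mph, "n_flagged"))
  }))

  ## genomic prediction ----------------------------------------------------
  cv <- NULL; acc <- NULL; cmp <- NULL
  if (isTRUE(cfg$run_cv)) {
    cv <- do.call(rbind, lapply(names(fits), function(nm) {
      bl <- fits[[nm]]$blups
      vals <- stats::setNames(bl$value, bl$entry_id)
      res <- stage("genomic_prediction", run_scheme(
        gm_subset(all_geno, entries = which(all_geno$entries$type != "hybrid")),
        gm_subset(all_geno, entries = which(all_geno$entries$type == "hybrid")),
        vals, vals, schemes = cfg$schemes, n_folds = cfg$n_folds,
        n_repetitions = cfg$n_repetitions, marker_counts = cfg$marker_counts,
        seed = cfg$seed + 30))
      res$trait <- nm
      res
    }))
    acc <- do.call(rbind, lapply(split(cv, cv$trait), function(d) {
      a <- cv_accuracy(d); a$trait <- d$trait[1]; a
    }))
    rownames(acc) <- NULL
    cmp <- compare_schemes(acc)
  }

  manifest <- data.frame(
    key = c("seed", "config_hash", "package", "r_version", "timestamp",
            "runtime_s"),
    value = c(cfg$seed, config_hash(cfg),
              paste0("milletgp ", as.character(utils::packageVersion("milletgp"))),
              paste(R.version$major, R.version$minor, sep = "."),
              format(t0, "%Y-%m-%d %H:%M:%S"),
              round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)))

  out <- list(marker_stats = stats_tab,
              filter_tally = attr(filtered, "exclusion_tally"),
              variance_components = vc_tab,
              heterosis_medians = het_tab,
              blups = lapply(fits, `[[`, "blups"),
              cv = cv, cv_accuracy = acc, scheme_comparison = cmp,
              manifest = manifest,
              fits = fits, plan = plan, genotypes = all_geno)
  if (!is.null(cfg$outdir)) {
    wr <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(cfg$outdir, f), row.names = FALSE)
    wr(stats_tab, "marker_stats.csv")
    wr(vc_tab, "variance_components.csv")
    wr(het_tab, "heterosis_medians.csv")
    wr(cv, "cv_folds.csv")
    wr(acc, "cv_accuracy.csv")
    wr(cmp, "scheme_comparison.csv")
    wr(manifest, "manifest.csv")
  }
  invisible(out)
}

#' Default pipeline configuration
#'
#' Returns the documented default config for [run_pipeline()]: a compact
#' synthetic study (60 B-lines x 60 R-lines, 800 markers, 233 tested
#' hybrids plus the 120 inbreds in a 4-location, 2-replicate alpha-lattice
#' with 15-plot blocks and 2 repeated checks) with one low-heterosis and
#' one high-heterosis trait.
#'
#' @param seed integer master seed
#' @param outdir output directory for CSV tables, or `NULL` to skip writing
#' @return a named list of settings
#' @export
default_config <- function(seed = 1, outdir = NULL) {
  list(
    seed = seed, outdir = outdir,
    n_b = 60, n_r = 60, n_markers = 800,
    maf_low = 0.05, maf_high = 0.5,
    missing_rate = 0.2, maf_threshold = 0.05,
    n_hybrids = 233,
    n_locations = 4, n_reps = 2, block_size = 15,
    controls = NULL,
    traits = list(
      list(name = "flowering", n_qtl = 40, additive_sd = 1,
           dominance_mean = 0, dominance_sd = 0.1, target_h2 = 0.88,
           loc_sd = 2, gxe_sd = 1, rep_sd = 0.5, block_sd = 0.5),
      list(name = "yield", n_qtl = 40, additive_sd = 1,
           dominance_mean = 1.2, dominance_sd = 0.3, target_h2 = 0.60,
           loc_sd = 2, gxe_sd = 1.5, rep_sd = 0.5, block_sd = 0.5)
    ),
    run_cv = TRUE,
    schemes = c("M1", "M2", "M3A", "M3B"),
    n_folds = 5, n_repetitions = 5, marker_counts = "all"
  )
}

config_hash <- function(cfg) {
  cfg$outdir <- NULL  # hash the analysis settings, not where they are written
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 12)), f)
  unname(tools::md5sum(f))
}

#' Paired comparison of prediction schemes
#'
#' For every trait/marker-count cell shared by two schemes, reports the mean
#' accuracies, their difference, and the p-value of a paired two-sided
#' t-test over repetitions. With a single repetition the p-value is `NA`.
#'
#' @param accuracy a per-repetition accuracy table from [cv_accuracy()]
#'   (optionally with a `trait` column)
#' @return data.frame: `trait`, `marker_count`, `scheme_a`, `scheme_b`,
#'   `mean_a`, `mean_b`, `difference` (b - a), `p_value`
#' @export
compare_schemes <- function(accuracy) {
  if (!"trait" %in% names(accuracy)) accuracy$trait <- "trait"
  cells <- unique(accuracy[, c("trait", "marker_count")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    d <- accuracy[accuracy$trait == cells$trait[i] &
                    accuracy$marker_count == cells$marker_count[i], ]
    scs <- sort(unique(d$scheme))
    if (length(scs) < 2) next
    for (a in seq_along(scs)) for (b in seq_along(scs)) {
      if (b <= a) next
      da <- d[d$scheme == scs[a], ]
      db <- d[d$scheme == scs[b], ]
      reps <- intersect(da$repetition, db$repetition)
      if (length(reps) < 1) next
      xa <- da$accuracy[match(reps, da$repetition)]
      xb <- db$accuracy[match(reps, db$repetition)]
      diffs <- xb - xa
      p <- if (length(reps) < 2) NA_real_
      else if (stats::sd(diffs) == 0) {
        # a constant difference across repetitions is either no effect at
        # all or an effect with zero sampling noise
        if (all(diffs == 0)) 1 else 0
      } else stats::t.test(xb, xa, paired = TRUE)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        trait = cells$trait[i], marker_count = cells$marker_count[i],
        scheme_a = scs[a], scheme_b = scs[b],
        mean_a = mean(xa), mean_b = mean(xb),
        difference = mean(diffs), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("need at least two schemes sharing repetitions")
  do.call(rbind, rows)
}
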