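#' Repeated fivefold cross-validation under four training schemes
#'
#' Evaluates genomic prediction of hybrid performance under the four
#' training schemes of a three-line hybrid program:
#' * **M1** (inbred-only): the inbreds are split into `n_folds` groups; each
#'   sub-prediction trains on the other groups' inbreds and predicts *all*
#'   hybrids.
#' * **M2** (hybrid-only): conventional fivefold cross-validation on the
#'   hybrids; train on 4/5, predict the held-out fifth.
#' * **M3A** (naive combined): as M2, with *all* inbreds (on the joint,
#'   uncentred value scale) appended to every training fold.
#' * **M3B** (population-centred combined): as M3A, but inbred and hybrid
#'   values are first centred on their own population means (see
#'   [center_by_population()]); held-out hybrids keep their (centred)
#'   values, which leaves the fold correlation unchanged.
#'
#' Each repetition draws a fresh fold split and, for every requested marker
#' count, a fresh marker subset (uniform, without replacement). Fold splits
#' and marker subsets are shared across schemes within a repetition, so
#' scheme contrasts are paired. Accuracy of one repetition is the mean over
#' folds of the correlation between predicted and observed values in the
#' test set.
#'
#' @param inbred_X,hybrid_X [geno_matrix()] objects (or plain matrices) on
#'   an identical marker set
#' @param inbred_values,hybrid_values named numeric values (typically
#'   mean-restored BLUPs) for each inbred / hybrid entry
#' @param schemes subset of `c("M1","M2","M3A","M3B")`
#' @param n_folds folds per repetition (default 5)
#' @param n_repetitions repetitions (default 20)
#' @param marker_counts integer marker-subset sizes and/or `"all"`
#'   (default `"all"`); subset sizes must not exceed the available markers
#' @param method correlation type, `"pearson"` (default) or `"spearman"`
#' @param seed integer seed; the same seed reproduces every fold split,
#'   marker draw and accuracy exactly
#' @return a `cv_result` data.frame, one row per
#'   (scheme, marker_count, repetition, fold) with the fold correlation `r`
#'   and test-set size `n_test`; summarise with [cv_accuracy()]
#' @export
run_scheme <- function(inbred_X, hybrid_X, inbred_values, hybrid_values,
                       schemes = c("M1", "M2", "M3A", "M3B"),
                       n_folds = 5, n_repetitions = 20,
                       marker_counts = "all",
                       method = c("pearson", "spearman"), seed = 1) {
  method <- match.arg(method)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (n_folds < 2) stop("n_folds must be >= 2")
  Xi <- if (inherits(inbred_X, "geno_matrix")) inbred_X$geno else as.matrix(inbred_X)
  Xh <- if (inherits(hybrid_X, "geno_matrix")) hybrid_X$geno else as.matrix(hybrid_X)
  if (!is.null(colnames(Xi)) && !identical(colnames(Xi), colnames(Xh)))
    stop("inbred and hybrid marker sets must be identical")
  if (ncol(Xi) != ncol(Xh)) stop("marker counts differ between populations")
  yi <- inbred_values[rownames(Xi)]
  yh <- hybrid_values[rownames(Xh)]
  if (anyNA(yi) || anyNA(yh))
    stop("every genotyped entry needs a value (names must match rownames)")
  if (any(c("M1", "M3A", "M3B") %in% schemes) && nrow(Xi) == 0)
    stop("schemes using inbred data need a non-empty inbred population")
  m <- ncol(Xh)
  mc <- marker_counts
  mc_num <- suppressWarnings(as.integer(mc[mc != "all"]))
  if (anyNA(mc_num) || any(mc_num > m) || any(mc_num < 1))
    stop("marker_counts must be 'all' or integers in [1, ", m, "]")

  # population-centred copies for M3B
  yi_c <- yi - mean(yi)
  yh_c <- yh - mean(yh)

  out <- vector("list", 0)
  set.seed(seed)
  for (rep_i in seq_len(n_repetitions)) {
    folds_h <- fold_assign(nrow(Xh), n_folds)
    folds_i <- fold_assign(nrow(Xi), n_folds)
    subsets <- lapply(mc, function(k) {
      if (identical(k, "all")) seq_len(m) else sample.int(m, as.integer(k))
    })
    names(subsets) <- as.character(mc)
    for (k_lab in names(subsets)) {
      cols <- subsets[[k_lab]]
      Xi_k <- Xi[, cols, drop = FALSE]
      Xh_k <- Xh[, cols, drop = FALSE]
      for (sc in schemes) {
        rs <- vapply(seq_len(n_folds), function(f) {
          if (sc == "M1") {
            tr <- folds_i != f
            if (sum(tr) < 2) return(NA_real_)
            mod <- rrblup_fit(Xi_k[tr, , drop = FALSE], yi[tr])
            fold_cor(predict(mod, Xh_k), yh, method)
          } else {
            te <- folds_h == f
            tr <- !te
            ytr <- if (sc == "M3B") yh_c[tr] else yh[tr]
            yte <- if (sc == "M3B") yh_c[te] else yh[te]
            Xtr <- Xh_k[tr, , drop = FALSE]
            if (sc %in% c("M3A", "M3B")) {
              Xtr <- rbind(Xtr, Xi_k)
              ytr <- c(ytr, if (sc == "M3B") yi_c else yi)
            }
            if (sum(te) < 2) return(NA_real_)
            mod <- rrblup_fit(Xtr, ytr)
            fold_cor(predict(mod, Xh_k[te, , drop = FALSE]), yte, method)
          }
        }, numeric(1))
        out[[length(out) + 1]] <- data.frame(
          scheme = sc, marker_count = k_lab, repetition = rep_i,
          fold = seq_len(n_folds), r = rs,
          n_test = if (sc == "M1") length(yh) else
            as.integer(table(factor(folds_h, levels = seq_len(n_folds)))),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_result", class(res))
  res
}

fold_assign <- function(n, n_folds) {
  # remainder entries are spread one per fold
  sample(rep(seq_len(n_folds), length.out = n))
}

fold_cor <- function(pred, obs, method) {
  if (length(obs) < 2 || stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    message("fold skipped: correlation undefined (", length(obs),
            " test entries)")
    return(NA_real_)
  }
  stats::cor(pred, obs, method = method)
}

#' Per-repetition prediction accuracy from a cv_result
#'
#' @param result a `cv_result` from [run_scheme()] or
#'   [holdout_parent_cv()]
#' @return data.frame, one row per (scheme, marker_count, repetition), with
#'   `accuracy` = mean fold correlation (folds with undefined correlation
#'   are dropped from the mean)
#' @export
cv_accuracy <- function(result) {
  agg <- stats::aggregate(r ~ scheme + marker_count + repetition,
                          data = result, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "r"] <- "accuracy"
  agg[order(agg$scheme, agg$marker_count, agg$repetition), ]
}

#' Hold-out-parent cross-validation
#'
#' Measures accuracy for hybrids whose parents never appear in training:
#' one B-line and one R-line are held out, every hybrid with either as a
#' parent is removed from the training pool, and per repetition the
#' remaining hybrids are split into `n_folds` groups; each sub-prediction
#' trains on all but one group and predicts the excluded-parent hybrids.
#'
#' @param hybrid_X [geno_matrix()] (or matrix) of hybrid genotypes
#' @param hybrid_values named values for the hybrids
#' @param plan cross plan mapping hybrids to parents
#' @param b_line,r_line ids of the held-out female and male parents
#' @param n_folds,n_repetitions,marker_counts,method,seed as in
#'   [run_scheme()]
#' @return a `cv_result` data.frame (scheme label `holdout`)
#' @export
holdout_parent_cv <- function(hybrid_X, hybrid_values, plan, b_line, r_line,
                              n_folds = 5, n_repetitions = 20,
                              marker_counts = "all",
                              method = c("pearson", "spearman"), seed = 1) {
  method <- match.arg(method)
  Xh <- if (inherits(hybrid_X, "geno_matrix")) hybrid_X$geno else as.matrix(hybrid_X)
  plan <- plan[plan$hybrid_id %in% rownames(Xh), , drop = FALSE]
  if (!b_line %in% plan$female_id)
    stop("held-out B-line '", b_line, "' has no hybrids in the plan")
  if (!r_line %in% plan$male_id)
    stop("held-out R-line '", r_line, "' has no hybrids in the plan")
  excl_ids <- plan$hybrid_id[plan$female_id == b_line |
                               plan$male_id == r_line]
  pool_ids <- setdiff(rownames(Xh), excl_ids)
  if (length(pool_ids) < n_folds)
    stop("training pool is empty (or smaller than the fold count) after ",
         "removing hybrids of the held-out parents")
  yh <- hybrid_values[rownames(Xh)]
  if (anyNA(yh)) stop("every hybrid needs a value")
  m <- ncol(Xh)
  mc <- marker_counts
  out <- vector("list", 0)
  set.seed(seed)
  for (rep_i in seq_len(n_repetitions)) {
    folds <- fold_assign(length(pool_ids), n_folds)
    subsets <- lapply(mc, function(k) {
      if (identical(k, "all")) seq_len(m) else sample.int(m, as.integer(k))
    })
    names(subsets) <- as.character(mc)
    for (k_lab in names(subsets)) {
      cols <- subsets[[k_lab]]
      rs <- vapply(seq_len(n_folds), function(f) {
        tr_ids <- pool_ids[folds != f]
        mod <- rrblup_fit(Xh[tr_ids, cols, drop = FALSE], yh[tr_ids])
        fold_cor(predict(mod, Xh[excl_ids, cols, drop = FALSE]),
                 yh[excl_ids], method)
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        scheme = "holdout", marker_count = k_lab, repetition = rep_i,
        fold = seq_len(n_folds), r = rs, n_test = length(excl_ids),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "held_out") <- c(b_line = b_line, r_line = r_line)
  attr(res, "n_excluded") <- length(excl_ids)
  class(res) <- c("cv_result", class(res))
  res
}

#' Genomic estimated breeding values for every cross in a plan
#'
#' Projects the genotype of each hybrid in the plan from its parents and
#' applies one fitted RR-BLUP model per trait.
#'
#' @param models a named list of `rrblup_model` objects, one per trait
#' @param plan cross plan (`hybrid_id`, `female_id`, `male_id`), typically
#'   the full B x R factorial
#' @param parents [geno_matrix()] of the parental inbreds on the model
#'   marker set
#' @return data.frame `hybrid_id`, `female_id`, `male_id` plus one GEBV
#'   column per trait
#' @export
predict_all_hybrids <- function(models, plan, parents) {
  if (inherits(models, "rrblup_model")) models <- list(trait = models)
  hyb <- project_all(plan, parents)
  out <- plan[, c("hybrid_id", "female_id", "male_id")]
  for (tr in names(models))
    out[[tr]] <- unname(predict(models[[tr]], hyb))
  out
}

#' Non-dominated trade-off frontier between two traits
#'
#' Returns the hybrids for which no other hybrid is at least as good on
#' both axes (higher-or-equal `maximize_trait`, lower-or-equal
#' `minimize_trait`) and strictly better on one. Exact ties on both axes
#' are all kept. This is the production-possibility frontier for, e.g.,
#' yield against growing-season length.
#'
#' @param gebv data.frame of per-hybrid predictions
#' @param maximize_trait,minimize_trait column names of the two axes
#' @return the frontier rows of `gebv`, sorted by `minimize_trait`
#' @export
pareto_frontier <- function(gebv, maximize_trait, minimize_trait) {
  if (!all(c(maximize_trait, minimize_trait) %in% names(gebv)))
    stop("both trait columns must be present in the GEBV table")
  up <- gebv[[maximize_trait]]
  dn <- gebv[[minimize_trait]]
  ord <- order(dn, -up)
  best <- -Inf
  keep_pair <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    if (up[i] > best) {
      best <- up[i]
      keep_pair <- rbind(keep_pair, c(dn[i], up[i]))
    }
  }
  on_front <- rep(FALSE, nrow(gebv))
  for (r in seq_len(nrow(keep_pair)))
    on_front <- on_front | (dn == keep_pair[r, 1] & up == keep_pair[r, 2])
  res <- gebv[on_front, , drop = FALSE]
  res[order(res[[minimize_trait]]), , drop = FALSE]
}
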