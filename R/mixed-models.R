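#' Fit the all-random field-trial model for one trait
#'
#' Fits, by REML (`lme4`), the linear mixed model in which genotype (G),
#' location (L), genotype-by-location (GxL), replicate (R) and block (B) are
#' all random and only the intercept is fixed:
#' `y = mu + G + L + GxL + R + B + e`.
#' With `nesting = "nested"` (default) replicates are coded within location
#' and blocks within replicate, matching the physical layout of a
#' multi-location alpha-lattice trial; `"flat"` uses the factor labels as
#' given.
#'
#' @param book field book data.frame with columns `location`, `replicate`,
#'   `block`, `entry_id`, `entry_type` and the trait column; rows with a
#'   missing trait value are dropped
#' @param trait name of the trait column
#' @param nesting `"nested"` or `"flat"` coding of replicate/block factors
#' @return an object of class `trait_fit`: list with
#'   * `vc`: named vector of variance components
#'     (`v_g`, `v_l`, `v_gxl`, `v_rep`, `v_block`, `v_resid`);
#'   * `blups`: data.frame `entry_id`, `population` (`inbred`/`hybrid`),
#'     `blup` (genotype BLUP, centred), `value` (grand mean + BLUP);
#'   * `grand_mean`, `trait`, `n_locations`, `n_reps`, `h2`
#'     (broad-sense heritability via [heritability()]).
#' @export
fit_random_model <- function(book, trait, nesting = c("nested", "flat")) {
  nesting <- match.arg(nesting)
  need <- c("location", "replicate", "block", "entry_id")
  if (!all(need %in% names(book)))
    stop("field book needs columns: ", paste(need, collapse = ", "))
  if (!trait %in% names(book)) stop("no column named '", trait, "'")
  df <- book[!is.na(book[[trait]]), , drop = FALSE]
  df$y <- df[[trait]]
  df$entry_id <- factor(df$entry_id)
  df$location <- factor(df$location)
  n_loc <- nlevels(df$location)
  if (n_loc < 2)
    stop("model is degenerate with ", n_loc, " location(s): the ",
         "genotype-by-location term cannot be separated from genotype; ",
         "need >= 2 locations")
  if (nesting == "nested") {
    df$rep_f <- factor(paste(df$location, df$replicate, sep = ":"))
    df$block_f <- factor(paste(df$location, df$replicate, df$block, sep = ":"))
  } else {
    df$rep_f <- factor(df$replicate)
    df$block_f <- factor(df$block)
  }
  n_reps <- max(table(unique(df[, c("location", "rep_f")])$location))
  if (max(table(df$entry_id)) < 2)
    stop("model is degenerate: no entry is replicated")
  # drop terms aliased with a coarser design factor (e.g. one block per
  # replicate, or one replicate per location): their variance is not
  # identifiable and would destabilise the fit
  aliased <- function(coarse, fine)
    nlevels(fine) == nlevels(coarse) &&
      nlevels(factor(paste(coarse, fine))) == nlevels(coarse)
  drop_rep <- aliased(df$location, df$rep_f)
  drop_block <- aliased(df$rep_f, df$block_f)
  terms <- c("(1 | entry_id)", "(1 | location)", "(1 | entry_id:location)",
             if (!drop_rep) "(1 | rep_f)", if (!drop_block) "(1 | block_f)")
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(
    fml, data = df, REML = TRUE,
    control = lme4::lmerControl(
      optimizer = "bobyqa",
      check.conv.singular = "ignore", calc.derivs = FALSE,
      optCtrl = list(rhoend = 1e-13)))
  vc_df <- as.data.frame(lme4::VarCorr(fit))
  grab <- function(term) {
    v <- vc_df$vcov[vc_df$grp == term]
    if (length(v) == 0) 0 else max(v, 0)
  }
  vc <- c(v_g = grab("entry_id"), v_l = grab("location"),
          v_gxl = grab("entry_id:location"), v_rep = grab("rep_f"),
          v_block = grab("block_f"), v_resid = grab("Residual"))
  mu <- as.numeric(lme4::fixef(fit)[1])
  re <- lme4::ranef(fit)$entry_id
  blup <- stats::setNames(re[, 1], rownames(re))
  pop_of <- if ("entry_type" %in% names(df)) {
    tp <- tapply(as.character(df$entry_type), df$entry_id, `[`, 1)
    ifelse(tp[names(blup)] == "hybrid", "hybrid", "inbred")
  } else rep("inbred", length(blup))
  blups <- data.frame(entry_id = names(blup),
                      population = unname(pop_of),
                      blup = unname(blup),
                      value = mu + unname(blup),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(vc = vc, blups = blups, grand_mean = mu, trait = trait,
                 n_locations = n_loc, n_reps = n_reps,
                 h2 = heritability(vc, n_locations = n_loc, n_reps = n_reps)),
            class = "trait_fit")
}

#' @method print trait_fit
#' @export
print.trait_fit <- function(x, ...) {
  cat("trait_fit for '", x$trait, "': ", nrow(x$blups), " entries, ",
      x$n_locations, " locations x ", x$n_reps, " reps\n", sep = "")
  print(round(x$vc, 4))
  cat("broad-sense H2 =", format(x$h2, digits = 3), "\n")
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = VG / (VG + VGxL / NL + Ve / (NR * NL))` where `NL` is the number of
#' locations and `NR` the number of replicates per location. Location,
#' replicate and block variances do not enter: they cancel from entry means
#' in a balanced trial.
#'
#' @param vc named variance components (needs `v_g`, `v_gxl`, `v_resid`), or
#'   a `trait_fit`
#' @param n_locations,n_reps trial dimensions NL and NR
#' @return heritability in \[0, 1\], or `NA` when all three entering
#'   components are zero
#' @export
heritability <- function(vc, n_locations, n_reps) {
  if (inherits(vc, "trait_fit")) vc <- vc$vc
  stopifnot(n_locations >= 1, n_reps >= 1)
  vg <- vc[["v_g"]]; vgxl <- vc[["v_gxl"]]; ve <- vc[["v_resid"]]
  if (any(c(vg, vgxl, ve) < 0)) stop("variance components must be nonnegative")
  denom <- vg + vgxl / n_locations + ve / (n_reps * n_locations)
  if (denom == 0) return(NA_real_)
  vg / denom
}

#' Mid-parent heterosis per hybrid
#'
#' For each hybrid, `(Y_hybrid - MP) / MP` with
#' `MP = (Y_female + Y_male) / 2`. By default Y values are the mean-restored
#' predictions (`value` column, grand mean + BLUP), since a ratio of
#' zero-centred BLUPs is ill-defined; `scale = "blup"` uses the raw BLUPs
#' instead. Hybrids whose mid-parent value is not strictly positive are
#' flagged and excluded from the median.
#'
#' @param blups a `trait_fit` or its `blups` data.frame (columns `entry_id`,
#'   `blup`, `value`)
#' @param plan cross plan (`hybrid_id`, `female_id`, `male_id`); only
#'   hybrids whose own value and both parent values are present are scored
#' @param scale `"restored"` (default) or `"blup"`
#' @return data.frame `hybrid_id`, `female_id`, `male_id`, `hybrid`,
#'   `midparent`, `heterosis` (NA when flagged); attributes `median`
#'   (over unflagged hybrids) and `n_flagged`
#' @export
midparent_heterosis <- function(blups, plan, scale = c("restored", "blup")) {
  scale <- match.arg(scale)
  if (inherits(blups, "trait_fit")) blups <- blups$blups
  val <- stats::setNames(
    if (scale == "restored") blups$value else blups$blup, blups$entry_id)
  keep <- plan$hybrid_id %in% names(val) &
    plan$female_id %in% names(val) & plan$male_id %in% names(val)
  if (!any(keep))
    stop("no hybrid in the plan has values for itself and both parents")
  plan <- plan[keep, , drop = FALSE]
  hy <- val[plan$hybrid_id]
  mp <- (val[plan$female_id] + val[plan$male_id]) / 2
  flagged <- mp <= 0
  het <- ifelse(flagged, NA_real_, (hy - mp) / mp)
  out <- data.frame(hybrid_id = plan$hybrid_id, female_id = plan$female_id,
                    male_id = plan$male_id, hybrid = unname(hy),
                    midparent = unname(mp), heterosis = unname(het),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "median") <- stats::median(het, na.rm = TRUE)
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' Centre trait values within each population
#'
#' Re-expresses every entry's BLUP and mean-restored value as the deviation
#' from its own population's mean (inbreds from the inbred mean, hybrids
#' from the hybrid mean). This is the normalisation that lets inbred and
#' hybrid records be pooled in one training set without the population-mean
#' gap created by heterosis leaking into marker effects.
#'
#' @param blups a `trait_fit` or its `blups` data.frame (columns `entry_id`,
#'   `population`, `blup`, `value`); both populations must be present
#' @return the data.frame with `blup` and `value` centred per population;
#'   attribute `pop_means` stores the subtracted means of `value`
#' @export
center_by_population <- function(blups) {
  if (inherits(blups, "trait_fit")) blups <- blups$blups
  pops <- unique(blups$population)
  if (!all(c("inbred", "hybrid") %in% pops))
    stop("both an inbred and a hybrid population are required; found: ",
         paste(pops, collapse = ", "))
  mv <- tapply(blups$value, blups$population, mean)
  mb <- tapply(blups$blup, blups$population, mean)
  blups$value <- blups$value - as.vector(mv[blups$population])
  blups$blup <- blups$blup - as.vector(mb[blups$population])
  attr(blups, "pop_means") <- mv
  blups
}
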