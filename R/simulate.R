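#' Simulate two fully inbred founder pools
#'
#' Generates B-line (seed parent / maintainer) and R-line (restorer) pools of
#' fully homozygous lines. For each marker each pool draws its own alternate
#' allele frequency uniformly in `[maf_low, maf_high]`, and each line then
#' draws a homozygous genotype (dosage 0 or 2) at that frequency. Independent
#' frequency draws per pool give the allele-frequency divergence between
#' seed-parent and restorer heterotic groups that a three-line breeding
#' program accumulates.
#'
#' @param n_b,n_r number of B- and R-lines
#' @param n_markers number of biallelic markers
#' @param maf_low,maf_high bounds of the per-pool alternate-allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`
#' @param seed integer RNG seed; the same seed reproduces the pools
#'   bit-for-bit
#' @return a list with elements `B` and `R`, each a `founder_pool`:
#'   a list of `pool_label`, `n_lines`, a [geno_matrix()] in `genotypes`
#'   (dosages all 0 or 2), and `allele_freqs` (the sampled per-marker
#'   alternate-allele frequency of the pool)
#' @export
simulate_founders <- function(n_b, n_r, n_markers,
                              maf_low = 0.05, maf_high = 0.5, seed = 1) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (n_b < 1 || n_r < 1 || n_markers < 1)
    stop("counts must be positive")
  set.seed(seed)
  markers <- data.frame(
    id = sprintf("m%04d", seq_len(n_markers)), chrom = "chr1",
    pos = seq_len(n_markers), ref = "A", alt = "B",
    stringsAsFactors = FALSE
  )
  one_pool <- function(label, n_lines) {
    p <- stats::runif(n_markers, maf_low, maf_high)
    g <- matrix(2 * stats::rbinom(n_lines * n_markers, 1,
                                  rep(p, each = n_lines)),
                nrow = n_lines, ncol = n_markers)
    rownames(g) <- sprintf("%s%03d", label, seq_len(n_lines))
    colnames(g) <- markers$id
    gm <- geno_matrix(g, markers = markers,
                      entries = data.frame(
                        id = rownames(g),
                        type = paste0("inbred_", label),
                        stringsAsFactors = FALSE))
    structure(list(pool_label = label, n_lines = n_lines,
                   genotypes = gm, allele_freqs = p),
              class = "founder_pool")
  }
  list(B = one_pool("B", n_b), R = one_pool("R", n_r))
}

#' @method print founder_pool
#' @export
print.founder_pool <- function(x, ...) {
  cat("founder_pool ", x$pool_label, ": ", x$n_lines, " inbred lines x ",
      length(x$allele_freqs), " markers\n", sep = "")
  invisible(x)
}

#' Combine founder pools into one inbred genotype matrix
#'
#' @param pools a list with `B` and `R` founder pools from
#'   [simulate_founders()]
#' @return a [geno_matrix()] of all inbred lines
#' @export
combine_pools <- function(pools) {
  gm_rbind(pools$B$genotypes, pools$R$genotypes)
}

#' Build a B x R cross plan
#'
#' @param female_ids B-line ids (seed parents)
#' @param male_ids R-line ids (pollinators)
#' @param n_hybrids optional number of distinct crosses to sample from the
#'   full factorial; `NULL` returns every combination
#' @param seed RNG seed used when sampling
#' @return a data.frame with columns `hybrid_id`, `female_id`, `male_id`
#' @export
make_cross_plan <- function(female_ids, male_ids, n_hybrids = NULL, seed = 1) {
  plan <- expand.grid(female_id = female_ids, male_id = male_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(n_hybrids)) {
    if (n_hybrids > nrow(plan))
      stop("n_hybrids exceeds the ", nrow(plan), " possible crosses")
    set.seed(seed)
    plan <- plan[sample.int(nrow(plan), n_hybrids), , drop = FALSE]
  }
  plan <- data.frame(hybrid_id = paste0("H_", plan$female_id, "_",
                                        plan$male_id),
                     plan, row.names = NULL, stringsAsFactors = FALSE)
  plan
}

#' Define an additive + dominance trait architecture
#'
#' Each QTL `j` contributes `a_j * (dosage - 1) + d_j * [dosage == 1]` to the
#' genotypic value. Because fully inbred lines carry no heterozygous calls,
#' the dominance effects `d_j` act only in hybrids; positive `d` therefore
#' generates positive mid-parent heterosis. Noise standard deviations are the
#' field-trial variance components used by [simulate_field_book()].
#'
#' @param qtl_indices distinct marker column indices of the causal loci
#' @param additive_effects,dominance_effects numeric, one per QTL
#' @param target_h2 optional broad-sense heritability target in (0, 1]; when
#'   set and `resid_sd` is `NA`, the residual SD is derived from the realised
#'   genetic variance so the trial's expected heritability equals the target
#' @param loc_sd,gxe_sd,rep_sd,block_sd,resid_sd standard deviations of the
#'   location, genotype-by-location, replicate, block and plot-residual
#'   effects (trait units)
#' @return a `trait_architecture` object
#' @export
trait_architecture <- function(qtl_indices, additive_effects,
                               dominance_effects = 0,
                               target_h2 = NA_real_,
                               loc_sd = 0, gxe_sd = 0, rep_sd = 0,
                               block_sd = 0, resid_sd = NA_real_) {
  n_qtl <- length(qtl_indices)
  additive_effects <- rep_len(additive_effects, n_qtl)
  dominance_effects <- rep_len(dominance_effects, n_qtl)
  if (anyDuplicated(qtl_indices)) stop("qtl_indices must be distinct")
  if (any(qtl_indices < 1)) stop("qtl_indices must be positive")
  sds <- c(loc_sd, gxe_sd, rep_sd, block_sd, resid_sd)
  if (any(sds < 0, na.rm = TRUE)) stop("variance parameters must be nonnegative")
  if (!is.na(target_h2) && (target_h2 <= 0 || target_h2 > 1))
    stop("target_h2 must lie in (0, 1]")
  structure(list(n_qtl = n_qtl, qtl_indices = qtl_indices,
                 additive_effects = additive_effects,
                 dominance_effects = dominance_effects,
                 target_h2 = target_h2, loc_sd = loc_sd, gxe_sd = gxe_sd,
                 rep_sd = rep_sd, block_sd = block_sd, resid_sd = resid_sd),
            class = "trait_architecture")
}

#' Draw a random trait architecture
#'
#' Convenience wrapper that samples QTL positions and effect sizes.
#' Additive effects are N(0, `additive_sd`); dominance effects are
#' N(`dominance_mean`, `dominance_sd`), so `dominance_mean > 0` yields a trait
#' with directional (positive) heterosis.
#'
#' @param n_markers total markers available
#' @param n_qtl number of causal loci
#' @param additive_sd SD of additive effects
#' @param dominance_mean,dominance_sd mean and SD of dominance effects
#' @param seed RNG seed
#' @param ... further arguments passed to [trait_architecture()]
#' @return a `trait_architecture`
#' @export
random_architecture <- function(n_markers, n_qtl, additive_sd = 1,
                                dominance_mean = 0, dominance_sd = 0,
                                seed = 1, ...) {
  set.seed(seed)
  trait_architecture(
    qtl_indices = sort(sample.int(n_markers, n_qtl)),
    additive_effects = stats::rnorm(n_qtl, 0, additive_sd),
    dominance_effects = stats::rnorm(n_qtl, dominance_mean, dominance_sd),
    ...
  )
}

#' True genotypic value of each entry under a trait architecture
#'
#' Deterministic given genotypes and architecture: the value is
#' `sum_j a_j (x_j - 1) + d_j [x_j == 1]` over QTL `j`. Dosage-1 calls are
#' the only ones receiving dominance, so genotyped inbreds (dosage 0/2) get a
#' purely additive value.
#'
#' @param architecture a [trait_architecture()]
#' @param genotypes a [geno_matrix()] with no missing calls at the QTL
#' @return named numeric vector of genotypic values, one per entry
#' @export
simulate_trait <- function(architecture, genotypes) {
  stopifnot(inherits(architecture, "trait_architecture"),
            inherits(genotypes, "geno_matrix"))
  if (max(architecture$qtl_indices) > ncol(genotypes$geno))
    stop("qtl_indices outside marker range")
  X <- genotypes$geno[, architecture$qtl_indices, drop = FALSE]
  if (anyNA(X))
    stop("missing genotype calls at QTL; impute or filter first")
  add <- (X - 1) %*% architecture$additive_effects
  dom <- (X == 1) %*% architecture$dominance_effects
  stats::setNames(as.numeric(add + dom), rownames(X))
}

#' Simulate an alpha-lattice multi-location field book
#'
#' Lays entries out as `n_locations` locations x `n_reps` replicates x
#' incomplete blocks of `block_size` plots. Every block carries every control
#' entry (repeated checks), and each non-control entry appears exactly once
#' per replicate per location, assigned to blocks at random. The plot value
#' is the entry's true genotypic value plus independent location, G-by-L,
#' replicate, block and residual effects, each drawn as
#' N(0, sd) with the architecture's standard deviations. Replicates and
#' blocks are nested within location by default (`rep` labels are unique per
#' location, `block` labels unique per replicate).
#'
#' When the architecture sets `target_h2` and leaves `resid_sd = NA`, the
#' residual SD is derived from the sample variance of `true_values` so that
#' entry-mean broad-sense heritability
#' `Vg / (Vg + Vgxl/NL + Ve/(NR*NL))` equals the target.
#'
#' @param true_values named numeric vector of genotypic values (names are
#'   entry ids)
#' @param architecture a [trait_architecture()] supplying the noise SDs
#' @param n_locations,n_reps,block_size trial dimensions
#' @param controls character vector of entry ids used as repeated checks in
#'   every block (they must be part of `true_values`)
#' @param entry_types optional named character vector of entry types copied
#'   into the field book (`"hybrid"`/`"inbred_B"`/...); defaults to
#'   `"unknown"`
#' @param segregate_populations if `TRUE`, hybrid entries are assigned to the
#'   leading blocks and inbred entries to the trailing blocks of each
#'   replicate, mimicking trials that separate the two populations to limit
#'   competition effects; default `FALSE` (fully random assignment)
#' @param trait_name column name for the simulated trait
#' @param seed RNG seed
#' @return a data.frame field book with columns `location`, `replicate`,
#'   `block`, `plot`, `entry_id`, `entry_type` and one trait column; the
#'   derived residual SD (if any) is attached as attribute `resid_sd`
#' @export
simulate_field_book <- function(true_values, architecture,
                                n_locations = 4, n_reps = 2, block_size = 15,
                                controls = character(),
                                entry_types = NULL,
                                segregate_populations = FALSE,
                                trait_name = "trait", seed = 1) {
  stopifnot(inherits(architecture, "trait_architecture"))
  entries <- names(true_values)
  if (is.null(entries)) stop("true_values must be named by entry id")
  if (!all(controls %in% entries)) stop("controls must appear in true_values")
  n_ctl <- length(controls)
  if (n_ctl > 0 && block_size < n_ctl + 1)
    stop("block_size too small to hold the controls plus an experimental plot")
  exper <- setdiff(entries, controls)
  per_block <- block_size - n_ctl
  if (length(exper) %% per_block != 0)
    stop("cannot lay out ", length(exper), " experimental entries in blocks of ",
         per_block, " experimental plots (", block_size, " minus ", n_ctl,
         " controls); entry count must be a multiple of ", per_block)
  n_blocks <- length(exper) / per_block

  resid_sd <- architecture$resid_sd
  if (is.na(resid_sd)) {
    if (is.na(architecture$target_h2))
      stop("resid_sd is NA and no target_h2 given")
    vg <- stats::var(true_values)
    h2 <- architecture$target_h2
    ve <- (vg * (1 - h2) / h2 - architecture$gxe_sd^2 / n_locations) *
      n_reps * n_locations
    if (ve < 0)
      stop("target_h2 unreachable: G-by-L variance alone exceeds the budget")
    resid_sd <- sqrt(ve)
  }

  set.seed(seed)
  loc_ids <- paste0("loc", seq_len(n_locations))
  loc_eff <- stats::setNames(stats::rnorm(n_locations, 0, architecture$loc_sd),
                             loc_ids)
  gxe <- matrix(stats::rnorm(length(entries) * n_locations, 0,
                             architecture$gxe_sd),
                nrow = length(entries), dimnames = list(entries, loc_ids))

  type_of <- function(id) {
    if (is.null(entry_types)) return(rep("unknown", length(id)))
    out <- unname(entry_types[id])
    out[is.na(out)] <- "unknown"
    out
  }

  rows <- vector("list", n_locations * n_reps)
  k <- 0L
  for (loc in loc_ids) {
    for (r in seq_len(n_reps)) {
      rep_eff <- stats::rnorm(1, 0, architecture$rep_sd)
      if (segregate_populations && !is.null(entry_types)) {
        is_hyb <- entry_types[exper] == "hybrid"
        ord <- c(sample(exper[which(is_hyb)]), sample(exper[which(!is_hyb)]))
      } else {
        ord <- sample(exper)
      }
      blk_of <- rep(seq_len(n_blocks), each = per_block)
      df <- data.frame(entry_id = ord, block = blk_of,
                       stringsAsFactors = FALSE)
      if (n_ctl > 0)
        df <- rbind(df, data.frame(
          entry_id = rep(controls, n_blocks),
          block = rep(seq_len(n_blocks), each = n_ctl)))
      blk_eff <- stats::rnorm(n_blocks, 0, architecture$block_sd)
      val <- true_values[df$entry_id] + loc_eff[loc] +
        gxe[df$entry_id, loc] + rep_eff + blk_eff[df$block] +
        stats::rnorm(nrow(df), 0, resid_sd)
      k <- k + 1L
      rows[[k]] <- data.frame(
        location = loc,
        replicate = paste0(loc, "_rep", r),
        block = paste0(loc, "_rep", r, "_blk", sprintf("%02d", df$block)),
        entry_id = df$entry_id,
        entry_type = type_of(df$entry_id),
        value = as.numeric(val),
        stringsAsFactors = FALSE
      )
    }
  }
  book <- do.call(rbind, rows)
  book <- book[order(book$location, book$replicate, book$block), ]
  book$plot <- seq_len(nrow(book))
  book <- book[, c("location", "replicate", "block", "plot",
                   "entry_id", "entry_type", "value")]
  names(book)[names(book) == "value"] <- trait_name
  rownames(book) <- NULL
  attr(book, "resid_sd") <- resid_sd
  book
}

#' Write / read a field book as CSV
#'
#' @param book field book data.frame
#' @param path file path
#' @param seed optional integer recorded in a header comment
#' @export
write_field_book <- function(book, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(book, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_book
#' @export
read_field_book <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a cross plan as CSV
#'
#' @param plan cross-plan data.frame (`hybrid_id`, `female_id`, `male_id`)
#' @param path file path
#' @param seed optional integer recorded in a header comment
#' @export
write_cross_plan <- function(plan, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(plan, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cross_plan
#' @export
read_cross_plan <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
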