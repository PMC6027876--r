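#' Call a genotype from per-allele read counts
#'
#' Implements depth/frequency genotype calling for reduced-representation
#' sequencing. With total depth `n` and allele frequencies computed within
#' the sample:
#' * homozygous call for the top allele when `n >= min_depth` and its
#'   frequency is strictly greater than 0.9;
#' * heterozygous call for the two most frequent alleles when
#'   `n >= min_depth`, the two jointly account for at least 90% of the
#'   reads, each is supported by at least two reads, and each has a
#'   frequency strictly greater than 0.2;
#' * otherwise missing. Missing is a value, not an error.
#'
#' @param counts named nonnegative integer vector of reads per allele
#'   (e.g. `c(A = 6, G = 4)`); order is irrelevant
#' @param min_depth minimum read depth to attempt a call (default 5)
#' @return character vector of the two called alleles (duplicated for a
#'   homozygote, sorted for a heterozygote), or `NA_character_` of length 1
#'   when the site is missing
#' @export
call_genotype <- function(counts, min_depth = 5) {
  if (any(counts < 0)) stop("read counts must be nonnegative")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < min_depth) return(NA_character_)
  ord <- order(counts, decreasing = TRUE)
  counts <- counts[ord]
  freq <- counts / n
  if (freq[1] > 0.9)
    return(rep(names(counts)[1], 2))
  if (length(counts) >= 2) {
    top2 <- counts[1:2]
    if (sum(top2) / n >= 0.9 && all(top2 >= 2) && all(top2 / n > 0.2))
      return(sort(names(top2)))
  }
  NA_character_
}

#' Call a genotype matrix from a long-format allele-depth table
#'
#' Applies [call_genotype()] to every (sample, site) cell of a long table of
#' read counts. Per site, the reference and alternate alleles are taken as
#' the two alleles with the highest total depth across samples (ties broken
#' alphabetically); calls involving any other allele are recorded as missing
#' dosage, but the number of distinct alleles seen in genotype calls is kept
#' in the marker metadata (`n_alleles`) so multi-allelic sites can be
#' filtered downstream.
#'
#' @param ad data.frame with columns `sample`, `chrom`, `pos`, `allele`,
#'   `count`
#' @param min_depth minimum depth for a call (default 5)
#' @param entry_types optional named vector of entry types
#' @return a [geno_matrix()]; dosage counts copies of the alternate allele
#' @export
call_genotypes <- function(ad, min_depth = 5, entry_types = NULL) {
  need <- c("sample", "chrom", "pos", "allele", "count")
  if (!all(need %in% names(ad)))
    stop("allele-depth table needs columns: ", paste(need, collapse = ", "))
  if (any(ad$count < 0)) stop("read counts must be nonnegative")
  ad$site <- paste0(ad$chrom, ":", ad$pos)
  sites <- unique(ad[, c("site", "chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  samples <- sort(unique(ad$sample))
  g <- matrix(NA_real_, nrow = length(samples), ncol = nrow(sites),
              dimnames = list(samples, sites$site))
  ref <- alt <- character(nrow(sites))
  n_alleles <- integer(nrow(sites))
  by_site <- split(ad, ad$site)
  for (j in seq_len(nrow(sites))) {
    sdf <- by_site[[sites$site[j]]]
    tot <- tapply(sdf$count, sdf$allele, sum)
    tot <- tot[order(-tot, names(tot))]
    ref[j] <- names(tot)[1]
    alt[j] <- if (length(tot) >= 2) names(tot)[2] else "."
    calls <- lapply(split(sdf, sdf$sample), function(x)
      call_genotype(stats::setNames(x$count, x$allele), min_depth = min_depth))
    called <- calls[!vapply(calls, function(z) anyNA(z), TRUE)]
    n_alleles[j] <- length(unique(unlist(called)))
    for (s in names(called)) {
      al <- called[[s]]
      if (all(al %in% c(ref[j], alt[j])))
        g[s, j] <- sum(al == alt[j])
    }
  }
  markers <- data.frame(id = sites$site, chrom = sites$chrom, pos = sites$pos,
                        ref = ref, alt = alt, n_alleles = n_alleles,
                        stringsAsFactors = FALSE)
  type <- rep("inbred_B", length(samples))
  if (!is.null(entry_types)) {
    hit <- samples %in% names(entry_types)
    type[hit] <- unname(entry_types[samples[hit]])
  }
  geno_matrix(g, markers = markers,
              entries = data.frame(id = samples, type = type,
                                   stringsAsFactors = FALSE))
}

#' Per-marker quality statistics
#'
#' For each marker, over integer genotype calls:
#' * `missing_rate` = samples with missing data / total samples;
#' * `het_rate` = heterozygous calls / (homozygous + heterozygous calls);
#' * `maf` = (2 x homozygous-minor calls + heterozygous calls) /
#'   (2 x samples with a call), the minor allele being whichever of the two
#'   alleles is rarer among the calls at that marker.
#'
#' @param x a [geno_matrix()] with integer dosages (genotyped material, not
#'   projected hybrids)
#' @return data.frame with one row per marker: `id`, `n_called`,
#'   `missing_rate`, `het_rate`, `maf`, `n_classes` (distinct genotype
#'   classes observed) and `minor_n_samples` (samples carrying the minor
#'   allele); all-missing markers get `NA` statistics
#' @export
marker_stats <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- x$geno
  if (any(!is.na(g) & g != round(g)))
    stop("marker_stats expects integer dosage calls")
  n <- nrow(g)
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  n_called <- n0 + n1 + n2
  missing_rate <- (n - n_called) / n
  het_rate <- ifelse(n_called > 0, n1 / n_called, NA_real_)
  alt_freq <- ifelse(n_called > 0, (2 * n2 + n1) / (2 * n_called), NA_real_)
  # minor allele: the rarer of the two; at 0.5 use the one with fewer carriers
  minor_is_alt <- ifelse(alt_freq < 0.5, TRUE,
                         ifelse(alt_freq > 0.5, FALSE, n2 <= n0))
  maf <- ifelse(n_called > 0, pmin(alt_freq, 1 - alt_freq), NA_real_)
  minor_n_samples <- ifelse(n_called > 0,
                            ifelse(minor_is_alt, n2 + n1, n0 + n1), NA_real_)
  n_classes <- (n0 > 0) + (n1 > 0) + (n2 > 0)
  data.frame(id = x$markers$id, n_called = n_called,
             missing_rate = missing_rate, het_rate = het_rate, maf = maf,
             n_classes = n_classes, minor_n_samples = minor_n_samples,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on call quality
#'
#' Retains markers that are (i) biallelic (at most two alleles identified in
#' genotype calls), (ii) polymorphic (at least two genotype classes
#' present), (iii) at most `max_het` heterozygous among called samples,
#' (iv) have the minor allele carried by at least `min_minor_samples`
#' samples (heterozygous or homozygous minor), and (v) called in at least
#' `min_call_rate` of samples. Boundary values are retained for (iii)--(v):
#' exclusion requires het strictly above 10%, carriers strictly below 5, or
#' call rate strictly below 20%.
#'
#' @param x a [geno_matrix()]
#' @param max_het maximum heterozygosity among called samples (default 0.10)
#' @param min_minor_samples minimum samples carrying the minor allele
#'   (default 5)
#' @param min_call_rate minimum fraction of samples with a call
#'   (default 0.20)
#' @return the filtered [geno_matrix()]; attribute `exclusion_tally` is a
#'   named vector counting, per rule, how many input markers failed it (a
#'   marker can fail several rules), plus the number kept
#' @export
filter_markers <- function(x, max_het = 0.10, min_minor_samples = 5,
                           min_call_rate = 0.20) {
  stopifnot(inherits(x, "geno_matrix"))
  st <- marker_stats(x)
  n_alleles <- if ("n_alleles" %in% names(x$markers)) x$markers$n_alleles
               else ifelse(st$n_classes > 0, 2L, 0L)
  fail_multi <- n_alleles > 2
  fail_mono <- st$n_classes < 2
  fail_het <- !is.na(st$het_rate) & st$het_rate > max_het
  fail_minor <- is.na(st$minor_n_samples) |
    st$minor_n_samples < min_minor_samples
  fail_call <- (st$n_called / nrow(x$geno)) < min_call_rate
  keep <- !(fail_multi | fail_mono | fail_het | fail_minor | fail_call)
  tally <- c(multi_allelic = sum(fail_multi), monomorphic = sum(fail_mono),
             high_het = sum(fail_het), rare_minor = sum(fail_minor),
             low_call_rate = sum(fail_call), kept = sum(keep))
  out <- gm_subset(x, markers = which(keep))
  attr(out, "exclusion_tally") <- tally
  out
}

#' Filter markers on minor allele frequency
#'
#' Retains markers whose MAF is strictly greater than `threshold` (markers
#' at exactly the threshold are dropped).
#'
#' @param x a [geno_matrix()]
#' @param threshold MAF cutoff (default 0.05)
#' @return the filtered [geno_matrix()]
#' @export
maf_filter <- function(x, threshold = 0.05) {
  st <- marker_stats(x)
  gm_subset(x, markers = which(!is.na(st$maf) & st$maf > threshold))
}

#' Fill missing genotype calls (naive single-marker imputation)
#'
#' A deliberately simple, clearly labelled stand-in for haplotype-based
#' imputation: each missing call is replaced either by a draw from the
#' marker's observed genotype-class frequencies (`method = "sample"`) or by
#' the marker's modal genotype (`method = "mode"`). It uses no linkage
#' information, so imputed sets should not be used to benchmark against
#' haplotype-aware imputation.
#'
#' @param x a [geno_matrix()] whose markers passed [filter_markers()]
#' @param seed RNG seed for the sampling method
#' @param method `"sample"` (default) or `"mode"`
#' @return a [geno_matrix()] with zero missing calls
#' @export
impute_naive <- function(x, seed = 1, method = c("sample", "mode")) {
  stopifnot(inherits(x, "geno_matrix"))
  method <- match.arg(method)
  g <- x$geno
  all_missing <- colSums(!is.na(g)) == 0
  if (any(all_missing))
    stop("marker(s) with no genotype calls cannot be imputed: ",
         paste(utils::head(x$markers$id[all_missing], 5), collapse = ", "))
  set.seed(seed)
  for (j in which(colSums(is.na(g)) > 0)) {
    obs <- g[!is.na(g[, j]), j]
    miss <- which(is.na(g[, j]))
    if (method == "sample") {
      g[miss, j] <- sample(obs, length(miss), replace = TRUE)
    } else {
      tab <- sort(table(obs), decreasing = TRUE)
      g[miss, j] <- as.numeric(names(tab)[1])
    }
  }
  x$geno <- g
  x
}

#' Overlap between two genotyping platforms
#'
#' Matches markers on (chromosome, position) and reports the shared set plus
#' genotype-call concordance over samples present in both matrices.
#'
#' @param set_a,set_b [geno_matrix()] objects on the same reference
#'   coordinates
#' @return a list: `n_overlap`, `markers` (data.frame of shared chrom/pos
#'   with both ids), `shared_samples`, and `concordance` (fraction of equal
#'   non-missing calls over shared sample x marker cells, `NA` if none)
#' @export
platform_overlap <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "geno_matrix"), inherits(set_b, "geno_matrix"))
  key_a <- paste0(set_a$markers$chrom, ":", set_a$markers$pos)
  key_b <- paste0(set_b$markers$chrom, ":", set_b$markers$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  samples <- intersect(rownames(set_a$geno), rownames(set_b$geno))
  concordance <- NA_real_
  if (length(shared) > 0 && length(samples) > 0) {
    ga <- set_a$geno[samples, ia, drop = FALSE]
    gb <- set_b$geno[samples, ib, drop = FALSE]
    both <- !is.na(ga) & !is.na(gb)
    if (any(both)) concordance <- mean(ga[both] == gb[both])
  }
  list(n_overlap = length(shared),
       markers = data.frame(chrom = set_a$markers$chrom[ia],
                            pos = set_a$markers$pos[ia],
                            id_a = set_a$markers$id[ia],
                            id_b = set_b$markers$id[ib],
                            stringsAsFactors = FALSE),
       shared_samples = samples,
       concordance = concordance)
}

#' Mask genotype calls at random (to emulate GBS missingness)
#'
#' @param x a [geno_matrix()]
#' @param missing_rate fraction of cells set to missing
#' @param seed RNG seed
#' @return a [geno_matrix()] with calls masked
#' @export
mask_genotypes <- function(x, missing_rate, seed = 1) {
  stopifnot(inherits(x, "geno_matrix"), missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  g <- x$geno
  drop <- stats::runif(length(g)) < missing_rate
  g[drop] <- NA_real_
  x$geno <- g
  x
}
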