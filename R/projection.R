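#' Project an F1 genotype from two parental dosages
#'
#' On the 0--2 dosage scale (0 = homozygous reference, 2 = homozygous
#' alternate), an F1 from two inbred or partially heterozygous parents is
#' assigned by case analysis:
#' * both parents homozygous for the same allele: the F1 receives that call;
#' * parents homozygous for opposite alleles: the F1 is heterozygous
#'   (dosage 1);
#' * either parent heterozygous: the F1 receives the mean of the two
#'   parental dosages (possibly fractional, e.g. 0.5);
#' * either parent missing: missing.
#'
#' The three non-missing rules are jointly equivalent to the midpoint rule
#' `(p1 + p2) / 2`.
#'
#' @param parent1_dosage,parent2_dosage numeric vectors of dosages in
#'   `{0, 1, 2}` or `NA` (recycled to a common length)
#' @return numeric vector of hybrid dosages in \[0, 2\] or `NA`
#' @export
project_hybrid <- function(parent1_dosage, parent2_dosage) {
  p1 <- parent1_dosage
  p2 <- parent2_dosage
  if (any(p1 < 0 | p1 > 2, na.rm = TRUE) ||
      any(p2 < 0 | p2 > 2, na.rm = TRUE))
    stop("parental dosages must lie in [0, 2]")
  n <- max(length(p1), length(p2))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(p1) & !is.na(p2)
  hom1 <- ok & p1 %in% c(0, 2)
  hom2 <- ok & p2 %in% c(0, 2)
  same <- hom1 & hom2 & p1 == p2
  oppo <- hom1 & hom2 & p1 != p2
  het <- ok & !(hom1 & hom2)
  out[same] <- p1[same]
  out[oppo] <- 1
  out[het] <- (p1[het] + p2[het]) / 2
  out
}

#' Project genotypes for every hybrid in a cross plan
#'
#' @param plan data.frame with columns `hybrid_id`, `female_id`, `male_id`
#' @param parents a [geno_matrix()] containing every parent in the plan
#' @return a [geno_matrix()] with one row per hybrid (entry type `hybrid`),
#'   markers aligned to the parental marker set
#' @export
project_all <- function(plan, parents) {
  stopifnot(inherits(parents, "geno_matrix"))
  need <- c("hybrid_id", "female_id", "male_id")
  if (!all(need %in% names(plan)))
    stop("plan needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(plan$hybrid_id)) stop("hybrid_id values must be unique")
  fi <- match(plan$female_id, rownames(parents$geno))
  mi <- match(plan$male_id, rownames(parents$geno))
  if (anyNA(fi))
    stop("unknown female parent id(s): ",
         paste(unique(plan$female_id[is.na(fi)]), collapse = ", "))
  if (anyNA(mi))
    stop("unknown male parent id(s): ",
         paste(unique(plan$male_id[is.na(mi)]), collapse = ", "))
  # the three projection rules reduce to the parental midpoint; NA propagates
  h <- (parents$geno[fi, , drop = FALSE] + parents$geno[mi, , drop = FALSE]) / 2
  rownames(h) <- plan$hybrid_id
  geno_matrix(h, markers = parents$markers,
              entries = data.frame(id = plan$hybrid_id, type = "hybrid",
                                   stringsAsFactors = FALSE))
}
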