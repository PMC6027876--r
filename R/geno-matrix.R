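#' Genotype matrix container
#'
#' An entries-by-markers dosage matrix on the 0--2 scale (0 = homozygous
#' reference, 2 = homozygous alternate, `NA` = missing) together with marker
#' metadata (chromosome, position, alleles) and entry metadata (id, type).
#' Genotyped inbred lines carry integer dosages; hybrids projected from
#' inbred parents may carry real-valued dosages such as 0.5.
#'
#' @param geno numeric matrix, entries in rows and markers in columns, with
#'   dosages in \[0, 2\] or `NA`. Row and column names are used as entry and
#'   marker ids when `entries`/`markers` are not supplied.
#' @param markers optional data.frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt` (and optionally `n_alleles`, the number of distinct alleles
#'   observed in genotype calls at the site). One row per column of `geno`.
#' @param entries optional data.frame with columns `id` and `type`; `type`
#'   is one of `"inbred_B"`, `"inbred_R"`, `"hybrid"`. One row per row of
#'   `geno`.
#' @return An object of class `geno_matrix`: a list with elements `geno`,
#'   `markers`, `entries`.
#' @export
geno_matrix <- function(geno, markers = NULL, entries = NULL) {
  if (!is.matrix(geno) || !is.numeric(geno))
    stop("`geno` must be a numeric matrix")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("entry", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("m", seq_len(ncol(geno)))
  if (is.null(markers)) {
    markers <- data.frame(
      id = colnames(geno), chrom = "chr1", pos = seq_len(ncol(geno)),
      ref = "A", alt = "B", stringsAsFactors = FALSE
    )
  }
  if (is.null(entries)) {
    entries <- data.frame(id = rownames(geno), type = "inbred_B",
                          stringsAsFactors = FALSE)
  }
  obj <- structure(list(geno = geno, markers = markers, entries = entries),
                   class = "geno_matrix")
  validate_geno_matrix(obj)
}

validate_geno_matrix <- function(x) {
  g <- x$geno
  if (nrow(x$markers) != ncol(g))
    stop("marker metadata rows (", nrow(x$markers),
         ") do not match marker columns (", ncol(g), ")")
  if (nrow(x$entries) != nrow(g))
    stop("entry metadata rows do not match genotype rows")
  if (anyDuplicated(x$entries$id))
    stop("entry ids must be unique")
  rng <- if (all(is.na(g))) c(NA_real_, NA_real_) else range(g, na.rm = TRUE)
  if (isTRUE(rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]; found range [",
         rng[1], ", ", rng[2], "]")
  if (anyDuplicated(x$markers[, c("chrom", "pos")]))
    stop("marker positions must be unique within a chromosome")
  if (!all(x$entries$type %in% c("inbred_B", "inbred_R", "hybrid")))
    stop("entry types must be inbred_B, inbred_R or hybrid")
  x
}

#' @method print geno_matrix
#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(x$entries$type)
  cat("geno_matrix: ", nrow(x$geno), " entries x ", ncol(x$geno),
      " markers\n", sep = "")
  cat("  entries:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  missing: ", format(100 * mean(is.na(x$geno)), digits = 3),
      "%\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a geno_matrix by markers and/or entries
#'
#' @param x a [geno_matrix()]
#' @param markers marker ids (character) or column indices to keep
#' @param entries entry ids (character) or row indices to keep
#' @return the subsetted `geno_matrix`
#' @export
gm_subset <- function(x, markers = NULL, entries = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  if (!is.null(markers)) {
    j <- if (is.character(markers)) match(markers, colnames(x$geno)) else markers
    if (anyNA(j)) stop("unknown marker id(s): ",
                       paste(markers[is.na(j)], collapse = ", "))
    x$geno <- x$geno[, j, drop = FALSE]
    x$markers <- x$markers[j, , drop = FALSE]
  }
  if (!is.null(entries)) {
    i <- if (is.character(entries)) match(entries, rownames(x$geno)) else entries
    if (anyNA(i)) stop("unknown entry id(s): ",
                       paste(entries[is.na(i)], collapse = ", "))
    x$geno <- x$geno[i, , drop = FALSE]
    x$entries <- x$entries[i, , drop = FALSE]
  }
  x
}

#' Combine two genotype matrices row-wise (same marker set)
#'
#' @param x,y `geno_matrix` objects sharing an identical marker set
#' @return a `geno_matrix` holding the entries of both
#' @export
gm_rbind <- function(x, y) {
  stopifnot(inherits(x, "geno_matrix"), inherits(y, "geno_matrix"))
  if (!identical(colnames(x$geno), colnames(y$geno)))
    stop("marker sets differ; align markers before combining")
  geno_matrix(rbind(x$geno, y$geno),
              markers = x$markers,
              entries = rbind(x$entries, y$entries))
}

# ---- readers / writers ----------------------------------------------------

#' Write a genotype matrix as a tab-delimited dosage table
#'
#' The first four columns are marker metadata (id, chrom, pos, alleles),
#' followed by one column per entry. A `# seed:` header comment is written
#' when `seed` is given so outputs are traceable to the RNG state that
#' produced them.
#'
#' @param x a [geno_matrix()]
#' @param path output file
#' @param seed optional integer recorded in the header comment
#' @export
write_geno_matrix <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  df <- data.frame(marker = x$markers$id, chrom = x$markers$chrom,
                   pos = x$markers$pos,
                   alleles = paste0(x$markers$ref, "/", x$markers$alt),
                   t(x$geno), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix written by [write_geno_matrix()]
#'
#' @param path file path
#' @param entry_types optional named character vector mapping entry id to
#'   type; entries not named default to `"inbred_B"`.
#' @return a [geno_matrix()]
#' @export
read_geno_matrix <- function(path, entry_types = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  markers <- data.frame(id = df$marker, chrom = df$chrom, pos = df$pos,
                        ref = vapply(al, `[`, "", 1),
                        alt = vapply(al, `[`, "", 2),
                        stringsAsFactors = FALSE)
  g <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  colnames(g) <- markers$id
  type <- rep("inbred_B", nrow(g))
  if (!is.null(entry_types)) {
    hit <- rownames(g) %in% names(entry_types)
    type[hit] <- unname(entry_types[rownames(g)[hit]])
  }
  geno_matrix(g, markers = markers,
              entries = data.frame(id = rownames(g), type = type,
                                   stringsAsFactors = FALSE))
}

#' Write genotypes as a VCF with dosage-coded GT (and DS for real dosages)
#'
#' Integer dosages are encoded as GT (`0/0`, `0/1`, `1/1`, `./.`); the DS
#' field always carries the numeric dosage so that projected hybrids with
#' fractional dosages round-trip losslessly.
#'
#' @param x a [geno_matrix()]
#' @param path output file (plain-text VCF)
#' @param seed optional integer recorded in a `##source` header line
#' @export
write_vcf <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=milletgp", if (!is.null(seed)) paste0(" seed=", seed)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage 0-2">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(x$geno)), collapse = "\t"), con)
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  for (j in seq_len(ncol(x$geno))) {
    d <- x$geno[, j]
    cells <- paste(gt_of(d), ifelse(is.na(d), ".", format(d, trim = TRUE)),
                   sep = ":")
    writeLines(paste(c(x$markers$chrom[j], x$markers$pos[j], x$markers$id[j],
                       x$markers$ref[j], x$markers$alt[j], ".", "PASS", ".",
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Uses the GT field (via `vcfR`) to build a 0/1/2 dosage matrix; sites with
#' half-missing or phased calls are handled, and a DS field, when present,
#' overrides GT so fractional dosages survive a round trip.
#'
#' @param path VCF file (plain or gzipped)
#' @param entry_types optional named vector of entry types, as in
#'   [read_geno_matrix()]
#' @return a [geno_matrix()]
#' @export
read_vcf_geno <- function(path, entry_types = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("DS", fmt, fixed = TRUE))) {
    ds <- suppressWarnings(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    dos[!is.na(ds)] <- ds[!is.na(ds)]
  }
  fix <- vcfR::getFIX(v)
  markers <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE
  )
  g <- t(dos)
  colnames(g) <- markers$id
  type <- rep("inbred_B", nrow(g))
  if (!is.null(entry_types)) {
    hit <- rownames(g) %in% names(entry_types)
    type[hit] <- unname(entry_types[rownames(g)[hit]])
  }
  geno_matrix(g, markers = markers,
              entries = data.frame(id = rownames(g), type = type,
                                   stringsAsFactors = FALSE))
}
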