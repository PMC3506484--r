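# Genotype containers and I/O.
#
# A genotype_matrix holds an individuals x SNPs additive-dosage matrix
# (minor-allele counts 0/1/2, NA allowed before QC) plus per-SNP metadata:
# id, region_label (gene), minor_allele_freq, position.

#' Construct a genotype matrix
#'
#' Container for an individuals-by-SNPs additive dosage matrix (minor-allele
#' counts in \{0, 1, 2\}, `NA` allowed before quality control) together with
#' per-SNP metadata and sample identifiers.
#'
#' @param values Numeric matrix, individuals in rows, SNPs in columns.
#' @param snps `data.frame` with one row per SNP and columns `id`,
#'   `region_label`, `minor_allele_freq` and optionally `position`. If
#'   `minor_allele_freq` is missing it is computed from `values`.
#' @param sample_ids Character vector of row identifiers; defaults to
#'   `"S1"`, `"S2"`, ...
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `snps` and `sample_ids`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2),
#'                      snps = data.frame(id = c("rs1", "rs2"),
#'                                        region_label = "GENE1"))
#' g
#' @export
genotype_matrix <- function(values, snps = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  p <- ncol(values)
  if (is.null(snps)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("snp", seq_len(p))
    snps <- data.frame(id = ids, region_label = "region1",
                       stringsAsFactors = FALSE)
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("id", "region_label") %in% names(snps)))
    stop("'snps' needs columns 'id' and 'region_label'")
  if (nrow(snps) != p)
    stop("snp table has ", nrow(snps), " rows but matrix has ", p, " columns")
  if (anyDuplicated(snps$id))
    stop("duplicated SNP ids: ",
         paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
  if (is.null(snps$minor_allele_freq))
    snps$minor_allele_freq <- .observed_maf(values)
  if (is.null(snps$position)) snps$position <- NA_integer_
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(m))
  }
  if (length(sample_ids) != m)
    stop("length(sample_ids) != nrow(values)")
  bad <- values[!is.na(values)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosages must be 0, 1 or 2 (or NA before QC)")
  dimnames(values) <- list(sample_ids, snps$id)
  structure(list(values = values, snps = snps,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

.observed_maf <- function(values) {
  f <- colMeans(values, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$values), " individuals x ",
      ncol(x$values), " SNPs\n", sep = "")
  cat("regions: ", paste(unique(x$snps$region_label), collapse = ", "), "\n",
      sep = "")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("missing entries: ", nmiss, " (pre-QC)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# Row subset, keeping metadata.
.subset_rows <- function(G, idx) {
  genotype_matrix(G$values[idx, , drop = FALSE], snps = G$snps,
                  sample_ids = G$sample_ids[idx])
}

.read_region_map <- function(region_map) {
  if (is.character(region_map) && length(region_map) == 1) {
    region_map <- utils::read.table(region_map, header = FALSE,
                                    stringsAsFactors = FALSE)
  }
  region_map <- as.data.frame(region_map, stringsAsFactors = FALSE)
  if (ncol(region_map) < 2)
    stop("region map needs two columns: SNP id, gene label")
  names(region_map)[1:2] <- c("id", "region_label")
  region_map[1:2]
}

#' Load genotype data
#'
#' Reads genotypes for one or more genes from a standard file and returns
#' additive minor-allele dosages. Three formats are supported: VCF (v4.x,
#' biallelic SNPs; dosages are flipped where the ALT allele is the major
#' allele so columns always count the minor allele), PLINK-style additive
#' dosage text (header row of SNP ids; `FID`/`IID`/`PHENOTYPE` columns are
#' tolerated and dropped), and a plain delimited numeric matrix as written
#' by [write_genotypes()].
#'
#' @param path Path to the input file.
#' @param format One of `"delimited"`, `"vcf"`, `"plink_additive"`.
#' @param region_map SNP-to-gene assignment: a two-column `data.frame`
#'   (SNP id, gene label) or the path of a two-column text file. SNPs absent
#'   from the map are dropped with a warning. `NULL` assigns every SNP to
#'   region `"region1"`.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path,
                           format = c("delimited", "vcf", "plink_additive"),
                           region_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  G <- switch(format,
              delimited = .load_delimited(path),
              plink_additive = .load_plink_additive(path),
              vcf = .load_vcf(path))
  if (!is.null(region_map)) {
    map <- .read_region_map(region_map)
    keep <- G$snps$id %in% map$id
    if (!all(keep)) {
      warning("dropping ", sum(!keep),
              " SNP(s) absent from the region map: ",
              paste(G$snps$id[!keep], collapse = ", "))
      if (!any(keep)) stop("no SNP left after applying the region map")
      G$values <- G$values[, keep, drop = FALSE]
      G$snps <- G$snps[keep, , drop = FALSE]
    }
    G$snps$region_label <- map$region_label[match(G$snps$id, map$id)]
  }
  genotype_matrix(G$values, snps = G$snps, sample_ids = G$sample_ids)
}

.load_delimited <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- NULL
  if (tolower(names(tab)[1]) %in% c("sample_id", "sample", "id")) {
    sample_ids <- as.character(tab[[1]])
    tab <- tab[-1]
  }
  pheno <- NULL
  if ("phenotype" %in% tolower(names(tab))) {
    j <- which(tolower(names(tab)) == "phenotype")
    pheno <- tab[[j]]
    tab <- tab[-j]
  }
  values <- as.matrix(tab)
  G <- list(values = values,
            snps = data.frame(id = colnames(values), region_label = "region1",
                              stringsAsFactors = FALSE),
            sample_ids = sample_ids)
  attr(G, "phenotype") <- pheno
  G
}

.load_plink_additive <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  low <- tolower(names(tab))
  sample_ids <- if ("iid" %in% low) as.character(tab[[which(low == "iid")]])
  drop <- low %in% c("fid", "iid", "phenotype", "pheno")
  tab <- tab[!drop]
  values <- as.matrix(tab)
  list(values = values,
       snps = data.frame(id = colnames(values), region_label = "region1",
                         stringsAsFactors = FALSE),
       sample_ids = sample_ids)
}

.load_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    warning("dropping ", sum(!bi), " non-biallelic site(s)")
    v <- v[bi, ]
  }
  if (nrow(v@fix) == 0) stop("no biallelic SNP in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; accept '/' or '|' separators
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  dose <- t(dose)                       # individuals x SNPs
  ids <- v@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(v@fix[noid, "CHROM"], ":", v@fix[noid, "POS"])
  # orient to the minor allele
  altf <- colMeans(dose, na.rm = TRUE) / 2
  flip <- !is.na(altf) & altf > 0.5
  dose[, flip] <- 2 - dose[, flip]
  list(values = dose,
       snps = data.frame(id = ids, region_label = "region1",
                         position = suppressWarnings(as.integer(v@fix[, "POS"])),
                         stringsAsFactors = FALSE),
       sample_ids = colnames(gt))
}

#' Write a genotype matrix to delimited text
#'
#' Writes a tab-separated table with a `sample_id` column, one column per
#' SNP (header = SNP id) and optionally a `phenotype` column. The format
#' round-trips exactly through [load_genotypes()] with
#' `format = "delimited"`.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file path.
#' @param phenotype Optional binary vector written as a final column.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, phenotype = NULL) {
  tab <- data.frame(sample_id = G$sample_ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(G$values, check.names = FALSE))
  if (!is.null(phenotype)) tab$phenotype <- phenotype
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for a genotype matrix
#'
#' Removes SNP columns whose missingness exceeds `max_missing_rate`, imputes
#' the remaining missing entries to the rounded column mean, and removes
#' monomorphic (constant) columns. Canonical-correlation machinery requires
#' complete, polymorphic matrices, so this is applied before any testing.
#' The operation is idempotent.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing_rate Maximum tolerated per-SNP missingness (default
#'   0.05).
#' @return The filtered [genotype_matrix()]; removals are reported via
#'   `message()`.
#' @export
qc_filter <- function(G, max_missing_rate = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  V <- G$values
  miss <- colMeans(is.na(V))
  drop_miss <- miss > max_missing_rate
  if (any(drop_miss))
    message("qc_filter: dropping ", sum(drop_miss),
            " SNP(s) with missingness > ", max_missing_rate, ": ",
            paste(G$snps$id[drop_miss], collapse = ", "))
  V <- V[, !drop_miss, drop = FALSE]
  snps <- G$snps[!drop_miss, , drop = FALSE]
  if (ncol(V) == 0)
    stop("qc_filter: all SNPs removed (missingness filter)")
  if (anyNA(V)) {
    n_imp <- sum(is.na(V))
    for (j in seq_len(ncol(V))) {
      na <- is.na(V[, j])
      if (any(na)) V[na, j] <- round(mean(V[!na, j]))
    }
    message("qc_filter: imputed ", n_imp,
            " missing entr(ies) to rounded column means")
  }
  mono <- apply(V, 2, function(x) length(unique(x)) < 2)
  if (any(mono))
    message("qc_filter: dropping ", sum(mono), " monomorphic SNP(s): ",
            paste(snps$id[mono], collapse = ", "))
  V <- V[, !mono, drop = FALSE]
  snps <- snps[!mono, , drop = FALSE]
  if (ncol(V) == 0)
    stop("qc_filter: all SNPs removed (monomorphic after imputation)")
  snps$minor_allele_freq <- .observed_maf(V)
  genotype_matrix(V, snps = snps, sample_ids = G$sample_ids)
}

#' Split two gene matrices by case/control status
#'
#' Partitions the rows of the two gene matrices into case (phenotype 1) and
#' control (phenotype 0) strata, preserving the original row order within
#' each stratum. The co-association statistics compare the canonical
#' correlation of the two genes between the resulting strata.
#'
#' @param G_A,G_B [genotype_matrix()] objects for gene A and gene B over the
#'   same individuals, in the same row order.
#' @param phenotype Binary vector (1 = case, 0 = control) of length
#'   `nrow(G_A)`.
#' @return An object of class `case_control_split` with elements `cases_A`,
#'   `cases_B`, `controls_A`, `controls_B` and `phenotype`.
#' @export
split_by_phenotype <- function(G_A, G_B, phenotype) {
  stopifnot(inherits(G_A, "genotype_matrix"), inherits(G_B, "genotype_matrix"))
  m <- nrow(G_A$values)
  if (nrow(G_B$values) != m)
    stop("G_A and G_B have different numbers of individuals")
  if (length(phenotype) != m)
    stop("phenotype length (", length(phenotype),
         ") does not match the number of individuals (", m, ")")
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be coded 0 (control) / 1 (case)")
  if (!any(phenotype == 1L)) stop("no cases in phenotype")
  if (!any(phenotype == 0L)) stop("no controls in phenotype")
  ca <- which(phenotype == 1L)
  co <- which(phenotype == 0L)
  structure(list(cases_A = .subset_rows(G_A, ca),
                 cases_B = .subset_rows(G_B, ca),
                 controls_A = .subset_rows(G_A, co),
                 controls_B = .subset_rows(G_B, co),
                 phenotype = phenotype),
            class = "case_control_split")
}

#' @export
print.case_control_split <- function(x, ...) {
  cat("case_control_split: ", nrow(x$cases_A$values), " cases / ",
      nrow(x$controls_A$values), " controls\n", sep = "")
  cat("gene A: ", ncol(x$cases_A$values), " SNPs (",
      x$cases_A$snps$region_label[1], "), gene B: ",
      ncol(x$cases_B$values), " SNPs (",
      x$cases_B$snps$region_label[1], ")\n", sep = "")
  invisible(x)
}
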